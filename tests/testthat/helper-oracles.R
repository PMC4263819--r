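# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the inverse normal is obtained by root-finding on
# pnorm (not qnorm), meta-d' by grid search (not optim), integrals by
# Riemann sums (not integrate).

# High-precision inverse normal by bisection/Brent on the CDF.
oracle_z <- function(p) {
  vapply(p, function(pp) {
    stats::uniroot(function(z) stats::pnorm(z) - pp, c(-10, 10),
                   tol = 1e-14)$root
  }, numeric(1))
}

oracle_d1 <- function(h, m, fa, cr) {
  oracle_z(h / (h + m)) - oracle_z(fa / (fa + cr))
}

oracle_d2 <- function(cc, gc, ci, gi) {
  oracle_z(cc / (cc + gc)) - oracle_z(ci / (ci + gi))
}

# Two-stage grid search for meta-d' under the same response-conditional
# binomial likelihood as fit_meta_d, refined to step 1e-3.
oracle_meta_d <- function(counts1, by_resp) {
  est1 <- dprime1(counts1)
  c_rel <- if (abs(est1$d1) < 1e-12) 0 else est1$criterion_c / est1$d1
  gr <- by_resp$grammatical
  un <- by_resp$ungrammatical
  k_conf <- c(gr[1], gr[3], un[1], un[3])
  n_tot <- c(gr[1] + gr[2], gr[3] + gr[4], un[1] + un[2], un[3] + un[4])
  nll <- function(md, du, dl) {
    meta_c <- c_rel * md
    u <- meta_c + du; l <- meta_c - dl
    mu <- c(md / 2, -md / 2, -md / 2, md / 2)
    resp_g <- c(TRUE, TRUE, FALSE, FALSE)
    p_resp <- ifelse(resp_g, pnorm(meta_c, mu, lower.tail = FALSE),
                     pnorm(meta_c, mu))
    p_conf <- ifelse(resp_g, pnorm(u, mu, lower.tail = FALSE),
                     pnorm(l, mu))
    p <- pmin(pmax(p_conf / p_resp, 1e-12), 1 - 1e-12)
    -sum(k_conf * log(p) + (n_tot - k_conf) * log1p(-p))
  }
  best <- c(NA, NA, NA); best_val <- Inf
  grid_pass <- function(md_seq, du_seq, dl_seq) {
    for (md in md_seq) for (du in du_seq) for (dl in dl_seq) {
      v <- nll(md, du, dl)
      if (v < best_val) { best_val <<- v; best <<- c(md, du, dl) }
    }
  }
  grid_pass(seq(-3, 3, by = 0.2), seq(0.05, 3, by = 0.15),
            seq(0.05, 3, by = 0.15))
  grid_pass(seq(best[1] - 0.3, best[1] + 0.3, by = 0.01),
            seq(max(best[2] - 0.3, 0.001), best[2] + 0.3, by = 0.02),
            seq(max(best[3] - 0.3, 0.001), best[3] + 0.3, by = 0.02))
  grid_pass(seq(best[1] - 0.02, best[1] + 0.02, by = 0.001),
            seq(max(best[2] - 0.04, 0.001), best[2] + 0.04, by = 0.004),
            seq(max(best[3] - 0.04, 0.001), best[3] + 0.04, by = 0.004))
  best[1]
}

# Expected (large-n) Type I and response-conditional Type II counts for an
# equal-variance SDT observer with sensitivity d, criterion c and confidence
# thresholds l < c < u, scaled to n trials total (half per class).
sdt_expected_counts <- function(d, c0, l, u, n = 1e4) {
  # class means +/- d/2; response G iff x > c0; confident iff x > u or x <= l
  p <- function(mu, lo, hi) pnorm(hi, mu) - pnorm(lo, mu)
  half <- n / 2
  mu_g <- d / 2; mu_u <- -d / 2
  counts1 <- c(hits = half * p(mu_g, c0, Inf),
               misses = half * p(mu_g, -Inf, c0),
               false_alarms = half * p(mu_u, c0, Inf),
               correct_rejections = half * p(mu_u, -Inf, c0))
  by_resp <- list(
    grammatical = c(confident_correct = half * p(mu_g, u, Inf),
                    guess_correct = half * p(mu_g, c0, u),
                    confident_incorrect = half * p(mu_u, u, Inf),
                    guess_incorrect = half * p(mu_u, c0, u)),
    ungrammatical = c(confident_correct = half * p(mu_u, -Inf, l),
                      guess_correct = half * p(mu_u, l, c0),
                      confident_incorrect = half * p(mu_g, -Inf, l),
                      guess_incorrect = half * p(mu_g, l, c0)))
  list(type1 = counts1, by_response = by_resp,
       type2 = by_resp$grammatical + by_resp$ungrammatical)
}

# Small hand-built trial data frame: one row per trial.
make_trials <- function(participant_id, is_grammatical, judgment, confidence,
                        trial_index = seq_along(judgment)) {
  data.frame(participant_id = participant_id, trial_index = trial_index,
             is_grammatical = is_grammatical, judgment = judgment,
             confidence = as.integer(confidence), stringsAsFactors = FALSE)
}
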