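#' Maximum-likelihood meta-d'
#'
#' Fits the Type I sensitivity that an ideal equal-variance SDT observer
#' would need in order to produce the observed response-conditional
#' confidence data, following the likelihood approach of Maniscalco and Lau.
#' Meta-d' is read on the d'1 scale and, unlike d'2, is unbiased by the
#' placement of the Type I criterion.
#'
#' Model: ungrammatical evidence ~ Normal(-meta_d/2, 1), grammatical
#' evidence ~ Normal(+meta_d/2, 1). The meta-level criterion is tied to the
#' empirical Type I relative criterion, `meta_c = (c / d'1) * meta_d`, and a
#' single confidence threshold sits on each side of it (binary confidence).
#' The fit maximizes the multinomial likelihood of the confident/guess
#' counts conditional on the Type I response and stimulus class.
#'
#' @param counts1 Type I table (named vector: `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`) used only to fix the relative
#'   criterion `c' = c/d'1`.
#' @param counts2_by_response list with elements `grammatical` and
#'   `ungrammatical`, each a Type II cell vector (`confident_correct`,
#'   `guess_correct`, `confident_incorrect`, `guess_incorrect`) restricted
#'   to that Type I response. Counts need not be integers (expected counts
#'   are accepted).
#' @param correction `"none"` (default) or `"loglinear"`, applied to the
#'   Type I table before deriving `c'` (the Type II likelihood uses the raw
#'   counts).
#' @return the fitted meta-d' (numeric scalar), with attributes
#'   `thresholds` (lower, meta_c, upper), `logLik` and `convergence`.
#' @examples
#' t1 <- c(hits = 20, misses = 10, false_alarms = 10, correct_rejections = 20)
#' t2 <- list(
#'   grammatical = c(confident_correct = 12, guess_correct = 8,
#'                   confident_incorrect = 4, guess_incorrect = 6),
#'   ungrammatical = c(confident_correct = 11, guess_correct = 9,
#'                     confident_incorrect = 4, guess_incorrect = 6))
#' fit_meta_d(t1, t2)
#' @export
fit_meta_d <- function(counts1, counts2_by_response,
                       correction = c("none", "loglinear")) {
  correction <- match.arg(correction)
  est1 <- dprime1(counts1, correction = correction)
  if (!est1$computable) {
    stop("Type I table has an empty cell; relative criterion is undefined")
  }
  # c' = c/d'; at d' = 0 the ratio is undefined and an unbiased criterion
  # (c' = 0) is assumed.
  c_rel <- if (abs(est1$d1) < 1e-12) 0 else est1$criterion_c / est1$d1

  gr <- counts2_by_response$grammatical
  un <- counts2_by_response$ungrammatical
  cells <- c("confident_correct", "guess_correct",
             "confident_incorrect", "guess_incorrect")
  gr <- gr[cells]; un <- un[cells]
  stopifnot(!anyNA(gr), !anyNA(un), all(gr >= 0), all(un >= 0))
  margins <- c(gr[1] + gr[2], gr[3] + gr[4], un[1] + un[2], un[3] + un[4])
  if (any(margins == 0)) {
    stop("a response-conditional Type II margin is empty; meta-d' is undefined")
  }

  # Confident counts and totals per (response, stimulus) class:
  #   response G, stimulus grammatical  (correct)   : gr[1] of gr[1]+gr[2]
  #   response G, stimulus ungrammatical (incorrect): gr[3] of gr[3]+gr[4]
  #   response U, stimulus ungrammatical (correct)  : un[1] of un[1]+un[2]
  #   response U, stimulus grammatical  (incorrect) : un[3] of un[3]+un[4]
  k_conf <- c(gr[1], gr[3], un[1], un[3])
  n_tot <- margins

  nll <- function(par) {
    md <- par[1]
    du <- exp(par[2])   # upper threshold offset above meta_c
    dl <- exp(par[3])   # lower threshold offset below meta_c
    meta_c <- c_rel * md
    u <- meta_c + du
    l <- meta_c - dl
    mu <- c(md / 2, -md / 2, -md / 2, md / 2)  # per class above
    resp_g <- c(TRUE, TRUE, FALSE, FALSE)
    p_resp <- ifelse(resp_g, stats::pnorm(meta_c, mu, lower.tail = FALSE),
                     stats::pnorm(meta_c, mu))
    p_conf_joint <- ifelse(resp_g, stats::pnorm(u, mu, lower.tail = FALSE),
                           stats::pnorm(l, mu))
    p <- pmin(pmax(p_conf_joint / p_resp, 1e-12), 1 - 1e-12)
    -sum(k_conf * log(p) + (n_tot - k_conf) * log1p(-p))
  }

  start <- c(est1$d1, log(0.5), log(0.5))
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  if (fit$convergence != 0) {
    stop("meta-d' fit did not converge (optim code ", fit$convergence,
         ", value ", signif(fit$value, 6), ")")
  }
  md <- fit$par[1]
  meta_c <- c_rel * md
  structure(md,
            thresholds = c(lower = meta_c - exp(fit$par[3]),
                           meta_c = meta_c,
                           upper = meta_c + exp(fit$par[2])),
            logLik = -fit$value,
            convergence = fit$convergence)
}
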