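test_that("split_by_fraction cuts at floor(fraction * T) by trial_index", {
  d64 <- generate_dataset(synth_config(n_participants = 2, n_trials = 64,
                                       seed = 1))
  s <- split_by_fraction(d64, 0.75)
  expect_equal(as.integer(table(s$selection_trials$participant_id)),
               c(48L, 48L))
  expect_equal(as.integer(table(s$analysis_trials$participant_id)),
               c(16L, 16L))
  expect_true(all(s$selection_trials$trial_index <= 48))
  expect_true(all(s$analysis_trials$trial_index > 48))

  d60 <- generate_dataset(synth_config(n_participants = 1, n_trials = 60,
                                       seed = 2))
  s60 <- split_by_fraction(d60, 0.75)
  expect_equal(nrow(s60$selection_trials), 45L)
  expect_equal(nrow(s60$analysis_trials), 15L)

  s50 <- split_by_fraction(d64, 0.5)
  expect_equal(nrow(s50$selection_trials), nrow(s50$analysis_trials))

  expect_error(split_by_fraction(d64, 1.2), "between 0 and 1")
  d4 <- generate_dataset(synth_config(n_participants = 1, n_trials = 4,
                                      seed = 3))
  expect_error(split_by_fraction(d4, 0.1), "empty partition")
})

test_that("partitions are disjoint, exhaustive and stable under row shuffling", {
  d <- generate_dataset(synth_config(n_participants = 5, n_trials = 16,
                                     seed = 4))
  s <- split_by_fraction(d, 0.75)
  key <- function(x) paste(x$participant_id, x$trial_index)
  expect_length(intersect(key(s$selection_trials), key(s$analysis_trials)), 0)
  expect_setequal(c(key(s$selection_trials), key(s$analysis_trials)), key(d))
  shuffled <- agl_dataset(as.data.frame(d)[sample(nrow(d)), ])
  s2 <- split_by_fraction(shuffled, 0.75)
  expect_setequal(key(s2$selection_trials), key(s$selection_trials))
})

test_that("classification follows selection d'1 sign with zero-cell exclusion", {
  # build three participants with hand-chosen counts on an 8+4 trial design:
  # selection (8 trials) and analysis (4 trials)
  mk <- function(pid, sel_judg, ana_judg, ana_conf) {
    make_trials(pid,
                is_grammatical = c(rep(c(TRUE, FALSE), 4), TRUE, TRUE, FALSE, FALSE),
                judgment = c(sel_judg, ana_judg),
                confidence = c(rep(70, 4), rep(50, 4), ana_conf))
  }
  # selection d'1 = 0 (hit rate = FA rate = 1/2); analysis all cells nonzero
  p_chance <- mk("chance",
                 sel_judg = c("G", "G", "U", "U", "U", "G", "G", "U"),
                 ana_judg = c("G", "U", "U", "G"),
                 ana_conf = c(80, 80, 50, 50))
  # selection d'1 > 0 (3/4 hits, 1/4 FA)
  p_above <- mk("above",
                sel_judg = c("G", "U", "G", "U", "G", "G", "U", "U"),
                ana_judg = c("G", "U", "U", "G"),
                ana_conf = c(80, 80, 50, 50))
  # analysis subset has no confident-incorrect trials -> excluded
  p_excl <- mk("excl",
               sel_judg = c("G", "G", "U", "U", "U", "G", "G", "U"),
               ana_judg = c("G", "U", "U", "G"),
               ana_conf = c(80, 50, 50, 50))
  d <- agl_dataset(rbind(p_chance, p_above, p_excl),
                   n_test_trials_declared = 12L)
  cls <- classify_participants(split_by_fraction(d, 2 / 3), fit_meta = FALSE)
  expect_equal(cls$group[cls$participant_id == "chance"], "at_chance")
  expect_equal(cls$group[cls$participant_id == "above"], "above_chance")
  expect_equal(cls$group[cls$participant_id == "excl"], "excluded")
  expect_equal(cls$selection_d1[cls$participant_id == "chance"], 0)
  expect_gt(cls$selection_d1[cls$participant_id == "above"], 0)
})

test_that("quarter_summaries returns per-quarter d'1 with NA for empty cells", {
  # a perfectly regular participant: every quarter has the same 2x2 pattern
  tr <- make_trials("p1",
                    is_grammatical = rep(c(TRUE, FALSE, TRUE, FALSE), 4),
                    judgment = rep(c("G", "U", "U", "G"), 4),
                    confidence = rep(60, 16))
  q <- quarter_summaries(agl_dataset(tr, n_test_trials_declared = 16L))
  expect_equal(dim(q), c(1L, 4L))
  expect_true(all(q == q[1, 1]))
  expect_equal(unname(q[1, 1]), 0)  # one hit, one miss, one FA, one CR
  # remove discrimination failures in one quarter -> zero cell -> NA
  tr2 <- tr
  tr2$judgment[1:4] <- c("G", "U", "G", "U")  # all correct in Q1
  q2 <- quarter_summaries(agl_dataset(tr2, n_test_trials_declared = 16L))
  expect_true(is.na(q2[1, 1]))
  expect_false(anyNA(q2[1, 2:4]))
  tr3 <- make_trials("p1", c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                     rep(c("G", "U"), 3), rep(60, 6))
  expect_error(quarter_summaries(agl_dataset(tr3, n_test_trials_declared = 6L)),
               "divisible by 4")
})

test_that("declining generative sensitivity yields a decreasing quarter profile", {
  d <- generate_dataset(synth_config(n_participants = 800, n_trials = 64,
                                     d1_start = 0.6, d1_slope = -0.008,
                                     between_participant_sd = 0, seed = 11))
  q <- quarter_summaries(d)
  prof <- colMeans(q, na.rm = TRUE)
  expect_true(all(diff(prof) < 0))
})

test_that("same-trials selection regresses toward the mean; split selection does not", {
  # null cohorts: every participant's true d'1 is exactly 0
  n_cohorts <- 100
  biased <- split_mean <- numeric(0)
  for (k in 1:n_cohorts) {
    d <- generate_dataset(synth_config(n_participants = 60, n_trials = 64,
                                       d1_start = 0, d1_slope = 0,
                                       between_participant_sd = 0,
                                       seed = 90000 + k))
    # (a) select on ALL trials and re-analyze the SAME trials
    s_all <- participant_summaries(d, fit_meta = FALSE)
    sel <- s_all$d1 <= 0 & !is.na(s_all$d1)
    biased <- c(biased, s_all$d1[sel])
    # (b) select on the first 75%, analyze the last 25%
    split <- split_by_fraction(d, 0.75)
    sel_s <- participant_summaries(split$selection_trials, fit_meta = FALSE)
    ana_s <- participant_summaries(split$analysis_trials, fit_meta = FALSE)
    at <- sel_s$participant_id[!is.na(sel_s$d1) & sel_s$d1 <= 0]
    v <- ana_s$d1[match(at, ana_s$participant_id)]
    split_mean <- c(split_mean, v[!is.na(v)])
  }
  expect_lt(one_sample_t(biased)$p_value, 1e-10)
  expect_lt(mean(biased), -0.1)
  se <- sd(split_mean) / sqrt(length(split_mean))
  expect_lt(abs(mean(split_mean)), 2 * se)
})
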