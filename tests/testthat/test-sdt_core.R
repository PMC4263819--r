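test_that("tabulate_trials produces consistent Type I and Type II tables", {
  tr <- make_trials("p1",
                    c(TRUE, TRUE, FALSE, FALSE),
                    c("G", "U", "U", "G"),
                    c(80, 50, 75, 50))
  tab <- tabulate_trials(tr)
  expect_equal(unname(tab$type1), c(1, 1, 1, 1))
  expect_equal(unname(tab$type2), c(2, 0, 0, 2))
  # Type II correct margin equals Type I correct margin
  expect_equal(tab$type2[["confident_correct"]] + tab$type2[["guess_correct"]],
               tab$type1[["hits"]] + tab$type1[["correct_rejections"]])
  # by-response split partitions the Type II table
  expect_equal(tab$by_response$grammatical + tab$by_response$ungrammatical,
               tab$type2)
  all_right <- make_trials("p1", c(TRUE, FALSE), c("G", "U"), c(90, 90))
  tab2 <- tabulate_trials(all_right)
  expect_equal(unname(tab2$type1), c(1, 0, 0, 1))
  expect_equal(unname(tab2$type2), c(2, 0, 0, 0))
  expect_error(tabulate_trials(tr[0, ]), "empty")
})

test_that("dprime1 matches the inverse-normal oracle on canonical tables", {
  est <- dprime1(c(hits = 15, misses = 5, false_alarms = 5,
                   correct_rejections = 15))
  expect_true(est$computable)
  expect_equal(est$d1, 1.348980, tolerance = 1e-6)
  expect_equal(est$criterion_c, 0, tolerance = 1e-12)
  # label-swap antisymmetry
  est2 <- dprime1(c(hits = 5, misses = 15, false_alarms = 15,
                    correct_rejections = 5))
  expect_equal(est2$d1, -1.348980, tolerance = 1e-6)
  # hit rate == false-alarm rate
  est3 <- dprime1(c(hits = 8, misses = 8, false_alarms = 4,
                    correct_rejections = 4))
  expect_equal(est3$d1, 0)
})

test_that("zero cells flag non-computability; log-linear flag smooths", {
  counts <- c(hits = 10, misses = 0, false_alarms = 3,
              correct_rejections = 7)
  est <- dprime1(counts)
  expect_false(est$computable)
  expect_true(is.na(est$d1))
  est_c <- dprime1(counts, correction = "loglinear")
  expect_true(est_c$computable)
  expect_true(is.finite(est_c$d1))
  t2 <- c(confident_correct = 5, guess_correct = 0,
          confident_incorrect = 2, guess_incorrect = 3)
  expect_false(dprime2(t2)$computable)
  expect_true(is.finite(dprime2(t2, correction = "loglinear")$d2))
})

test_that("dprime2 and ca_slope match direct arithmetic on fixed tables", {
  t2 <- c(confident_correct = 12, guess_correct = 4,
          confident_incorrect = 6, guess_incorrect = 10)
  expect_equal(dprime2(t2)$d2, 0.993129, tolerance = 1e-6)
  expect_equal(ca_slope(t2)$ca_slope, 12 / 18 - 4 / 14, tolerance = 1e-12)
  # equal confidence rates in both accuracy classes
  eq <- c(confident_correct = 6, guess_correct = 6,
          confident_incorrect = 3, guess_incorrect = 3)
  expect_equal(dprime2(eq)$d2, 0)
  expect_equal(ca_slope(eq)$ca_slope, 0)
  # swap correct/incorrect: d2 negates
  sw <- c(confident_correct = 6, guess_correct = 10,
          confident_incorrect = 12, guess_incorrect = 4)
  expect_equal(dprime2(sw)$d2, -dprime2(t2)$d2)
  # bound attained
  ext <- c(confident_correct = 7, guess_correct = 0,
           confident_incorrect = 0, guess_incorrect = 5)
  expect_equal(ca_slope(ext)$ca_slope, 1)
})

test_that("d' estimators agree with the root-finding oracle to 1e-10", {
  set.seed(101)
  for (i in 1:250) {
    n <- sample(5:40, 4, replace = TRUE)
    d1 <- dprime1(c(hits = n[1], misses = n[2], false_alarms = n[3],
                    correct_rejections = n[4]))
    expect_lt(abs(d1$d1 - oracle_d1(n[1], n[2], n[3], n[4])), 1e-10)
    d2 <- dprime2(c(confident_correct = n[1], guess_correct = n[2],
                    confident_incorrect = n[3], guess_incorrect = n[4]))
    expect_lt(abs(d2$d2 - oracle_d2(n[1], n[2], n[3], n[4])), 1e-10)
  }
})

test_that("d'1 is invariant under joint label swap and antisymmetric under judgment swap", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(1:30, 4, replace = TRUE)
    base <- dprime1(c(hits = n[1], misses = n[2], false_alarms = n[3],
                      correct_rejections = n[4]))$d1
    # swapping judgment labels alone: hits<->misses, fa<->cr
    judg <- dprime1(c(hits = n[2], misses = n[1], false_alarms = n[4],
                      correct_rejections = n[3]))$d1
    # swapping stimulus and judgment labels together: (h,m,fa,cr)->(cr,fa,m,h)
    both <- dprime1(c(hits = n[4], misses = n[3], false_alarms = n[2],
                      correct_rejections = n[1]))$d1
    expect_equal(judg, -base, tolerance = 1e-12)
    expect_equal(both, base, tolerance = 1e-12)
  }
})

test_that("ca_slope stays within [-1, 1] on random tables", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(0:20, 4, replace = TRUE)
    t2 <- c(confident_correct = n[1], guess_correct = n[2],
            confident_incorrect = n[3], guess_incorrect = n[4])
    s <- ca_slope(t2)
    if (s$computable) {
      expect_gte(s$ca_slope, -1)
      expect_lte(s$ca_slope, 1)
    }
  }
})

test_that("participant_summaries agrees with per-participant tabulation", {
  d <- generate_dataset(synth_config(n_participants = 6, n_trials = 32,
                                     d1_start = 1, d1_slope = 0, seed = 5))
  s <- participant_summaries(d, fit_meta = FALSE)
  expect_equal(nrow(s), 6L)
  for (pid in s$participant_id) {
    tab <- tabulate_trials(d[d$participant_id == pid, ])
    est <- dprime1(tab$type1)
    row <- s[s$participant_id == pid, ]
    if (est$computable) {
      expect_equal(row$d1, est$d1)
      expect_equal(row$c, est$criterion_c)
    } else {
      expect_true(is.na(row$d1))
    }
    expect_equal(row$n_trials, 32L)
  }
})

test_that("per-participant meta-d' fits run and track d'1 for hierarchical observers", {
  d <- generate_dataset(synth_config(n_participants = 5, n_trials = 2000,
                                     d1_start = 1.2, d1_slope = 0,
                                     between_participant_sd = 0, seed = 17))
  s <- participant_summaries(d, fit_meta = TRUE)
  ok <- !is.na(s$meta_d)
  expect_gte(sum(ok), 4L)
  # confidence uses the judgment signal itself, so group-level meta-d'
  # tracks d'1 (per-participant fits carry larger sampling noise)
  expect_lt(abs(mean(s$meta_d[ok]) - mean(s$d1[ok])), 0.25)
})
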