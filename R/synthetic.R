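#' Configuration for the synthetic AGL data generator
#'
#' The generator emulates the statistical structure of a dual-grammar AGL
#' test phase: each participant judges `n_trials` strings (exactly half
#' grammatical, in randomized order) with a first-order sensitivity that may
#' decline linearly across the phase, and reports binarizable confidence.
#' Two confidence mechanisms are available:
#'
#' * `hierarchical` -- classical SDT: confidence derives from the same
#'   signal as the judgment; a trial is a guess when the signal lands within
#'   `confidence_width` of the decision criterion. This observer cannot show
#'   metacognition without first-order accuracy.
#' * `error_monitoring` -- confidence comes from an independent channel:
#'   any trial is reported as a guess with probability `base_guess_rate`,
#'   and an incorrect judgment is additionally flagged (and reported as a
#'   guess) with probability `error_detect_rate`. With `d1_start = 0` this
#'   produces below-chance accuracy on guesses with at-chance accuracy on
#'   confident trials -- the blind-insight signature.
#'
#' @param n_participants number of participants.
#' @param n_trials test trials per participant (even; default 64).
#' @param d1_start generating d'1 on trial 1 (population mean).
#' @param d1_slope per-trial change in d'1 (default -0.008, a decline of
#'   about 0.5 across a 64-trial phase, the magnitude typical of
#'   dual-grammar designs).
#' @param criterion_c decision criterion on the signal axis (default 0).
#' @param confidence_width half-width of the guess band around the
#'   criterion (hierarchical mode; default 0.5).
#' @param mode `"hierarchical"` or `"error_monitoring"`.
#' @param error_detect_rate probability an incorrect judgment is flagged by
#'   the error monitor (error_monitoring mode; default 0.3).
#' @param base_guess_rate baseline probability of reporting a guess absent
#'   an error flag (error_monitoring mode; default 0.3).
#' @param between_participant_sd SD of participant-level variation in
#'   `d1_start` (default 0.3).
#' @param seed integer seed; identical configs give bit-identical datasets.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_participants = 100L, n_trials = 64L,
                         d1_start = 0.5, d1_slope = -0.008,
                         criterion_c = 0, confidence_width = 0.5,
                         mode = c("hierarchical", "error_monitoring"),
                         error_detect_rate = 0.3, base_guess_rate = 0.3,
                         between_participant_sd = 0.3, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_participants >= 1, n_trials >= 2, n_trials %% 2 == 0,
            confidence_width >= 0,
            error_detect_rate >= 0, error_detect_rate <= 1,
            base_guess_rate >= 0, base_guess_rate <= 1,
            between_participant_sd >= 0)
  structure(list(n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials), d1_start = d1_start,
                 d1_slope = d1_slope, criterion_c = criterion_c,
                 confidence_width = confidence_width, mode = mode,
                 error_detect_rate = error_detect_rate,
                 base_guess_rate = base_guess_rate,
                 between_participant_sd = between_participant_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic AGL dataset
#'
#' Draws trial-level data under the generative model described in
#' [synth_config()]. Per participant p and trial t the generating
#' sensitivity is `delta(t) = d1_start_p + d1_slope * (t - 1)` with
#' `d1_start_p ~ Normal(d1_start, between_participant_sd^2)`; the signal is
#' Normal(0, 1) for ungrammatical strings and Normal(delta(t), 1) for
#' grammatical ones; the judgment is grammatical when the signal exceeds
#' `criterion_c`. Guess trials carry confidence 50; confident trials a
#' uniform integer in 51..100 (all analyses binarize, so no graded-
#' confidence realism is attempted). In hierarchical mode a familiarity
#' rating in 0..100 is emitted as a monotone transform of the signal plus
#' noise; in error-monitoring mode the column is absent (NA). Attribution
#' labels are uniform noise.
#'
#' @param config a [synth_config()].
#' @return an `agl_dataset`.
#' @export
generate_dataset <- function(config) {
  set.seed(config$seed)
  np <- config$n_participants
  nt <- config$n_trials
  n <- np * nt
  pid <- rep(sprintf("P%04d", seq_len(np)), each = nt)
  trial <- rep(seq_len(nt), times = np)

  # random half of trial positions grammatical, per participant
  gram <- as.vector(vapply(seq_len(np), function(i) {
    g <- logical(nt); g[sample.int(nt, nt %/% 2L)] <- TRUE; g
  }, logical(nt)))

  d1p <- rep(stats::rnorm(np, config$d1_start, config$between_participant_sd),
             each = nt)
  delta <- d1p + config$d1_slope * (trial - 1)
  x <- stats::rnorm(n, mean = ifelse(gram, delta, 0), sd = 1)
  judged_g <- x > config$criterion_c

  if (config$mode == "hierarchical") {
    guess <- abs(x - config$criterion_c) <= config$confidence_width
    familiarity <- as.integer(round(100 * stats::pnorm(
      (x + stats::rnorm(n)) / sqrt(2))))
  } else {
    correct <- judged_g == gram
    guess <- stats::runif(n) < config$base_guess_rate
    guess <- guess | (!correct & stats::runif(n) < config$error_detect_rate)
    familiarity <- NA_integer_
  }
  confidence <- ifelse(guess, 50L, sample(51:100, n, replace = TRUE))
  attribution <- sample(ATTRIBUTION_LEVELS, n, replace = TRUE)

  agl_dataset(data.frame(participant_id = pid, trial_index = trial,
                         is_grammatical = gram,
                         judgment = ifelse(judged_g, "G", "U"),
                         confidence = as.integer(confidence),
                         familiarity = familiarity,
                         attribution = attribution,
                         stringsAsFactors = FALSE),
              n_test_trials_declared = nt)
}

#' Analytic Type I / Type II cell probabilities for a stationary generator
#'
#' Exact per-trial cell probabilities implied by a [synth_config()] with no
#' sensitivity trend and no between-participant variation, used as an
#' independent oracle for the generator. Hierarchical mode evaluates the
#' Gaussian integrals directly; error-monitoring mode combines the Type I
#' probabilities with the correctness-conditional guess probabilities
#' (`P(guess | correct) = base_guess_rate`;
#' `P(guess | incorrect) = base_guess_rate + (1 - base_guess_rate) *
#' error_detect_rate`).
#'
#' @param config a [synth_config()] with `d1_slope = 0` and
#'   `between_participant_sd = 0`.
#' @return list with probability vectors `type1` (hits, misses,
#'   false_alarms, correct_rejections; each cell joint with its stimulus
#'   class at prior 0.5) and `type2` (confident_correct, guess_correct,
#'   confident_incorrect, guess_incorrect). Both sum to 1.
#' @export
expected_cells <- function(config) {
  if (config$d1_slope != 0 || config$between_participant_sd != 0) {
    stop("expected_cells requires a stationary config (d1_slope = 0, between_participant_sd = 0)")
  }
  d <- config$d1_start
  cc <- config$criterion_c
  type1 <- c(hits = 0.5 * stats::pnorm(cc - d, lower.tail = FALSE),
             misses = 0.5 * stats::pnorm(cc - d),
             false_alarms = 0.5 * stats::pnorm(cc, lower.tail = FALSE),
             correct_rejections = 0.5 * stats::pnorm(cc))
  if (config$mode == "hierarchical") {
    w <- config$confidence_width
    # correct & guess: grammatical in (c, c+w], ungrammatical in (c-w, c]
    gc <- 0.5 * (stats::pnorm(cc + w - d) - stats::pnorm(cc - d)) +
      0.5 * (stats::pnorm(cc) - stats::pnorm(cc - w))
    # incorrect & guess: grammatical in (c-w, c], ungrammatical in (c, c+w]
    gi <- 0.5 * (stats::pnorm(cc - d) - stats::pnorm(cc - w - d)) +
      0.5 * (stats::pnorm(cc + w) - stats::pnorm(cc))
    p_correct <- type1[["hits"]] + type1[["correct_rejections"]]
    type2 <- c(confident_correct = p_correct - gc, guess_correct = gc,
               confident_incorrect = 1 - p_correct - gi, guess_incorrect = gi)
  } else {
    beta <- config$base_guess_rate
    gamma <- config$error_detect_rate
    p_correct <- type1[["hits"]] + type1[["correct_rejections"]]
    p_guess_incorrect <- beta + (1 - beta) * gamma
    type2 <- c(confident_correct = p_correct * (1 - beta),
               guess_correct = p_correct * beta,
               confident_incorrect = (1 - p_correct) * (1 - p_guess_incorrect),
               guess_incorrect = (1 - p_correct) * p_guess_incorrect)
  }
  list(type1 = type1, type2 = type2)
}
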