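#' Tabulate Type I and Type II contingency tables for one participant
#'
#' Grammatical is treated as the signal-present class: a hit is a grammatical
#' string judged grammatical, a false alarm an ungrammatical string judged
#' grammatical. The Type II table crosses accuracy of the grammaticality
#' judgment with binarized confidence (guess = rating of exactly 50).
#' `by_response` splits the Type II table by the Type I response, as needed
#' by the meta-d' fit.
#'
#' @param trials data frame of one participant's trials with columns
#'   `is_grammatical`, `judgment`, `confidence`.
#' @return list with components `type1` (hits, misses, false_alarms,
#'   correct_rejections), `type2` (confident_correct, guess_correct,
#'   confident_incorrect, guess_incorrect) and `by_response` (the same four
#'   Type II cells within `grammatical` and `ungrammatical` responses).
#' @export
tabulate_trials <- function(trials) {
  if (nrow(trials) == 0L) stop("cannot tabulate an empty trial list")
  gram <- trials$is_grammatical
  judged_g <- trials$judgment == "G"
  guess <- binarize_confidence(trials$confidence) == "guess"
  correct <- judged_g == gram

  type1 <- c(hits = sum(gram & judged_g),
             misses = sum(gram & !judged_g),
             false_alarms = sum(!gram & judged_g),
             correct_rejections = sum(!gram & !judged_g))
  type2 <- c(confident_correct = sum(correct & !guess),
             guess_correct = sum(correct & guess),
             confident_incorrect = sum(!correct & !guess),
             guess_incorrect = sum(!correct & guess))
  split_cells <- function(sel) {
    c(confident_correct = sum(sel & correct & !guess),
      guess_correct = sum(sel & correct & guess),
      confident_incorrect = sum(sel & !correct & !guess),
      guess_incorrect = sum(sel & !correct & guess))
  }
  list(type1 = type1, type2 = type2,
       by_response = list(grammatical = split_cells(judged_g),
                          ungrammatical = split_cells(!judged_g)))
}

# Vectorized per-participant cell counts for a whole dataset.
# Returns a matrix with one row per participant (rownames = ids) and 16
# columns: the 4 Type I cells, 4 Type II cells, and the 4 Type II cells
# within each Type I response class.
participant_cells <- function(trials) {
  gram <- trials$is_grammatical
  judged_g <- trials$judgment == "G"
  guess <- trials$confidence == 50L
  correct <- judged_g == gram
  ind <- cbind(
    hits = gram & judged_g, misses = gram & !judged_g,
    false_alarms = !gram & judged_g, correct_rejections = !gram & !judged_g,
    confident_correct = correct & !guess, guess_correct = correct & guess,
    confident_incorrect = !correct & !guess, guess_incorrect = !correct & guess,
    g_confident_correct = judged_g & correct & !guess,
    g_guess_correct = judged_g & correct & guess,
    g_confident_incorrect = judged_g & !correct & !guess,
    g_guess_incorrect = judged_g & !correct & guess,
    u_confident_correct = !judged_g & correct & !guess,
    u_guess_correct = !judged_g & correct & guess,
    u_confident_incorrect = !judged_g & !correct & !guess,
    u_guess_incorrect = !judged_g & !correct & guess)
  rowsum(ind + 0L, trials$participant_id)
}

apply_correction <- function(counts, correction) {
  if (correction == "loglinear") counts + 0.5 else counts
}

# strip the g_/u_ response prefix from a participant_cells() slice so the
# four Type II cell names match the tabulate_trials() convention
type2_cells <- function(x) {
  stats::setNames(x, c("confident_correct", "guess_correct",
                       "confident_incorrect", "guess_incorrect"))
}

#' Type I sensitivity (d'1) and decision criterion
#'
#' `d'1 = z(hit rate) - z(false-alarm rate)`; the criterion is
#' `c = -(z(hit rate) + z(false-alarm rate)) / 2`. By default no correction
#' is applied to zero cells: a table with any empty Type I cell is flagged
#' `computable = FALSE` (and such participants are excluded downstream,
#' rather than estimated from corrected counts). A log-linear +0.5
#' correction is available behind `correction = "loglinear"` but is never
#' the default.
#'
#' @param counts Type I table as produced by [tabulate_trials()] (`$type1`),
#'   or any numeric vector with named elements `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`.
#' @param correction `"none"` (default) or `"loglinear"`.
#' @return list with `d1`, `criterion_c`, `computable`.
#' @examples
#' dprime1(c(hits = 15, misses = 5, false_alarms = 5, correct_rejections = 15))
#' @export
dprime1 <- function(counts, correction = c("none", "loglinear")) {
  correction <- match.arg(correction)
  counts <- counts[c("hits", "misses", "false_alarms", "correct_rejections")]
  stopifnot(!anyNA(counts), all(counts >= 0))
  if (any(counts == 0) && correction == "none") {
    return(list(d1 = NA_real_, criterion_c = NA_real_, computable = FALSE))
  }
  counts <- apply_correction(counts, correction)
  hr <- counts[["hits"]] / (counts[["hits"]] + counts[["misses"]])
  far <- counts[["false_alarms"]] /
    (counts[["false_alarms"]] + counts[["correct_rejections"]])
  list(d1 = stats::qnorm(hr) - stats::qnorm(far),
       criterion_c = -(stats::qnorm(hr) + stats::qnorm(far)) / 2,
       computable = TRUE)
}

#' Type II sensitivity (d'2)
#'
#' Metacognitive sensitivity as `z(P(confident | correct)) -
#' z(P(confident | incorrect))`: how well binarized confidence discriminates
#' correct from incorrect first-order judgments.
#'
#' @param counts Type II table (`$type2` of [tabulate_trials()]), elements
#'   `confident_correct`, `guess_correct`, `confident_incorrect`,
#'   `guess_incorrect`.
#' @inheritParams dprime1
#' @return list with `d2`, `computable`.
#' @export
dprime2 <- function(counts, correction = c("none", "loglinear")) {
  correction <- match.arg(correction)
  counts <- counts[c("confident_correct", "guess_correct",
                     "confident_incorrect", "guess_incorrect")]
  stopifnot(!anyNA(counts), all(counts >= 0))
  if (any(counts == 0) && correction == "none") {
    return(list(d2 = NA_real_, computable = FALSE))
  }
  counts <- apply_correction(counts, correction)
  p_conf_correct <- counts[["confident_correct"]] /
    (counts[["confident_correct"]] + counts[["guess_correct"]])
  p_conf_incorrect <- counts[["confident_incorrect"]] /
    (counts[["confident_incorrect"]] + counts[["guess_incorrect"]])
  list(d2 = stats::qnorm(p_conf_correct) - stats::qnorm(p_conf_incorrect),
       computable = TRUE)
}

#' Confidence-accuracy slope
#'
#' The difference in proportion correct between confident trials and guess
#' trials, `P(correct | confident) - P(correct | guess)`, in proportion
#' units (multiply by 100 for percentage points). Bounded in \[-1, 1\].
#'
#' @inheritParams dprime2
#' @return list with `ca_slope`, `computable`. `computable` is `FALSE` when
#'   either confidence margin is empty.
#' @export
ca_slope <- function(counts) {
  counts <- counts[c("confident_correct", "guess_correct",
                     "confident_incorrect", "guess_incorrect")]
  stopifnot(!anyNA(counts), all(counts >= 0))
  n_conf <- counts[["confident_correct"]] + counts[["confident_incorrect"]]
  n_guess <- counts[["guess_correct"]] + counts[["guess_incorrect"]]
  if (n_conf == 0 || n_guess == 0) {
    return(list(ca_slope = NA_real_, computable = FALSE))
  }
  list(ca_slope = counts[["confident_correct"]] / n_conf -
         counts[["guess_correct"]] / n_guess,
       computable = TRUE)
}

#' Per-participant sensitivity and metacognition summary
#'
#' Computes d'1, criterion, d'2, meta-d' and the confidence-accuracy slope
#' for every participant in a dataset. Estimates that require an empty cell
#' are `NA` with the corresponding computable flag `FALSE`.
#'
#' @param dataset an `agl_dataset` (or any data frame with the trial
#'   columns).
#' @param fit_meta whether to fit meta-d' per participant (slower).
#' @return data frame with one row per participant: `participant_id`,
#'   `n_trials`, `d1`, `c`, `d2`, `meta_d`, `ca_slope`,
#'   `computable_d1`, `computable_d2`.
#' @export
participant_summaries <- function(dataset, fit_meta = TRUE) {
  cells <- participant_cells(dataset)
  s <- summarize_cells(cells)
  meta <- rep(NA_real_, nrow(cells))
  if (fit_meta) {
    for (i in seq_len(nrow(cells))) {
      if (s$computable_d1[i] && s$computable_d2[i]) {
        meta[i] <- tryCatch(
          fit_meta_d(cells[i, 1:4],
                     list(grammatical = type2_cells(cells[i, 9:12]),
                          ungrammatical = type2_cells(cells[i, 13:16]))),
          error = function(e) NA_real_)
      }
    }
  }
  data.frame(participant_id = rownames(cells),
             n_trials = as.integer(rowSums(cells[, 1:4, drop = FALSE])),
             d1 = s$d1, c = s$c, d2 = s$d2, meta_d = meta,
             ca_slope = s$ca_slope,
             computable_d1 = s$computable_d1,
             computable_d2 = s$computable_d2,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized index computation over a participant_cells() matrix.
summarize_cells <- function(cells) {
  t1 <- cells[, c("hits", "misses", "false_alarms", "correct_rejections"),
              drop = FALSE]
  t2 <- cells[, c("confident_correct", "guess_correct",
                  "confident_incorrect", "guess_incorrect"), drop = FALSE]
  comp1 <- rowSums(t1 == 0) == 0
  comp2 <- rowSums(t2 == 0) == 0
  hr <- t1[, 1] / (t1[, 1] + t1[, 2])
  far <- t1[, 3] / (t1[, 3] + t1[, 4])
  d1 <- ifelse(comp1, stats::qnorm(hr) - stats::qnorm(far), NA_real_)
  cc <- ifelse(comp1, -(stats::qnorm(hr) + stats::qnorm(far)) / 2, NA_real_)
  pcc <- t2[, 1] / (t2[, 1] + t2[, 2])
  pci <- t2[, 3] / (t2[, 3] + t2[, 4])
  d2 <- ifelse(comp2, stats::qnorm(pcc) - stats::qnorm(pci), NA_real_)
  n_conf <- t2[, 1] + t2[, 3]
  n_guess <- t2[, 2] + t2[, 4]
  slope <- ifelse(n_conf > 0 & n_guess > 0,
                  t2[, 1] / n_conf - t2[, 2] / n_guess, NA_real_)
  list(d1 = unname(d1), c = unname(cc), d2 = unname(d2),
       ca_slope = unname(slope),
       computable_d1 = unname(comp1), computable_d2 = unname(comp2))
}
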