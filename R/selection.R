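#' Split each participant's trials into early (selection) and late
#' (analysis) subsets
#'
#' Selecting participants on a noisy score and re-analyzing the same trials
#' regresses toward the mean; splitting the test phase so that selection
#' uses only early trials and analysis only later trials removes that bias.
#' The first `floor(fraction * T)` trials by `trial_index` form the
#' selection subset, the remainder the analysis subset.
#'
#' @param dataset an `agl_dataset`.
#' @param fraction fraction of each participant's trials used for selection,
#'   strictly between 0 and 1 (default 0.75). Must leave both partitions
#'   nonempty for every participant.
#' @return list of class `agl_split` with data frames `selection_trials` and
#'   `analysis_trials` plus `split_fraction`.
#' @export
split_by_fraction <- function(dataset, fraction = 0.75) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1")
  }
  n_per <- stats::ave(dataset$trial_index, dataset$participant_id,
                      FUN = length)
  cut <- floor(fraction * n_per)
  if (any(cut < 1) || any(cut >= n_per)) {
    stop("fraction ", fraction, " yields an empty partition for at least one participant")
  }
  sel <- dataset$trial_index <= cut
  structure(list(selection_trials = dataset[sel, , drop = FALSE],
                 analysis_trials = dataset[!sel, , drop = FALSE],
                 split_fraction = fraction),
            class = "agl_split")
}

#' Classify participants as at-chance or above-chance from selection trials
#'
#' Each participant is labeled by the sign of d'1 on the selection subset:
#' `at_chance` when selection d'1 <= 0, `above_chance` when > 0. Group
#' labels are assigned first; a participant is then `excluded` when any
#' required cell count is zero -- either the selection-subset Type I table
#' (the label itself would be undefined) or the analysis-subset Type I or
#' Type II table (the analysis indices would be undefined). No cell
#' correction is applied: exclusion, not smoothing, is the default policy.
#'
#' @param split an `agl_split` from [split_by_fraction()].
#' @param fit_meta fit meta-d' on the analysis subset for included
#'   participants (default `TRUE`).
#' @return data frame with one row per participant: `participant_id`,
#'   `selection_d1`, `group` (`at_chance` / `above_chance` / `excluded`),
#'   analysis-subset `analysis_d1`, `analysis_c`, `analysis_d2`,
#'   `analysis_meta_d`, `analysis_ca_slope`, and the trial counts.
#' @export
classify_participants <- function(split, fit_meta = TRUE) {
  sel_cells <- participant_cells(split$selection_trials)
  ana_cells <- participant_cells(split$analysis_trials)
  ids <- rownames(sel_cells)
  stopifnot(identical(ids, rownames(ana_cells)))
  sel <- summarize_cells(sel_cells)
  ana <- summarize_cells(ana_cells)

  group <- ifelse(sel$d1 <= 0, "at_chance", "above_chance")
  group[!sel$computable_d1 | !ana$computable_d1 | !ana$computable_d2] <- "excluded"

  meta <- rep(NA_real_, length(ids))
  if (fit_meta) {
    for (i in which(group != "excluded")) {
      meta[i] <- tryCatch(
        fit_meta_d(ana_cells[i, 1:4],
                   list(grammatical = type2_cells(ana_cells[i, 9:12]),
                        ungrammatical = type2_cells(ana_cells[i, 13:16]))),
        error = function(e) NA_real_)
    }
  }
  data.frame(participant_id = ids,
             n_selection = as.integer(rowSums(sel_cells[, 1:4, drop = FALSE])),
             n_analysis = as.integer(rowSums(ana_cells[, 1:4, drop = FALSE])),
             selection_d1 = sel$d1,
             group = group,
             analysis_d1 = ana$d1,
             analysis_c = ana$c,
             analysis_d2 = ana$d2,
             analysis_meta_d = meta,
             analysis_ca_slope = ana$ca_slope,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quarter-wise d'1 profiles
#'
#' Splits each participant's test phase into four consecutive quarters by
#' `trial_index` and computes d'1 within each. Quarters with an empty Type I
#' cell are `NA` (flagged non-computable); downstream trend tests drop such
#' participants listwise.
#'
#' @param dataset an `agl_dataset` whose per-participant trial counts are
#'   divisible by 4.
#' @return numeric matrix, one row per participant (rownames = ids), columns
#'   `Q1`..`Q4`.
#' @export
quarter_summaries <- function(dataset) {
  n_per <- stats::ave(dataset$trial_index, dataset$participant_id,
                      FUN = length)
  if (any(n_per %% 4L != 0L)) {
    stop("per-participant trial counts must be divisible by 4")
  }
  quarter <- ceiling(dataset$trial_index / (n_per / 4L))
  ids <- sort(unique(dataset$participant_id))
  out <- matrix(NA_real_, nrow = length(ids), ncol = 4L,
                dimnames = list(ids, paste0("Q", 1:4)))
  for (q in 1:4) {
    sub <- dataset[quarter == q, , drop = FALSE]
    cells <- participant_cells(sub)
    s <- summarize_cells(cells)
    out[rownames(cells), q] <- s$d1
  }
  out
}

#' Write a participant classification table to CSV
#'
#' @param classification data frame from [classify_participants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  utils::write.csv(classification, path, row.names = FALSE)
  invisible(path)
}
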