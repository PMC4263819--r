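#' Run the full blind-insight analysis on a trial-level dataset
#'
#' Orchestrates the whole analytical sequence: quarter-wise d'1 profiles and
#' the linear trend test; the early/late trial split at `split_fraction`;
#' participant classification (at-chance vs. above-chance on selection
#' trials, zero-cell exclusion on both subsets); listwise group means of the
#' analysis-subset indices; and the inferential battery -- per-group d'2
#' (and meta-d', confidence-accuracy slope) against zero, the at-chance
#' group's d'1 against zero with a half-normal Bayes factor, between-group
#' comparisons, and the 2 x 2 judgment-by-confidence within-subject ANOVA on
#' proportion correct in the at-chance group.
#'
#' All group means are listwise over participants with computable d'1 and
#' d'2 on the analysis subset; meta-d' means are over the (possibly smaller)
#' subset where the response-conditional fit is defined, with the n
#' reported.
#'
#' @param dataset an `agl_dataset`, or a path to a trial CSV readable by
#'   [read_trials()].
#' @param split_fraction fraction of early trials used for selection
#'   (default 0.75).
#' @param bf_alt_sd scale of the half-normal alternative for the Bayes
#'   factor on the at-chance group's d'1. Default `NULL` uses the
#'   above-chance group's mean selection-subset d'1 -- the observed size of
#'   a real first-order effect, hence a principled scale for "if there were
#'   an effect, how big would it plausibly be".
#' @param fit_meta fit per-participant meta-d' (default `TRUE`).
#' @return a `bi_report` list: `trend`, `classification`, `groups`, `tests`,
#'   `anova`, `provenance`.
#' @export
run_analysis <- function(dataset, split_fraction = 0.75, bf_alt_sd = NULL,
                         fit_meta = TRUE) {
  input_path <- NULL
  if (is.character(dataset)) {
    input_path <- dataset
    dataset <- read_trials(dataset)
  }
  if (!inherits(dataset, "agl_dataset")) dataset <- agl_dataset(dataset)
  quarters <- quarter_summaries(dataset)
  trend <- linear_trend(quarters)
  split <- split_by_fraction(dataset, split_fraction)
  cls <- classify_participants(split, fit_meta = fit_meta)

  group_stats <- function(g) {
    sub <- cls[cls$group == g, , drop = FALSE]
    meta <- sub$analysis_meta_d[!is.na(sub$analysis_meta_d)]
    list(n = nrow(sub),
         d1 = mean_se(sub$analysis_d1), d2 = mean_se(sub$analysis_d2),
         meta_d = c(mean_se(meta), n = length(meta)),
         ca_slope = mean_se(sub$analysis_ca_slope))
  }
  groups <- list(above_chance = group_stats("above_chance"),
                 at_chance = group_stats("at_chance"),
                 n_excluded = sum(cls$group == "excluded"))

  at <- cls[cls$group == "at_chance", , drop = FALSE]
  ab <- cls[cls$group == "above_chance", , drop = FALSE]
  tests <- list()
  if (nrow(at) >= 2L) {
    tests$at_chance_d2_vs_0 <- one_sample_t(at$analysis_d2)
    tests$at_chance_d1_vs_0 <- one_sample_t(at$analysis_d1)
    if (sum(!is.na(at$analysis_meta_d)) >= 2L) {
      tests$at_chance_meta_d_vs_0 <- one_sample_t(at$analysis_meta_d)
    }
    tests$at_chance_slope_vs_0 <- one_sample_t(at$analysis_ca_slope)
    alt_sd <- bf_alt_sd
    if (is.null(alt_sd) && nrow(ab) >= 1L) alt_sd <- mean(ab$selection_d1)
    if (!is.null(alt_sd) && is.finite(alt_sd) && alt_sd > 0) {
      tests$at_chance_d1_bf <- list(
        bayes_factor = bf_halfnormal(mean(at$analysis_d1),
                                     stats::sd(at$analysis_d1) / sqrt(nrow(at)),
                                     alt_sd),
        observed_mean = mean(at$analysis_d1),
        observed_se = stats::sd(at$analysis_d1) / sqrt(nrow(at)),
        alt_sd = alt_sd)
    }
  } else {
    warning("no (or a degenerate) at-chance group after exclusion; test battery restricted")
  }
  if (nrow(ab) >= 2L) {
    tests$above_chance_d2_vs_0 <- one_sample_t(ab$analysis_d2)
  }
  if (nrow(at) >= 2L && nrow(ab) >= 2L) {
    tests$between_d2 <- two_sample_t_pooled(ab$analysis_d2, at$analysis_d2)
    if (sum(!is.na(ab$analysis_meta_d)) >= 2L &&
        sum(!is.na(at$analysis_meta_d)) >= 2L) {
      tests$between_meta_d <- two_sample_t_pooled(ab$analysis_meta_d,
                                                  at$analysis_meta_d)
    }
    tests$between_slope <- two_sample_t_pooled(ab$analysis_ca_slope,
                                               at$analysis_ca_slope)
  }

  anova <- NULL
  if (nrow(at) >= 2L) {
    cellm <- judgment_confidence_cells(split$analysis_trials,
                                       at$participant_id)
    anova <- tryCatch(anova_2x2_within(cellm), error = function(e) NULL)
  }

  structure(list(trend = trend, quarter_means = colMeans(quarters, na.rm = TRUE),
                 classification = cls, groups = groups, tests = tests,
                 anova = anova,
                 provenance = list(
                   input = if (is.null(input_path)) "in-memory dataset" else input_path,
                   input_md5 = if (is.null(input_path)) NA_character_ else
                     unname(tools::md5sum(input_path)),
                   n_participants = length(unique(dataset$participant_id)),
                   n_trials_declared = attr(dataset, "n_test_trials_declared"),
                   split_fraction = split_fraction,
                   package_version = as.character(utils::packageVersion("blindinsight")))),
            class = "bi_report")
}

mean_se <- function(x) {
  x <- x[!is.na(x)]
  c(mean = if (length(x)) mean(x) else NA_real_,
    se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_)
}

# Proportion correct in the 2 x 2 judgment-by-confidence cells, one row per
# requested participant; a cell with no trials is NA (listwise deletion is
# left to anova_2x2_within, so the reported df reflects it).
judgment_confidence_cells <- function(trials, participant_ids) {
  trials <- trials[trials$participant_id %in% participant_ids, , drop = FALSE]
  judged_g <- trials$judgment == "G"
  guess <- trials$confidence == 50L
  correct <- judged_g == trials$is_grammatical
  ind <- cbind(g_conf = judged_g & !guess, g_guess = judged_g & guess,
               u_conf = !judged_g & !guess, u_guess = !judged_g & guess)
  n <- rowsum(ind + 0L, trials$participant_id)
  k <- rowsum(ind * correct, trials$participant_id)
  p <- ifelse(n > 0, k / n, NA_real_)
  out <- matrix(NA_real_, nrow = length(participant_ids), ncol = 4L,
                dimnames = list(participant_ids, colnames(ind)))
  out[rownames(n), ] <- p
  out
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (group tables, test battery, trend, provenance) and
#' `participants.csv` (the per-participant classification) under `dir`.
#'
#' @param report a `bi_report` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- report
  out$classification <- NULL
  jsonlite::write_json(strip_classes(out), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write_classification(report$classification,
                       file.path(dir, "participants.csv"))
  invisible(dir)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Run both parametric SDT simulations and write JSON reports
#'
#' Executes the unequal-variance null simulation and the criterion-jitter
#' simulation under their standard parameterizations (overridable), writing
#' `sim_unequal_variance.json` and `sim_jitter.json` (config echo, solved
#' criterion set, exceedance probability, grand mean and SE, exclusion
#' counts) under `dir`.
#'
#' @param dir output directory, or `NULL` to skip writing.
#' @param n_reps replicates per simulation (default 1000).
#' @param seed master seed.
#' @param which `"both"` (default), `"unequal_variance"` or `"jitter"`.
#' @param uv_config,jitter_config optional full [sim_config()] overrides.
#' @param reference_d2,reference_d1 empirical reference values for the
#'   exceedance probabilities.
#' @return named list of `sim_result` objects, invisibly when writing.
#' @export
run_sims <- function(dir = NULL, n_reps = 1000L, seed = 1L,
                     which = c("both", "unequal_variance", "jitter"),
                     uv_config = NULL, jitter_config = NULL,
                     reference_d2 = 0.23, reference_d1 = 0) {
  which <- match.arg(which)
  out <- list()
  if (which %in% c("both", "unequal_variance")) {
    cfg <- if (is.null(uv_config)) {
      sim_config(n_reps = n_reps, seed = seed)
    } else uv_config
    out$unequal_variance <- run_unequal_variance_sim(cfg, reference_d2)
  }
  if (which %in% c("both", "jitter")) {
    cfg <- if (is.null(jitter_config)) {
      sim_config(d1_true = 0.46, jitter_sd = 1.5, n_trials = 32L,
                 n_reps = n_reps, seed = seed)
    } else jitter_config
    out$jitter <- run_jitter_sim(cfg, reference_d1)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(unequal_variance = "sim_unequal_variance.json",
               jitter = "sim_jitter.json")
    for (nm in names(out)) {
      res <- out[[nm]]
      payload <- list(config = unclass(res$config),
                      criteria = res$criteria,
                      exceedance_p = res$exceedance_p,
                      grand_mean = res$grand_mean, grand_se = res$grand_se,
                      n_excluded_participants_total = res$n_excluded_participants_total,
                      n_replicates_redrawn = res$n_replicates_redrawn)
      jsonlite::write_json(payload, file.path(dir, files[[nm]]),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
    }
    return(invisible(out))
  }
  out
}

#' Read a plain-text key = value configuration file
#'
#' Minimal config format shared by the generator and the simulations: one
#' `key = value` pair per line, `#` comments, blank lines ignored. Values
#' are parsed as numeric where possible, otherwise kept as strings.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed config line: ", ln)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
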