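#' blindinsight: signal-detection analysis of metacognition without
#' first-order accuracy
#'
#' Trial-level analysis of artificial-grammar-learning (AGL) data with
#' confidence ratings: Type I / Type II signal-detection indices, meta-d',
#' a bias-robust early/late trial-split participant selection, the
#' associated inferential battery (including a half-normal Bayes factor),
#' and parametric Monte Carlo signal-detection simulations.
#'
#' @docType package
#' @name blindinsight-package
#' @keywords internal
"_PACKAGE"

ATTRIBUTION_LEVELS <- c("random", "intuition", "familiarity", "rules", "recollection")

#' Construct a validated AGL trial dataset
#'
#' An `agl_dataset` is a data frame with one row per test-phase trial and
#' columns `participant_id`, `trial_index`, `is_grammatical` (logical),
#' `judgment` (`"G"` or `"U"`), `confidence` (integer in \[50, 100\]), plus
#' optional `familiarity` (integer in \[0, 100\]) and `attribution`
#' (one of random/intuition/familiarity/rules/recollection). Rows are stored
#' ordered by participant and then by `trial_index`.
#'
#' The 50--100 confidence scale is the standard AGL elicitation: 50 means a
#' 50:50 chance of being right ("no confidence whatsoever"), 100 complete
#' certainty.
#'
#' @param trials data frame with at least the five mandatory columns.
#' @param n_test_trials_declared declared per-participant test-trial count
#'   (typically 60 or 64), or `NA` to take the modal observed count.
#' @param strict if `TRUE` (default) validation problems are errors; if
#'   `FALSE` offending rows are dropped with a warning and structural
#'   problems (unbalanced design, wrong trial count) only warn.
#' @return an `agl_dataset` (data frame subclass) with attribute
#'   `n_test_trials_declared`.
#' @seealso [read_trials()], [write_trials()], [generate_dataset()]
#' @export
agl_dataset <- function(trials, n_test_trials_declared = NA_integer_,
                        strict = TRUE) {
  required <- c("participant_id", "trial_index", "is_grammatical",
                "judgment", "confidence")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  trials$participant_id <- as.character(trials$participant_id)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$is_grammatical <- coerce_binary(trials$is_grammatical, "is_grammatical")
  trials$judgment <- coerce_judgment(trials$judgment)
  trials$confidence <- as.integer(trials$confidence)
  if (!"familiarity" %in% names(trials)) trials$familiarity <- NA_integer_
  trials$familiarity <- as.integer(trials$familiarity)
  if (!"attribution" %in% names(trials)) trials$attribution <- NA_character_
  trials$attribution <- as.character(trials$attribution)

  bad <- is.na(trials$confidence) | trials$confidence < 50L | trials$confidence > 100L
  if (any(bad)) {
    msg <- sprintf("%d row(s) with confidence outside [50, 100]", sum(bad))
    if (strict) stop(msg) else {
      warning(msg, "; rows dropped")
      trials <- trials[!bad, , drop = FALSE]
    }
  }
  bad_fam <- !is.na(trials$familiarity) &
    (trials$familiarity < 0L | trials$familiarity > 100L)
  if (any(bad_fam)) {
    msg <- sprintf("%d row(s) with familiarity outside [0, 100]", sum(bad_fam))
    if (strict) stop(msg) else {
      warning(msg, "; rows dropped")
      trials <- trials[!bad_fam, , drop = FALSE]
    }
  }
  bad_attr <- !is.na(trials$attribution) &
    !(trials$attribution %in% ATTRIBUTION_LEVELS)
  if (any(bad_attr)) {
    msg <- sprintf("%d row(s) with unknown attribution label", sum(bad_attr))
    if (strict) stop(msg) else {
      warning(msg, "; labels set to NA")
      trials$attribution[bad_attr] <- NA_character_
    }
  }
  if (anyNA(trials$judgment) || anyNA(trials$is_grammatical) ||
      anyNA(trials$trial_index)) {
    msg <- "malformed row(s): NA in trial_index, is_grammatical or judgment"
    if (strict) stop(msg) else {
      keep <- !(is.na(trials$judgment) | is.na(trials$is_grammatical) |
                  is.na(trials$trial_index))
      warning(msg, "; rows dropped")
      trials <- trials[keep, , drop = FALSE]
    }
  }

  dup <- duplicated(trials[, c("participant_id", "trial_index")])
  if (any(dup)) {
    msg <- sprintf("%d duplicate (participant, trial_index) pair(s)", sum(dup))
    if (strict) stop(msg) else {
      warning(msg, "; duplicates dropped")
      trials <- trials[!dup, , drop = FALSE]
    }
  }

  trials <- trials[order(trials$participant_id, trials$trial_index), ,
                   drop = FALSE]
  rownames(trials) <- NULL

  # per-participant structural checks: contiguity from 1, balance, trial count
  counts <- table(trials$participant_id)
  if (is.na(n_test_trials_declared) && length(counts) > 0L) {
    tab <- table(as.integer(counts))
    n_test_trials_declared <-
      as.integer(names(tab)[which.max(tab)])
  }
  by_p <- split(trials$trial_index, trials$participant_id)
  contiguous <- vapply(by_p, function(ix) identical(ix, seq_along(ix)),
                       logical(1))
  if (any(!contiguous)) {
    msg <- sprintf("trial_index not contiguous from 1 for participant(s): %s",
                   paste(names(by_p)[!contiguous], collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  n_gram <- tapply(trials$is_grammatical, trials$participant_id, sum)
  n_all <- tapply(trials$is_grammatical, trials$participant_id, length)
  unbalanced <- names(n_all)[n_all != 2L * n_gram]
  if (length(unbalanced) > 0L) {
    warning(sprintf("unbalanced grammatical/ungrammatical design for %d participant(s)",
                    length(unbalanced)))
  }
  off_count <- names(n_all)[n_all != n_test_trials_declared]
  if (length(off_count) > 0L && !is.na(n_test_trials_declared)) {
    warning(sprintf("%d participant(s) deviate from the declared %d test trials",
                    length(off_count), n_test_trials_declared))
  }

  structure(trials,
            n_test_trials_declared = as.integer(n_test_trials_declared),
            class = c("agl_dataset", "data.frame"))
}

coerce_binary <- function(x, what) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    out <- rep(NA, length(x))
    out[x == 0] <- FALSE
    out[x == 1] <- TRUE
    return(as.logical(out))
  }
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("0", "FALSE", "false", "F")] <- FALSE
  out[x %in% c("1", "TRUE", "true", "T")] <- TRUE
  as.logical(out)
}

coerce_judgment <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x == "GRAMMATICAL"] <- "G"
  x[x == "UNGRAMMATICAL"] <- "U"
  x[!x %in% c("G", "U")] <- NA_character_
  x
}

#' Read trial-level AGL data from CSV
#'
#' Expects a header with at least `participant_id`, `trial_index`,
#' `is_grammatical` (0/1), `judgment` (`G`/`U`), `confidence`; optional
#' `familiarity` and `attribution`. Rows are re-ordered by `trial_index`
#' within participant, so file order is irrelevant.
#'
#' @param source path to a CSV file, or a connection.
#' @param strict hard-error on malformed rows (default) or drop them with a
#'   warning.
#' @param n_test_trials_declared see [agl_dataset()].
#' @return an `agl_dataset`.
#' @export
read_trials <- function(source, strict = TRUE,
                        n_test_trials_declared = NA_integer_) {
  raw <- utils::read.csv(source, stringsAsFactors = FALSE)
  agl_dataset(raw, n_test_trials_declared = n_test_trials_declared,
              strict = strict)
}

#' Write trial-level AGL data to CSV
#'
#' Inverse of [read_trials()]: booleans are serialized as 0/1, judgments as
#' `G`/`U`, so that `read_trials(write_trials(d, f))` reproduces `d` exactly.
#'
#' @param dataset an `agl_dataset`.
#' @param path output file path or connection.
#' @return `path`, invisibly.
#' @export
write_trials <- function(dataset, path) {
  out <- as.data.frame(dataset)
  out$is_grammatical <- as.integer(out$is_grammatical)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Binarize a confidence rating into guess vs. confident
#'
#' On the 50--100 scale, 50 denotes "no confidence whatsoever" (a pure
#' guess); every rating above 50 expresses some degree of confidence. All
#' Type II analyses in this package use this binary split.
#'
#' @param confidence integer vector in \[50, 100\].
#' @return character vector, `"guess"` or `"confident"`.
#' @examples
#' binarize_confidence(c(50, 51, 100))
#' @export
binarize_confidence <- function(confidence) {
  if (any(is.na(confidence)) || any(confidence < 50) || any(confidence > 100)) {
    stop("confidence must lie in [50, 100]")
  }
  ifelse(confidence == 50, "guess", "confident")
}
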