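#' @keywords internal
test_result <- function(method, statistic, df, p_value, effect_size,
                        effect_name, tail = "two", n = NA_integer_,
                        estimate = NA_real_) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 effect_size = unname(effect_size),
                 effect_name = effect_name, tail = tail,
                 n = unname(n), estimate = unname(estimate)),
            class = "bi_test")
}

#' @export
print.bi_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g (%s-tailed), %s = %.4g\n",
              x$method, x$statistic, x$df, x$p_value, x$tail,
              x$effect_name, x$effect_size))
  invisible(x)
}

#' One-sample t test with Cohen's d
#'
#' Classical one-sample t test of `mean(values) == mu0`, with effect size
#' `d = (mean - mu0) / sd`. Two-tailed by default; `tail = "one"` halves the
#' p value in the direction of the observed mean.
#'
#' @param values numeric vector, `n >= 2`, nonzero variance.
#' @param mu0 null value (default 0).
#' @param tail `"two"` (default) or `"one"`.
#' @return a `bi_test` result (statistic, df, p_value, effect_size).
#' @export
one_sample_t <- function(values, mu0 = 0, tail = c("two", "one")) {
  tail <- match.arg(tail)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("one_sample_t needs at least 2 observations")
  s <- stats::sd(values)
  if (s == 0) stop("one_sample_t: zero variance")
  m <- mean(values)
  t_stat <- (m - mu0) / (s / sqrt(n))
  p <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  if (tail == "one") p <- p / 2
  test_result("one-sample t", t_stat, n - 1, p, (m - mu0) / s, "cohen_d",
              tail, n, estimate = m)
}

#' Two-sample pooled-variance t test with Cohen's d
#'
#' Independent-samples t test with the pooled variance estimate,
#' `df = n1 + n2 - 2`; Cohen's d uses the pooled standard deviation.
#' (Pooled rather than Welch, so printed degrees of freedom equal
#' `n1 + n2 - 2`.)
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @inheritParams one_sample_t
#' @return a `bi_test` result.
#' @export
two_sample_t_pooled <- function(a, b, tail = c("two", "one")) {
  tail <- match.arg(tail)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("two_sample_t_pooled: zero pooled variance")
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  if (tail == "one") p <- p / 2
  test_result("two-sample pooled t", t_stat, df, p,
              (mean(a) - mean(b)) / sqrt(sp2), "cohen_d", tail, n1 + n2,
              estimate = mean(a) - mean(b))
}

# One-sample t on a per-participant contrast, reported on the F scale
# (F = t^2 with df (1, n-1)), as is exact for single-df effects in a fully
# within-subject design. Partial eta squared = F / (F + df_error).
contrast_f <- function(scores, method) {
  if (length(scores) >= 2L && stats::sd(scores) == 0) {
    # degenerate zero-error-variance contrast: F is exactly 0 when the
    # contrast is null, unbounded when it is not
    null_contrast <- abs(mean(scores)) < 1e-12
    return(test_result(method,
                       statistic = if (null_contrast) 0 else Inf,
                       df = length(scores) - 1,
                       p_value = if (null_contrast) 1 else 0,
                       effect_size = if (null_contrast) 0 else 1,
                       "partial_eta_sq", "two", length(scores),
                       estimate = mean(scores)))
  }
  tt <- one_sample_t(scores)
  f_stat <- tt$statistic^2
  df_err <- tt$df
  test_result(method, f_stat, df_err, tt$p_value, f_stat / (f_stat + df_err),
              "partial_eta_sq", "two", tt$n, estimate = tt$estimate)
}

#' 2 x 2 within-subject ANOVA via contrast t tests
#'
#' For a fully within-subject 2 (judgment: grammatical vs. ungrammatical)
#' x 2 (confidence: confident vs. guess) design on proportion correct, each
#' single-df effect is exactly a one-sample t test on the per-participant
#' contrast score; it is reported as `F = t^2` with df (1, n-1) and partial
#' eta squared `F / (F + df_error)`. Participants missing any cell are
#' dropped listwise.
#'
#' @param cell_means matrix or data frame with one row per participant and
#'   four columns in the order grammatical-confident, grammatical-guess,
#'   ungrammatical-confident, ungrammatical-guess.
#' @return list of `bi_test` results: `judgment`, `confidence`,
#'   `interaction`, plus `n_included`.
#' @export
anova_2x2_within <- function(cell_means) {
  cell_means <- as.matrix(cell_means)
  stopifnot(ncol(cell_means) == 4L)
  keep <- stats::complete.cases(cell_means)
  m <- cell_means[keep, , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 participants with all four cells")
  judgment <- (m[, 1] + m[, 2]) / 2 - (m[, 3] + m[, 4]) / 2
  confidence <- (m[, 1] + m[, 3]) / 2 - (m[, 2] + m[, 4]) / 2
  interaction <- (m[, 1] - m[, 2]) - (m[, 3] - m[, 4])
  list(judgment = contrast_f(judgment, "within-ANOVA judgment"),
       confidence = contrast_f(confidence, "within-ANOVA confidence"),
       interaction = contrast_f(interaction, "within-ANOVA interaction"),
       n_included = nrow(m))
}

#' Linear trend across test-phase quarters
#'
#' Tests a linear change in d'1 over the four quarters of the test phase
#' using the orthogonal linear contrast (-3, -1, +1, +3) on each
#' participant's quarter profile; a one-sample t on the contrast scores is
#' reported as `F = t^2` with df (1, n-1). Participants with any
#' non-computable quarter are dropped listwise.
#'
#' @param quarter_d1 matrix with one row per participant and four columns of
#'   quarter-wise d'1 (NA for non-computable quarters).
#' @return a `bi_test` result (F scale) with the mean contrast as
#'   `estimate` (negative = declining) and `n` the included count.
#' @export
linear_trend <- function(quarter_d1) {
  quarter_d1 <- as.matrix(quarter_d1)
  stopifnot(ncol(quarter_d1) == 4L)
  keep <- stats::complete.cases(quarter_d1)
  m <- quarter_d1[keep, , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 participants with all four quarters")
  scores <- m %*% c(-3, -1, 1, 3)
  res <- contrast_f(drop(scores), "linear trend")
  res$n <- nrow(m)
  res
}

#' Half-normal Bayes factor for a group mean
#'
#' Evidence ratio comparing H1 -- the true effect follows a half-normal
#' prior on theta >= 0 with scale `alt_sd` -- against the point null
#' theta = 0, given an observed group mean with standard error
#' `observed_se`. The marginal likelihood under H1,
#' `int_0^inf Normal(observed_mean; theta, observed_se^2) *
#' 2 Normal(theta; 0, alt_sd^2) dtheta`, is evaluated by adaptive
#' quadrature over `[0, 10 * alt_sd]` to relative tolerance 1e-8 and divided
#' by the likelihood at theta = 0. Values below 1/3 are conventionally read
#' as substantial evidence for the null.
#'
#' @param observed_mean observed group mean.
#' @param observed_se its standard error (> 0).
#' @param alt_sd scale of the half-normal alternative (> 0); typically an
#'   independently motivated plausible effect size.
#' @return the Bayes factor (numeric scalar; < 1 favors the null).
#' @examples
#' bf_halfnormal(-0.06, 0.11, 0.38)  # ~0.19: evidence for the null
#' @export
bf_halfnormal <- function(observed_mean, observed_se, alt_sd) {
  if (!is.finite(observed_mean) || !is.finite(observed_se) ||
      !is.finite(alt_sd) || observed_se <= 0 || alt_sd <= 0) {
    stop("bf_halfnormal: inputs must be finite with observed_se, alt_sd > 0")
  }
  marginal <- stats::integrate(
    function(theta) stats::dnorm(observed_mean, theta, observed_se) *
      2 * stats::dnorm(theta, 0, alt_sd),
    lower = 0, upper = 10 * alt_sd, rel.tol = 1e-8,
    subdivisions = 500L)$value
  marginal / stats::dnorm(observed_mean, 0, observed_se)
}
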