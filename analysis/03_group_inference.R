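#!/usr/bin/env Rscript
# Step 3: the full inferential battery on the blind-insight cohort.
#
# run_analysis() re-does the split and classification, then tests: d'2 (and
# meta-d', confidence-accuracy slope) against zero within each group; the
# at-chance group's d'1 against zero, with a half-normal Bayes factor whose
# scale is the above-chance group's selection-phase d'1 (the observed size
# of a real first-order effect); between-group comparisons; and the 2x2
# judgment-by-confidence ANOVA on proportion correct in the at-chance
# group.

suppressPackageStartupMessages(library(blindinsight))

report <- run_analysis("scratch/data/cohort_blind_insight.csv",
                       split_fraction = 0.75)
write_report(report, "results/03_report")

fmt_t <- function(x) sprintf("t(%d) = %.2f, p = %.3g, d = %.2f",
                             x$df, x$statistic, x$p_value, x$effect_size)
fmt_f <- function(x) sprintf("F(1, %d) = %.2f, p = %.3g, eta_p^2 = %.2f",
                             x$df, x$statistic, x$p_value, x$effect_size)

g <- report$groups
cat(sprintf("Groups: above-chance n = %d, at-chance n = %d, excluded n = %d\n\n",
            g$above_chance$n, g$at_chance$n, g$n_excluded))
cat(sprintf("At-chance group, analysis trials: d'1 = %.3f (SE %.3f), d'2 = %.3f (SE %.3f)\n",
            g$at_chance$d1[["mean"]], g$at_chance$d1[["se"]],
            g$at_chance$d2[["mean"]], g$at_chance$d2[["se"]]))
tst <- report$tests
cat("  d'2 vs 0:      ", fmt_t(tst$at_chance_d2_vs_0), "\n")
cat("  meta-d' vs 0:  ", fmt_t(tst$at_chance_meta_d_vs_0), "\n")
cat("  CA slope vs 0: ", fmt_t(tst$at_chance_slope_vs_0), "\n")
cat("  d'1 vs 0:      ", fmt_t(tst$at_chance_d1_vs_0), "\n")
cat(sprintf("  Bayes factor for d'1 (half-normal scale %.2f): %.3f\n",
            tst$at_chance_d1_bf$alt_sd, tst$at_chance_d1_bf$bayes_factor))
cat("\nBetween groups:\n")
cat("  d'2:   ", fmt_t(tst$between_d2), "\n")
cat("  slope: ", fmt_t(tst$between_slope), "\n")
if (!is.null(report$anova)) {
  cat("\n2x2 judgment x confidence ANOVA (at-chance group, n =",
      report$anova$n_included, "):\n")
  cat("  judgment:    ", fmt_f(report$anova$judgment), "\n")
  cat("  confidence:  ", fmt_f(report$anova$confidence), "\n")
  cat("  interaction: ", fmt_f(report$anova$interaction), "\n")
}
cat("\nA Bayes factor below 1/3 is strong evidence that the at-chance\n")
cat("group's first-order sensitivity is genuinely null, while its d'2\n")
cat("remains positive: metacognition without first-order accuracy.\n")
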