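#!/usr/bin/env Rscript
# ELISA stage: generate a 30-sample plate over the SEQ1-8 + CTD antigen set
# with the LNA-vs-DNA location/scale contrast, then run the plate statistics:
# group dispersity, Welch t-test on the dispersities, one-way ANOVA across
# antigens, OLS against a synthetic comparator assay, and boxplot summaries.
# Writes: results/elisa_plate.csv, results/elisa_dispersity.tsv,
#         results/elisa_tests.tsv, results/elisa_box.tsv

library(oligoantigen)
dir.create("results", showWarnings = FALSE)
seed <- 2016L

plate <- gen_elisa_plate(list(n_samples = 30, seed = seed))
write_plate_csv(plate, "results/elisa_plate.csv")

disp <- dispersity_report(plate, groups = c("LNA", "DNA"))
write.table(disp$summary, "results/elisa_dispersity.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("dispersity by antigen group (max - min per sample):\n")
print(disp$summary, row.names = FALSE)

wt <- welch_t_test(disp$per_sample[, "LNA"], disp$per_sample[, "DNA"])
an <- one_way_anova(lapply(plate$antigen_labels,
                           function(a) plate$absorbance[, a]))
# synthetic comparator assay: correlated with the CTD control column
set.seed(seed)
comparator <- plate$absorbance[, "CTD"] * 50 + rnorm(30, 0, 5)
ols <- ols_compare(plate$absorbance[, "CTD"], comparator)
tests <- data.frame(
  test = c("welch_t_dispersity", "welch_df", "welch_p",
           "anova_F_antigens", "anova_p", "ols_slope_vs_comparator",
           "ols_r_squared", "ols_p_slope"),
  value = c(wt$t, wt$df, wt$p, an$f, an$p, ols$slope, ols$r_squared,
            ols$p_slope))
write.table(tests, "results/elisa_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("Welch t on dispersity (LNA vs DNA): t = %.2f, p = %.3g\n",
            wt$t, wt$p))
cat(sprintf("one-way ANOVA across antigens: F = %.2f, p = %.3g\n", an$f, an$p))

box <- do.call(rbind, lapply(plate$antigen_labels, function(a) {
  b <- boxplot_stats(plate$absorbance[, a])
  data.frame(antigen = a, median = round(b$median, 3),
             q1 = round(b$q1, 3), q3 = round(b$q3, 3),
             lower_arm = round(b$lower_arm, 3),
             upper_arm = round(b$upper_arm, 3),
             n_outliers = length(b$outliers))
}))
write.table(box, "results/elisa_box.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("boxplot summaries written for %d antigens\n", nrow(box)))
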