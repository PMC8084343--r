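#!/usr/bin/env Rscript
# Phylogenetic comparative analysis: filter species (complete pathway +
# s-value >= 0.5), regress normalized galactose growth on pathway estAI
# by independent contrasts, fit the equivalent PGLS, screen outliers, and
# predict growth for held-out species from their codon optimization alone.

library(galcodon)
library(ape)

tree <- read.tree("results/dataset/tree.nwk")
report <- read.delim("results/pathway_report.tsv")
s_tab <- read.delim("results/s_values.tsv")
growth <- read.delim("results/growth.tsv")

completeness <- tapply(report$completeness, report$species, `[`, 1)
assign_df <- data.frame(species = names(completeness),
                        completeness = unname(completeness))
kept <- filter_species(s_tab, assign_df)

pw_mean <- tapply(report$estai, report$species, mean)[kept]
gal <- growth[growth$source == "galactose", ]
y <- setNames(gal$normalized, gal$species)[kept]

xc <- pic_contrasts(tree, pw_mean)
yc <- pic_contrasts(tree, y)
flagged <- contrast_outliers(xc, yc)
if (length(flagged) > 0) {
  cat("Contrast outliers excluded (close relatives with discordant",
      "measurements):", paste(flagged, collapse = ", "), "\n")
  keep2 <- setdiff(kept, flagged)
  xc <- pic_contrasts(tree, pw_mean[keep2])
  yc <- pic_contrasts(tree, y[keep2])
} else keep2 <- kept

pic <- pic_regression(xc, yc)
cat(sprintf("PIC regression: slope %.3f (se %.3f), r2 %.3f, p %.3g\n",
            pic$slope, pic$se, pic$r_squared, pic$p_value))

pgls <- pgls_fit(tree, y[keep2], setNames(pw_mean[keep2], keep2))
print(pgls)
cat("PGLS residual outliers (|z| > 3):",
    if (length(residual_outliers(pgls)) == 0) "none"
    else residual_outliers(pgls), "\n")

# hold out 5 species, refit, and predict their growth from estAI alone
hold <- keep2[seq(1, length(keep2), length.out = 5)]
fit_sp <- setdiff(keep2, hold)
m_ho <- pgls_fit(tree, y[fit_sp], setNames(pw_mean[fit_sp], fit_sp))
pred <- pgls_predict(m_ho, setNames(pw_mean[hold], hold))
ho <- data.frame(species = hold, predicted = round(pred, 3),
                 measured = round(y[hold], 3))
cat("\nHeld-out growth prediction from codon optimization:\n")
print(ho, row.names = FALSE)

write.table(
  data.frame(term = c("pic_slope", "pic_se", "pic_r2", "pic_p",
                      "pgls_intercept", "pgls_slope", "n_species",
                      "n_excluded"),
             value = c(pic$slope, pic$se, pic$r_squared, pic$p_value,
                       pgls$coefficients[1], pgls$coefficients[2],
                       length(keep2), length(flagged))),
  "results/comparative.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ho, "results/holdout_predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
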