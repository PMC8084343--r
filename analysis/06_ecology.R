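#!/usr/bin/env Rscript
# Ecological associations: does pathway codon optimization differ between
# niches, and which other orthology groups (KOs) share the pathway's
# optimization signal across the phylogeny?

library(galcodon)
library(ape)

tree <- read.tree("results/dataset/tree.nwk")
report <- read.delim("results/pathway_report.tsv")
s_tab <- read.delim("results/s_values.tsv")
niches <- read.delim("results/dataset/niches.tsv")
ko_tab <- read.delim("results/dataset/ko_estai.tsv", check.names = FALSE)

completeness <- tapply(report$completeness, report$species, `[`, 1)
kept <- filter_species(
  s_tab, data.frame(species = names(completeness),
                    completeness = unname(completeness)))
pw_mean <- tapply(report$estai, report$species, mean)[kept]

nk <- niches[niches$species %in% kept, ]
a <- pw_mean[nk$species[nk$dairy]]
b <- pw_mean[nk$species[!nk$dairy]]
nc <- niche_contrast(a, b)
cat(sprintf("Niche contrast (dairy vs non-dairy, %d vs %d species):\n",
            nc$n_a, nc$n_b))
cat(sprintf("  medians %.3f vs %.3f, Wilcoxon p = %.4g (%s)\n",
            nc$summary_a[["median"]], nc$summary_b[["median"]], nc$p_value,
            if (nc$exact) "exact" else "normal approximation"))

ko <- as.matrix(ko_tab[, -1])
rownames(ko) <- ko_tab$species
scan <- ko_scan(ko[kept, ], pw_mean, tree,
                min_species = max(3, floor(length(kept) / 2)))
res <- scan$results
stars <- cut(res$p_adjusted, c(-Inf, 0.001, 0.005, 0.05, Inf),
             labels = c("***", "**", "*", ""))
res$stars <- as.character(stars)
cat("\nKO scan:", scan$n_tested, "KOs tested,",
    sum(res$significant), "Bonferroni-significant\n")
print(head(res, 10), row.names = FALSE)
write.table(res, "results/ko_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(
  data.frame(group = c("dairy", "non_dairy"), n = c(nc$n_a, nc$n_b),
             median = c(nc$summary_a[["median"]], nc$summary_b[["median"]]),
             q1 = c(nc$summary_a[["q1"]], nc$summary_b[["q1"]]),
             q3 = c(nc$summary_a[["q3"]], nc$summary_b[["q3"]]),
             p_value = nc$p_value),
  "results/niche_contrast.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
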