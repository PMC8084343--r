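#!/usr/bin/env Rscript
# Codon-optimization profiling: per-species wi from the tRNA pools,
# gene stAI, genome-percentile estAI, the translational-selection s-value,
# and the pathway report (representative copy, completeness, clustering).
# Reads the dataset written by 01_simulate.R from disk, exercising the
# FASTA/TSV readers rather than the in-memory objects.

library(galcodon)

dir.create("results", showWarnings = FALSE)
data_dir <- "results/dataset"
pools <- read_trna_counts(file.path(data_dir, "trna_counts.tsv"))
fam_tab <- read.delim(file.path(data_dir, "pathway_families.tsv"))
ref_tab <- read.delim(file.path(data_dir, "reference_genes.tsv"))

wi_rows <- list(); report_rows <- list(); s_rows <- list()
for (sp in names(pools)) {
  genome <- read_cds_fasta(file.path(data_dir, "cds", paste0(sp, ".fasta")),
                           species = sp)
  wi <- compute_wi(pools[[sp]], species = sp)
  stai <- genome_stai(genome, wi)
  fam_sp <- fam_tab[fam_tab$species == sp, c("gene_id", "family")]
  ribosomal <- genome$gene_id %in% ref_tab$gene_id[ref_tab$species == sp]
  s_val <- selection_s_value(stai$stai, as.numeric(ribosomal))
  prof <- estai_normalize(stai, species = sp,
                          selection = list(s_value = s_val,
                                           pass = s_val >= 0.5))
  assignment <- pathway_profile(prof, fam_sp)
  wi_rows[[sp]] <- data.frame(species = sp, codon = names(wi$wi),
                              wi = unname(wi$wi),
                              imputed = unname(wi$imputed))
  report_rows[[sp]] <- pathway_report(assignment)
  s_rows[[sp]] <- data.frame(species = sp, s_value = s_val)
}

wi_tab <- do.call(rbind, wi_rows)
report <- do.call(rbind, report_rows)
s_tab <- do.call(rbind, s_rows)
write.table(wi_tab, "results/wi.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(report, "results/pathway_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(s_tab, "results/s_values.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Imputed codon fraction:", round(mean(wi_tab$imputed), 3), "\n")
cat("Complete pathways:", sum(tapply(report$completeness == "complete",
                                     report$species, all)), "species\n")
cat("Clustered pathways:", sum(tapply(report$clustered, report$species,
                                      all)), "species\n")
cat("Mean representative estAI:", round(mean(report$estai), 3), "\n")
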