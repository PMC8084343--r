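test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(n_species = 2), "n_species")
  expect_error(sim_config(pi_high = 1.4), "pi_high")
  expect_error(sim_config(beta = 0.5, pathway_families = character(0)),
               "pathway")
  cfg <- sim_config(seed = 2)
  expect_s3_class(cfg, "sim_config")
})

test_that("the same seed reproduces the dataset byte-identically", {
  cfg <- sim_config(seed = 5, n_species = 8, n_genes = 50)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$genomes, d2$genomes)
  expect_identical(d1$curves, d2$curves)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_dataset(d1, dir1); write_dataset(d2, dir2)
  f1 <- list.files(dir1, recursive = TRUE)
  expect_true(length(f1) > 5)
  for (f in f1)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     info = f)
})

test_that("every generated CDS is a clean coding sequence", {
  ds <- small_sim()
  code <- genetic_code()
  for (sp in names(ds$genomes)[1:3]) {
    g <- ds$genomes[[sp]]
    expect_true(all(nchar(g$seq) %% 3 == 0))
    expect_true(all(substr(g$seq, 1, 3) == "ATG"))
    aa <- vapply(g$seq[1:10], translate_cds, character(1), code = code)
    expect_false(any(grepl("\\*", substr(aa, 1, nchar(aa) - 1))))
  }
})

test_that("gene stAI increases with the optimal-codon probability", {
  ds <- small_sim()
  sp <- names(ds$genomes)[1]
  g <- ds$genomes[[sp]]
  bg <- g[is.na(g$family), ]
  stai <- genome_stai(bg, ds$true_wi[[sp]])
  truth <- ds$gene_truth[ds$gene_truth$species == sp, ]
  m <- merge(stai, truth, by = "gene_id")
  # strong default coupling: stAI tracks the expression proxy
  expect_gt(stats::cor(m$stai, m$proxy, method = "spearman"), 0.8)
  # monotone across p_opt bins
  bins <- cut(m$p_opt, breaks = stats::quantile(m$p_opt, 0:4 / 4),
              include.lowest = TRUE)
  mean_by_bin <- tapply(m$stai, bins, mean)
  expect_true(all(diff(mean_by_bin) > 0))
})

test_that("decoupled codon usage gives no stAI-proxy association", {
  ds0 <- generate_dataset(sim_config(seed = 13, n_species = 4,
                                     n_genes = 500, coupling = 0))
  sp <- names(ds0$genomes)[1]
  bg <- ds0$genomes[[sp]]
  bg <- bg[is.na(bg$family), ]
  stai <- genome_stai(bg, ds0$true_wi[[sp]])
  truth <- ds0$gene_truth[ds0$gene_truth$species == sp, ]
  m <- merge(stai, truth, by = "gene_id")
  expect_lt(abs(stats::cor(m$stai, m$proxy, method = "spearman")), 0.2)
})

test_that("niche labels achieve the configured enrichment", {
  counts_hi <- 0; n_hi <- 0; counts_lo <- 0; n_lo <- 0
  for (s in 1:5) {
    ds <- generate_dataset(sim_config(seed = 300 + s, n_species = 40,
                                      n_genes = 50))
    hi <- ds$truth$niche_enriched
    counts_hi <- counts_hi + sum(ds$niches$dairy[hi])
    n_hi <- n_hi + sum(hi)
    counts_lo <- counts_lo + sum(ds$niches$dairy[!hi])
    n_lo <- n_lo + sum(!hi)
  }
  # binomial sampling error around pi_high = 0.8 and pi_low = 0.2
  expect_lt(abs(counts_hi / n_hi - 0.8), 3 * sqrt(0.8 * 0.2 / n_hi))
  expect_lt(abs(counts_lo / n_lo - 0.2), 3 * sqrt(0.8 * 0.2 / n_lo))
})

test_that("the worked-example fixture reproduces the printed arithmetic", {
  wk <- worked_example_fixture()
  per_rep <- lapply(split(wk, list(wk$source, wk$replicate)), function(d)
    max_slope_rate(d$time_h[order(d$time_h)], d$od[order(d$time_h)]))
  gal <- unlist(per_rep[grep("galactose", names(per_rep))])
  glu <- unlist(per_rep[grep("glucose", names(per_rep))])
  expect_equal(sort(unname(gal)), c(0.0495, 0.0747, 0.0862),
               tolerance = 1e-12)
  expect_equal(sort(unname(glu)), c(0.0682, 0.0712, 0.0762),
               tolerance = 1e-12)
})
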