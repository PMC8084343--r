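test_that("wi follows the wobble-weighted decoding sums", {
  # one anticodon (AAA, tGCN = 2) decodes TTT by Watson-Crick (s = 0) and
  # TTC through the I:C wobble class; with s(I:C) = 0.5 the raw weights
  # are W(TTT) = 2 and W(TTC) = 1, so wi(TTC) = 0.5 after normalization
  # (the I:A class is switched off so only these two codons are decoded)
  rules <- default_wobble_rules(c(IC = 0.5, IA = 1))
  ra <- compute_wi(c(AAA = 2L), rules)
  expect_equal(unname(ra$wi["TTT"]), 1)
  expect_equal(unname(ra$wi["TTC"]), 0.5)
  expect_false(ra$imputed[["TTT"]])
  expect_false(ra$imputed[["TTC"]])
  # all undecoded codons imputed with the geometric mean of {1, 0.5}
  expect_true(all(ra$imputed[setdiff(names(ra$wi), c("TTT", "TTC"))]))
  expect_equal(unname(ra$wi["AAA"]), sqrt(1 * 0.5))
  # single decoder: its codon gets wi = 1, everything else imputed
  ra1 <- compute_wi(c(CAT = 3L))
  expect_equal(unname(ra1$wi["ATG"]), 1)
  expect_error(compute_wi(integer(0)), "empty")
  expect_error(compute_wi(c(AAA = 0L)), "empty|zero")
})

test_that("wi is scale-invariant and monotone in decoder copy number", {
  pool <- c(AAA = 4L, GAA = 1L, CAT = 2L, GTT = 3L)
  expect_equal(compute_wi(pool)$wi, compute_wi(pool * 5L)$wi)
  # raising the sole decoder of AAC (anticodon GTT) cannot decrease wi(AAC)
  w1 <- compute_wi(pool)$wi["AAC"]
  pool2 <- pool; pool2[["GTT"]] <- 6L
  expect_gte(compute_wi(pool2)$wi[["AAC"]], w1)
  expect_true(all(compute_wi(pool)$wi > 0 & compute_wi(pool)$wi <= 1))
  expect_equal(max(compute_wi(pool)$wi), 1)
})

test_that("stAI is the start-excluded geometric mean of wi", {
  w <- toy_wi(TTT = 0.5, TTC = 0.5)
  expect_equal(compute_stai(cds("ATG", "TTT", "TTC", "AAA"), w),
               0.25^(1 / 3), tolerance = 1e-12)
  expect_equal(compute_stai(cds("ATG", rep("AAA", 7)), w), 1)
  # start exclusion leaves one codon
  expect_equal(compute_stai(cds("ATG", "GGG"), toy_wi(GGG = 0.7)), 0.7)
  # stop codons excluded
  expect_equal(compute_stai(cds("ATG", "GGG", "TAA"), toy_wi(GGG = 0.7)), 0.7)
  expect_error(compute_stai("ATG", w), "no codons")
})

test_that("stAI matches the naive product oracle on random genes", {
  set.seed(101)
  w <- stats::setNames(runif(61, 0.05, 1), sense_codons())
  w <- w / max(w)
  for (i in 1:50) {
    g <- random_cds(sample(3:100, 1))
    expect_equal(compute_stai(g, w), stai_oracle(g, w), tolerance = 1e-12)
  }
})

test_that("CUG frequency is the CTG codon fraction", {
  expect_equal(cug_frequency(cds("ATG", rep("AAA", 10))), 0)
  expect_equal(cug_frequency(cds("ATG", "CTG", rep("AAA", 198))), 0.005)
  # concatenation: frequency of the concatenation is the
  # count-weighted mean of the parts
  g1 <- cds("CTG", rep("AAA", 3)); g2 <- cds("CTG", "CTG", rep("GGG", 4))
  f <- cug_frequency(cds(g1, g2))
  n1 <- 4; n2 <- 6
  expect_equal(f, (cug_frequency(g1) * n1 + cug_frequency(g2) * n2) /
                 (n1 + n2))
})

test_that("the s-value separates selected from unselected genomes", {
  ds <- small_sim()
  sp <- names(ds$genomes)[1]
  genome <- ds$genomes[[sp]]
  genome <- genome[is.na(genome$family), ]
  proxy <- stats::setNames(as.numeric(genome$ribosomal), genome$gene_id)
  res <- optimize_wobble_weights(genome, ds$pools[[sp]], proxy,
                                 max_sweeps = 5L)
  expect_gte(res$s_value, 0.5)
  expect_true(res$pass)
  expect_true(all(res$rules$s >= 0 & res$rules$s <= 1))
  expect_true(abs(res$s_value) <= 1)

  # genome with uniformly random synonymous codons: s-value near zero
  set.seed(202)
  null_genome <- data.frame(
    gene_id = sprintf("n%03d", 1:500),
    seq = vapply(1:500, function(i) random_cds(100), character(1)),
    stringsAsFactors = FALSE
  )
  proxy0 <- stats::setNames(rep(c(1, 0), c(50, 450)), null_genome$gene_id)
  stai0 <- genome_stai(null_genome, compute_wi(ds$pools[[sp]]))
  expect_lt(abs(selection_s_value(stai0$stai, proxy0[stai0$gene_id])), 0.2)
})

test_that("wobble-weight optimization is deterministic", {
  ds <- small_sim()
  sp <- names(ds$genomes)[2]
  genome <- ds$genomes[[sp]]
  genome <- genome[is.na(genome$family), ][1:60, ]
  proxy <- stats::setNames(as.numeric(genome$ribosomal), genome$gene_id)
  r1 <- optimize_wobble_weights(genome, ds$pools[[sp]], proxy,
                                max_sweeps = 2L)
  r2 <- optimize_wobble_weights(genome, ds$pools[[sp]], proxy,
                                max_sweeps = 2L)
  expect_identical(r1$rules, r2$rules)
  expect_identical(r1$s_value, r2$s_value)
})
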