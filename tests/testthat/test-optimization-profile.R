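test_that("estAI is the strictly-below genome fraction", {
  # a gene with 40% of the genome below it gets estAI 0.4
  g <- data.frame(gene_id = paste0("g", 1:10),
                  stai = c(0.1, 0.2, 0.3, 0.4, 0.55, 0.6, 0.7, 0.8, 0.9, 1))
  p <- estai_normalize(g)
  expect_equal(p$genes$estai[p$genes$gene_id == "g5"], 0.4)
  # genome minimum gets 0; 4th lowest of 10 distinct gets 0.3
  expect_equal(min(p$genes$estai), 0)
  expect_equal(p$genes$estai[4], 0.3)
  # distinct stAI values give the exact grid {0, 1/N, ..., (N-1)/N}
  expect_equal(sort(p$genes$estai), (0:9) / 10)
  # ties share the estAI of the lowest tied member
  gt <- data.frame(gene_id = paste0("t", 1:4), stai = c(0.2, 0.5, 0.5, 0.9))
  pt <- estai_normalize(gt)
  expect_equal(pt$genes$estai, c(0, 0.25, 0.25, 0.75))
  expect_error(estai_normalize(g[1, , drop = FALSE]), "at least 2")
})

test_that("estAI is invariant to monotone transforms of stAI", {
  set.seed(33)
  g <- data.frame(gene_id = paste0("g", 1:50), stai = runif(50))
  e1 <- estai_normalize(g)$genes$estai
  g2 <- g; g2$stai <- g$stai^3          # strictly monotone
  expect_equal(estai_normalize(g2)$genes$estai, e1)
  g3 <- g; g3$stai <- exp(5 * g$stai)
  expect_equal(estai_normalize(g3)$genes$estai, e1)
})

test_that("the representative copy is the max-estAI copy", {
  copies <- data.frame(gene_id = c("a", "b"), estai = c(0.46, 0.44))
  r <- representative_copy(copies)
  expect_equal(r$representative$estai, 0.46)
  expect_equal(r$gap, 0.02)
  one <- representative_copy(copies[1, , drop = FALSE])
  expect_equal(one$representative$gene_id, "a")
  expect_equal(one$gap, 0)
  # exact tie: lexicographically smallest gene id
  tie <- data.frame(gene_id = c("zz", "aa"), estai = c(0.5, 0.5))
  expect_equal(representative_copy(tie)$representative$gene_id, "aa")
  expect_error(representative_copy(copies[0, ]), "no copies")
  # adding a copy never decreases the representative estAI
  more <- rbind(copies, data.frame(gene_id = "c", estai = 0.2))
  expect_gte(representative_copy(more)$representative$estai,
             r$representative$estai)
})

test_that("pathway completeness counts required families", {
  expect_equal(pathway_completeness(c("GAL1", "GAL10", "GAL7")), "complete")
  expect_equal(pathway_completeness(c("GAL1", "GAL7")), "partial")
  expect_equal(pathway_completeness(character(0)), "absent")
})

make_assignment <- function(fam_df, stai_jitter = 0) {
  genes <- data.frame(gene_id = fam_df$gene_id,
                      contig = fam_df$contig,
                      stai = seq(0.5, 0.9, length.out = nrow(fam_df)))
  genes <- rbind(genes, data.frame(gene_id = sprintf("bg%02d", 1:20),
                                   contig = "bgc",
                                   stai = seq(0.01, 0.4, length.out = 20)))
  prof <- estai_normalize(genes, species = "spX")
  pathway_profile(prof, fam_df[, c("gene_id", "family")])
}

test_that("cluster detection requires a shared contig", {
  all_one <- make_assignment(data.frame(
    gene_id = c("a", "b", "c"), family = c("GAL1", "GAL10", "GAL7"),
    contig = "c1"))
  expect_true(all_one$clustered)
  split_ctg <- make_assignment(data.frame(
    gene_id = c("a", "b", "c"), family = c("GAL1", "GAL10", "GAL7"),
    contig = c("c1", "c1", "c2")))
  expect_false(split_ctg$clustered)
  # multi-copy: clustered iff some combination of copies colocates
  multi <- make_assignment(data.frame(
    gene_id = c("a1", "a2", "b", "c"),
    family = c("GAL1", "GAL1", "GAL10", "GAL7"),
    contig = c("c9", "c1", "c1", "c1")))
  expect_true(multi$clustered)
  partial <- make_assignment(data.frame(
    gene_id = c("a", "b"), family = c("GAL1", "GAL10"), contig = "c1"))
  expect_equal(partial$completeness, "partial")
  expect_error(detect_cluster(partial), "complete")
})

test_that("pathway report carries representative values and flags", {
  multi <- make_assignment(data.frame(
    gene_id = c("a1", "a2", "b", "c"),
    family = c("GAL1", "GAL1", "GAL10", "GAL7"),
    contig = c("c9", "c1", "c1", "c1")))
  rep_tab <- pathway_report(multi)
  expect_setequal(rep_tab$family, c("GAL1", "GAL10", "GAL7"))
  expect_equal(rep_tab$n_copies[rep_tab$family == "GAL1"], 2)
  expect_true(all(rep_tab$completeness == "complete"))
  g1 <- multi$families$GAL1
  expect_equal(rep_tab$estai[rep_tab$family == "GAL1"], max(g1$estai))
})
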