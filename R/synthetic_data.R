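#' Simulation configuration with study-condition defaults
#'
#' Defaults define the study conditions used throughout the test suites:
#' 60 species on a Yule tree, 200 background genes per genome plus one copy
#' of each pathway family, log-normal gene lengths around 150 codons,
#' expression-proxy coupling strong enough to mimic genomes under
#' translational selection, a Brownian species-level pathway-optimization
#' trait, normalized growth rate alpha + beta * optimization + Brownian
#' noise (beta = 0.5, sigma = 0.1), logistic growth curves sampled 0-48 h
#' at 0.5 h in 3 replicates with OD noise sd 0.01, niche enrichment
#' pi_high = 0.8 / pi_low = 0.2 for top-quartile optimization, and a KO
#' matrix of 40 KOs of which 8 share the pathway signal.
#'
#' @param seed integer seed; every random draw in the generator flows from
#'   it.
#' @param n_species number of tips on the simulated tree.
#' @param n_genes background genes per genome.
#' @param mean_codons,sd_log_codons log-normal gene length (in codons).
#' @param coupling slope of the logistic map from standardized log
#'   expression proxy to the probability of choosing the top-wi codon;
#'   0 decouples codon usage from expression.
#' @param pathway_families gene families of the focal pathway.
#' @param pathway_codons codon length of pathway genes.
#' @param alpha,beta,sigma_bm trait model: normalized growth rate =
#'   alpha + beta * pathway optimization + Brownian noise with tip sd
#'   sigma_bm on the depth-1 tree.
#' @param glucose_rate mean control growth rate (OD/h).
#' @param od_noise_sd Gaussian OD noise on the curves.
#' @param n_replicates growth-curve replicates.
#' @param t_max,t_step growth sampling grid in hours.
#' @param pi_high,pi_low niche membership probabilities for top-quartile
#'   vs other species.
#' @param n_ko,n_ko_signal KO matrix size and number of KOs sharing the
#'   pathway optimization signal.
#' @param frac_ribosomal fraction of background genes labeled as the
#'   highly expressed reference (proxy) set.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L, n_species = 60L, n_genes = 200L,
                       mean_codons = 150, sd_log_codons = 0.3,
                       coupling = 2, pathway_families = c("GAL1", "GAL10", "GAL7"),
                       pathway_codons = 350L,
                       alpha = 0.3, beta = 0.5, sigma_bm = 0.1,
                       glucose_rate = 0.07, od_noise_sd = 0.01,
                       n_replicates = 3L, t_max = 48, t_step = 0.5,
                       pi_high = 0.8, pi_low = 0.2,
                       n_ko = 40L, n_ko_signal = 8L,
                       frac_ribosomal = 0.1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 4, cfg$n_genes >= 50,
            cfg$pi_high >= 0 && cfg$pi_high <= 1,
            cfg$pi_low >= 0 && cfg$pi_low <= 1,
            cfg$n_ko_signal <= cfg$n_ko, cfg$frac_ribosomal > 0)
  if (cfg$beta != 0 && length(cfg$pathway_families) == 0)
    stop("trait slope beta set but no pathway families configured")
  class(cfg) <- "sim_config"
  cfg
}

# uniform choice among synonymous codons, vectorized over positions
# (fams_flat = unlist(fams_list), fam_offset = 0-based start per family)
sample_codons_for_aa <- function(aa_idx, fams_flat, fam_offset, fam_sizes) {
  pick <- floor(stats::runif(length(aa_idx)) * fam_sizes[aa_idx]) + 1L
  fams_flat[fam_offset[aa_idx] + pick]
}

# one gene: ATG + codons drawn optimal-with-prob-p else uniform synonymous
simulate_gene <- function(n_codons, p_opt, fams_flat, fam_offset, fam_sizes,
                          best_codon) {
  aa_idx <- sample.int(length(fam_sizes), n_codons, replace = TRUE)
  use_opt <- stats::runif(n_codons) < p_opt
  cod <- character(n_codons)
  if (any(use_opt)) cod[use_opt] <- best_codon[aa_idx[use_opt]]
  if (any(!use_opt))
    cod[!use_opt] <- sample_codons_for_aa(aa_idx[!use_opt], fams_flat,
                                          fam_offset, fam_sizes)
  paste0("ATG", paste(cod, collapse = ""))
}

#' Generate a fully specified synthetic dataset with known ground truth
#'
#' Simulates: (a) a Yule species tree rescaled to depth 1; (b) per-species
#' tRNA pools and the true wi implied by the default wobble penalties; (c)
#' background genes whose codons are the top-wi synonymous codon with a
#' probability that increases with a log-normal expression proxy (the
#' top-proxy genes are labeled as the ribosomal-like reference set); (d)
#' pathway genes whose optimal-codon probability equals a Brownian
#' species-level optimization trait squashed to (0, 1); (e) normalized
#' growth rate alpha + beta * optimization + Brownian noise, realized as
#' noisy logistic growth curves on galactose with glucose controls; (f)
#' niche labels enriched in high-optimization species; (g) a KO estAI
#' matrix in which a configured subset of KOs shares the pathway signal.
#'
#' @param config a \code{sim_config}.
#' @param out_dir optional directory; when given, writes FASTA per species,
#'   tRNA/growth/niche/KO/ground-truth TSVs, and the Newick tree.
#' @return list: tree, genomes (named list of CDS data frames), pools,
#'   true_wi, curves, niches, ko_estai, truth (per-species data frame with
#'   every latent variable), gene_truth (per-gene proxy and p_opt),
#'   config.
#' @export
generate_dataset <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$seed)
  code <- genetic_code()
  fams <- synonym_families(code)
  fams_list <- unname(fams)
  fam_sizes <- vapply(fams_list, length, integer(1))
  fams_flat <- unlist(fams_list)
  fam_offset <- c(0L, cumsum(fam_sizes))[seq_along(fam_sizes)]

  # (a) Yule tree, depth rescaled to 1
  tree <- ape::rphylo(config$n_species, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(config$n_species))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth

  # species-level pathway optimization trait (Brownian on the tree)
  z <- ape::rTraitCont(tree, model = "BM", sigma = 1.5)
  opt_trait <- stats::plogis(2 * z)

  # growth: normalized rate with Brownian residual
  eps <- ape::rTraitCont(tree, model = "BM", sigma = config$sigma_bm)
  norm_rate <- stats::setNames(
    pmax(0.02, config$alpha + config$beta * opt_trait + eps),
    tree$tip.label)
  glu_rate <- config$glucose_rate * exp(stats::rnorm(config$n_species, 0, 0.1))
  names(glu_rate) <- tree$tip.label

  wc_anticodons <- reverse_complement(sense_codons())
  pools <- list(); true_wi <- list(); genomes <- list()
  gene_truth <- list()
  for (sp in tree$tip.label) {
    # (b) tRNA pool: Poisson copies at each Watson-Crick anticodon, with
    # the first codon of every synonymous family guaranteed a decoder
    cnt <- stats::rpois(length(wc_anticodons), 3)
    names(cnt) <- wc_anticodons
    pool <- tapply(cnt, names(cnt), sum)
    pool <- stats::setNames(as.integer(pool), names(pool))
    for (f in fams_list) {
      ac <- reverse_complement(f[1])
      pool[ac] <- max(pool[ac], 1L, na.rm = TRUE)
    }
    pools[[sp]] <- pool
    wi <- compute_wi(pool, species = sp)
    true_wi[[sp]] <- wi
    best_codon <- vapply(fams_list, function(f) f[which.max(wi$wi[f])],
                         character(1))

    # (c) background genes
    n_cod <- pmax(50L, round(stats::rlnorm(config$n_genes,
                                           log(config$mean_codons),
                                           config$sd_log_codons)))
    proxy <- stats::rlnorm(config$n_genes, 0, 1)
    zp <- as.numeric(scale(log(proxy)))
    p_opt <- stats::plogis(config$coupling * zp)
    seqs <- vapply(seq_len(config$n_genes), function(i)
      simulate_gene(n_cod[i], p_opt[i], fams_flat, fam_offset, fam_sizes,
                    best_codon), character(1))
    ribosomal <- rank(-proxy) <= ceiling(config$frac_ribosomal *
                                           config$n_genes)
    gene_id <- sprintf("%s_g%04d", sp, seq_len(config$n_genes))
    contig <- sprintf("ctg%02d", 1 + (seq_len(config$n_genes) %% 8))

    # (d) pathway genes: optimal-codon probability = species trait
    pw <- config$pathway_families
    pw_seqs <- vapply(pw, function(f)
      simulate_gene(config$pathway_codons, opt_trait[sp], fams_flat,
                    fam_offset, fam_sizes, best_codon), character(1))
    genomes[[sp]] <- data.frame(
      gene_id = c(gene_id, paste0(sp, "_", pw)),
      species = sp,
      contig = c(contig, rep("ctg01", length(pw))),
      seq = c(seqs, pw_seqs),
      family = c(rep(NA_character_, config$n_genes), pw),
      ribosomal = c(ribosomal, rep(FALSE, length(pw))),
      stringsAsFactors = FALSE
    )
    gene_truth[[sp]] <- data.frame(
      gene_id = gene_id, species = sp, proxy = proxy, p_opt = p_opt,
      n_codons = n_cod, stringsAsFactors = FALSE
    )
  }

  # (e) growth curves: logistic with max derivative = rate, plus noise
  grid <- seq(0, config$t_max, by = config$t_step)
  curve_rows <- list()
  for (sp in tree$tip.label) {
    for (src in c("galactose", "glucose")) {
      rate <- if (src == "glucose") glu_rate[[sp]]
              else norm_rate[[sp]] * glu_rate[[sp]]
      K <- 1; r <- 4 * rate / K; tm <- config$t_max / 2.5
      for (rep_i in seq_len(config$n_replicates)) {
        od <- 0.05 + K / (1 + exp(-r * (grid - tm))) +
          stats::rnorm(length(grid), 0, config$od_noise_sd)
        curve_rows[[length(curve_rows) + 1L]] <- data.frame(
          species = sp, source = src, replicate = rep_i,
          time_h = grid, od = pmax(0, od), stringsAsFactors = FALSE)
      }
    }
  }
  curves <- do.call(rbind, curve_rows)

  # (f) niche labels enriched in high-optimization species
  top_q <- opt_trait >= stats::quantile(opt_trait, 0.75)
  p_a <- ifelse(top_q, config$pi_high, config$pi_low)
  niches <- data.frame(
    species = tree$tip.label,
    dairy = stats::runif(config$n_species) < p_a,
    alcohol = stats::runif(config$n_species) < 0.3,
    stringsAsFactors = FALSE
  )

  # (g) KO matrix: signal KOs track the optimization trait; the rest are
  # independent Brownian traits (KO optimization is itself phylogenetically
  # structured, so white-noise nulls would misrepresent real data)
  ko_ids <- sprintf("K%05d", seq_len(config$n_ko))
  ko_estai <- matrix(NA_real_, nrow = config$n_species,
                     dimnames = list(tree$tip.label, ko_ids),
                     ncol = config$n_ko)
  for (j in seq_len(config$n_ko)) {
    ko_estai[, j] <- if (j <= config$n_ko_signal)
      stats::plogis(2 * z + stats::rnorm(config$n_species, 0, 0.3))
    else
      stats::plogis(ape::rTraitCont(tree, model = "BM",
                                    sigma = 1.5))[tree$tip.label]
  }

  truth <- data.frame(
    species = tree$tip.label,
    pathway_optimization = unname(opt_trait[tree$tip.label]),
    bm_latent = unname(z[tree$tip.label]),
    normalized_rate = unname(norm_rate[tree$tip.label]),
    glucose_rate = unname(glu_rate[tree$tip.label]),
    niche_enriched = unname(top_q[tree$tip.label]),
    stringsAsFactors = FALSE
  )

  ds <- list(tree = tree, genomes = genomes, pools = pools,
             true_wi = true_wi, curves = curves, niches = niches,
             ko_estai = ko_estai, truth = truth,
             gene_truth = do.call(rbind, gene_truth), config = config)
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' Write a synthetic dataset to plain-text files
#' @param ds dataset from \code{generate_dataset}.
#' @param out_dir output directory (created if needed).
#' @return out_dir, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "cds"), showWarnings = FALSE)
  for (sp in names(ds$genomes))
    write_cds_fasta(ds$genomes[[sp]], file.path(out_dir, "cds",
                                                paste0(sp, ".fasta")))
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(trna_pool_to_table(ds$pools), "trna_counts.tsv")
  tsv(ds$curves, "growth_curves.tsv")
  tsv(ds$niches, "niches.tsv")
  tsv(ds$truth, "ground_truth_species.tsv")
  tsv(ds$gene_truth, "ground_truth_genes.tsv")
  ko <- data.frame(species = rownames(ds$ko_estai), ds$ko_estai,
                   stringsAsFactors = FALSE)
  tsv(ko, "ko_estai.tsv")
  fam <- do.call(rbind, lapply(ds$genomes, function(g)
    g[!is.na(g$family), c("species", "gene_id", "family")]))
  tsv(fam, "pathway_families.tsv")
  ref <- do.call(rbind, lapply(ds$genomes, function(g)
    g[g$ribosomal, c("species", "gene_id")]))
  tsv(ref, "reference_genes.tsv")
  ape::write.tree(ds$tree, file.path(out_dir, "tree.nwk"))
  invisible(out_dir)
}

#' Growth-curve fixture reproducing the documented worked example
#'
#' Emits three galactose and three glucose replicate curves, each an exact
#' line whose slope equals the corresponding published replicate slope
#' (galactose 0.0495, 0.0747, 0.0862; glucose 0.0712, 0.0762, 0.0682
#' OD/h), so the growth pipeline reproduces the printed means (0.070 and
#' 0.072) and glucose-normalized ratio (0.97).
#'
#' @param t_max,t_step sampling grid in hours.
#' @return long-format data frame: species, source, replicate, time_h, od.
#' @export
worked_example_fixture <- function(t_max = 24, t_step = 1) {
  slopes <- list(galactose = c(0.0495, 0.0747, 0.0862),
                 glucose = c(0.0712, 0.0762, 0.0682))
  grid <- seq(0, t_max, by = t_step)
  do.call(rbind, lapply(names(slopes), function(src) {
    do.call(rbind, lapply(seq_along(slopes[[src]]), function(i) {
      data.frame(species = "worked_example", source = src, replicate = i,
                 time_h = grid, od = 0.1 + slopes[[src]][i] * grid,
                 stringsAsFactors = FALSE)
    }))
  }))
}
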