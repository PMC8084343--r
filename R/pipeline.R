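#' Run the full reverse-ecology pipeline on a dataset
#'
#' Chains the stages in order: wi -> stAI -> S-test -> estAI -> pathway
#' report -> growth quantification -> species filtering -> PIC/PGLS ->
#' random-codon null test -> niche contrast -> KO scan. Each stage writes
#' one TSV under \code{out_dir} (when given) and the run ends with a JSON
#' manifest recording seeds, thresholds, per-stage row counts, and output
#' checksums. Any stage failure aborts with the stage name.
#'
#' @param ds dataset list as produced by \code{generate_dataset} (tree,
#'   genomes, pools, curves, niches, ko_estai).
#' @param out_dir optional output directory.
#' @param s_threshold s-value gate (default 0.5).
#' @param min_cds_nt minimum CDS length in nt (default 500) applied before
#'   scoring, as when handling newly annotated genomes; pathway genes are
#'   exempt so short fixtures remain scorable.
#' @param ko_min_species KO scan gate (default 100; lowered automatically
#'   to half the species count when the dataset is smaller, with a
#'   message).
#' @param null_n random-codon replicates for the null stage (default 1000).
#' @param seed seed for the null stage.
#' @param run_s_test run the (grid-search) wobble-weight optimization per
#'   species; when FALSE (default) the s-value is computed at the
#'   literature wobble penalties, which is much faster.
#' @param screen_outliers exclude high-leverage contrast outliers
#'   (\code{contrast_outliers}) from the comparative stage, logging the
#'   species removed — the residual-plot screen applied in comparative
#'   growth analyses. Excluded species are reported in the result.
#' @return list with every stage's result and the manifest.
#' @export
run_pipeline <- function(ds, out_dir = NULL, s_threshold = 0.5,
                         min_cds_nt = 500L, ko_min_species = 100L,
                         null_n = 1000L, seed = 1L, run_s_test = FALSE,
                         screen_outliers = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(df, name) {
    if (is.null(out_dir) || is.null(df)) return(invisible(NULL))
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- p
    invisible(p)
  }
  species <- names(ds$genomes)
  code <- genetic_code()

  profiles <- list(); s_values <- stats::setNames(numeric(0), character(0))
  wi_rows <- list(); stai_rows <- list()
  for (sp in species) {
    genome <- ds$genomes[[sp]]
    is_pathway <- !is.na(genome$family)
    keep <- nchar(genome$seq) >= min_cds_nt | is_pathway
    genome <- genome[keep, , drop = FALSE]

    wi <- stage("wi", compute_wi(ds$pools[[sp]], species = sp))
    s_res <- NULL
    if (run_s_test) {
      proxy <- stats::setNames(as.numeric(genome$ribosomal), genome$gene_id)
      s_res <- stage("s_test", optimize_wobble_weights(
        genome[!is_pathway[keep], ], ds$pools[[sp]], proxy, code,
        threshold = s_threshold))
      wi <- s_res$wi
    } else {
      proxy <- stats::setNames(as.numeric(genome$ribosomal), genome$gene_id)
      stai0 <- genome_stai(genome, wi, code)
      s_val <- selection_s_value(stai0$stai, proxy[stai0$gene_id])
      s_res <- list(s_value = s_val, pass = !is.na(s_val) &&
                      s_val >= s_threshold)
    }
    st <- stage("stai", genome_stai(genome, wi, code))
    prof <- stage("estai", estai_normalize(st, species = sp,
                                           selection = s_res))
    profiles[[sp]] <- prof
    s_values[[sp]] <- s_res$s_value
    wi_rows[[sp]] <- data.frame(species = sp, codon = names(wi$wi),
                                wi = unname(wi$wi),
                                imputed = unname(wi$imputed))
    stai_rows[[sp]] <- cbind(prof$genes,
                             family = genome$family[match(prof$genes$gene_id,
                                                          genome$gene_id)])
  }
  emit(do.call(rbind, wi_rows), "wi.tsv")
  emit(do.call(rbind, stai_rows), "stai_estai.tsv")

  assignments <- stage("pathway", lapply(profiles, function(pr) {
    g <- ds$genomes[[pr$species]]
    fam <- g[!is.na(g$family), c("gene_id", "family")]
    pathway_profile(pr, fam)
  }))
  pw_report <- do.call(rbind, lapply(assignments, pathway_report))
  emit(pw_report, "pathway_report.tsv")

  growth <- stage("growth", quantify_growth(ds$curves))
  emit(growth, "growth.tsv")

  profile_df <- data.frame(
    species = species,
    s_value = unname(s_values[species]), stringsAsFactors = FALSE)
  assign_df <- data.frame(
    species = species,
    completeness = vapply(assignments[species], `[[`, character(1),
                          "completeness"), stringsAsFactors = FALSE)
  kept <- stage("filter", suppressMessages(
    filter_species(profile_df, assign_df, s_threshold = s_threshold)))

  pw_mean <- vapply(assignments, function(a) mean(a$representative),
                    numeric(1))
  gal <- growth[growth$source == "galactose", ]
  y <- stats::setNames(gal$normalized, gal$species)[kept]
  x <- pw_mean[kept]
  comparative <- stage("comparative", {
    excluded <- character(0)
    for (round in 1:3) {           # documented outlier screen, as in
      keep2 <- setdiff(names(x), excluded)  # residual-plot-based removal
      xc <- pic_contrasts(ds$tree, x[keep2])
      yc <- pic_contrasts(ds$tree, y[keep2])
      if (!screen_outliers) break
      flagged <- contrast_outliers(xc, yc)
      if (length(flagged) == 0) break
      message("comparative stage excluding contrast outliers: ",
              paste(flagged, collapse = ", "))
      excluded <- c(excluded, flagged)
    }
    pic <- pic_regression(xc, yc)
    keep2 <- setdiff(names(x), excluded)
    pgls <- pgls_fit(ds$tree, y[keep2],
                     stats::setNames(x[keep2], keep2))
    list(pic = pic, pgls = pgls, outliers = residual_outliers(pgls),
         excluded = excluded)
  })
  emit(data.frame(term = c("pic_slope", "pic_p", "pic_r2", "pgls_intercept",
                           "pgls_slope", "pgls_sigma2"),
                  value = c(comparative$pic$slope, comparative$pic$p_value,
                            comparative$pic$r_squared,
                            comparative$pgls$coefficients[1],
                            comparative$pgls$coefficients[2],
                            comparative$pgls$sigma2)),
       "comparative.tsv")

  null_res <- stage("null_test", {
    sp0 <- kept[1]
    g <- ds$genomes[[sp0]]
    pw_gene <- g$seq[!is.na(g$family)][1]
    null_test(pw_gene, compute_wi(ds$pools[[sp0]], species = sp0), code,
              n = null_n, seed = seed)
  })

  niche <- stage("niche_test", {
    nt <- ds$niches[ds$niches$species %in% kept, ]
    a <- pw_mean[nt$species[nt$dairy]]
    b <- pw_mean[nt$species[!nt$dairy]]
    niche_contrast(a, b)
  })
  emit(data.frame(group = c("in_niche", "out_niche"),
                  n = c(niche$n_a, niche$n_b),
                  median = c(niche$summary_a[["median"]],
                             niche$summary_b[["median"]]),
                  p_value = niche$p_value), "niche.tsv")

  ms <- ko_min_species
  if (ms > length(kept)) {
    ms <- max(3L, floor(length(kept) / 2))
    message("KO scan min_species lowered to ", ms,
            " for a ", length(kept), "-species dataset")
  }
  ko <- stage("ko_scan", ko_scan(ds$ko_estai[kept, , drop = FALSE],
                                 pw_mean[kept], ds$tree, min_species = ms))
  emit(ko$results, "ko_scan.tsv")

  manifest <- list(
    stages = c("wi", "stai", "s_test", "estai", "pathway", "growth",
               "filter", "comparative", "null_test", "niche_test",
               "ko_scan"),
    n_species = length(species), n_kept = length(kept),
    thresholds = list(s_value = s_threshold, min_cds_nt = min_cds_nt,
                      ko_min_species = ms, null_n = null_n),
    seed = seed,
    checksums = if (length(outputs))
      as.list(stats::setNames(unname(tools::md5sum(unlist(outputs))),
                              names(outputs)))
    else list()
  )
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  list(profiles = profiles, assignments = assignments, growth = growth,
       kept = kept, comparative = comparative, null = null_res,
       niche = niche, ko = ko, pathway_mean = pw_mean,
       manifest = manifest)
}
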