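#' Filter species for ecological association testing
#'
#' Retains the intersection of species with a complete pathway and species
#' passing the genome-wide translational-selection gate (s-value >=
#' threshold, inclusive). Stratum counts are reported via message.
#'
#' @param profiles data frame with columns species, s_value.
#' @param assignments data frame with columns species, completeness.
#' @param require_complete require a complete pathway (default TRUE).
#' @param s_threshold s-value gate (default 0.5); set to 0 together with
#'   \code{require_complete = FALSE} to keep all species.
#' @return character vector of retained species ids.
#' @export
filter_species <- function(profiles, assignments, require_complete = TRUE,
                           s_threshold = 0.5) {
  complete <- assignments$species[assignments$completeness == "complete"]
  selected <- profiles$species[!is.na(profiles$s_value) &
                                 profiles$s_value >= s_threshold]
  keep <- intersect(
    if (require_complete) complete else profiles$species,
    selected
  )
  message(length(complete), " species with complete pathway; ",
          length(selected), " passing s-value >= ", s_threshold, "; ",
          length(keep), " retained")
  if (length(keep) == 0) warning("no species retained by the filters")
  keep
}

#' Wilcoxon rank-sum contrast of optimization between two niches
#'
#' Two-sided Wilcoxon rank-sum test: exact enumeration when both groups
#' have <= 10 observations and there are no ties, normal approximation
#' with tie correction otherwise. Also reports the five-number summary of
#' each group.
#'
#' @param a,b numeric estAI values for the two groups (non-empty).
#' @param exact_max largest group size for exact enumeration (default 10).
#' @return list: p_value, statistic (W), exact flag, and summary_a /
#'   summary_b (min, q1, median, q3, max).
#' @export
niche_contrast <- function(a, b, exact_max = 10L) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= exact_max && length(b) <= exact_max && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = !exact)
  )
  five <- function(x) stats::setNames(stats::fivenum(x),
                                      c("min", "q1", "median", "q3", "max"))
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       exact = exact, summary_a = five(a), summary_b = five(b),
       n_a = length(a), n_b = length(b))
}

#' Genome-wide KO correlated-optimization scan
#'
#' For every KO (orthology group) present in at least \code{min_species}
#' species, prunes the tree to species carrying both the KO estAI and the
#' target pathway estAI, regresses KO contrasts on target contrasts through
#' the origin, and Bonferroni-adjusts p-values over the number of KOs
#' actually tested. Results are ordered by absolute slope among
#' Bonferroni-significant KOs first, then by raw p.
#'
#' @param ko_estai numeric matrix, species x KO, NA where the KO is absent.
#' @param target named numeric: species -> pathway estAI.
#' @param tree phylo object covering the species.
#' @param min_species minimum species per KO (default 100, the gate used at
#'   subphylum scale; must be >= 3).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return list: results (data frame ko, n_species, slope, r_squared,
#'   p_value, p_adjusted, significant), n_tested, skipped (KO ids).
#' @export
ko_scan <- function(ko_estai, target, tree, min_species = 100L,
                    alpha = 0.05) {
  if (min_species < 3L) stop("min_species must be at least 3")
  target <- target[!is.na(target)]
  rows <- list()
  skipped <- character(0)
  for (ko in colnames(ko_estai)) {
    v <- ko_estai[, ko]
    sp <- intersect(names(v)[!is.na(v)], names(target))
    sp <- intersect(sp, tree$tip.label)
    if (length(sp) < min_species) { skipped <- c(skipped, ko); next }
    xc <- pic_contrasts(tree, target[sp])
    yc <- pic_contrasts(tree, v[sp])
    fit <- pic_regression(xc, yc)
    rows[[ko]] <- data.frame(ko = ko, n_species = length(sp),
                             slope = fit$slope, r_squared = fit$r_squared,
                             p_value = fit$p_value, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(list(results = NULL, n_tested = 0L, skipped = skipped))
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "bonferroni")
  res$significant <- res$p_adjusted < alpha
  res <- res[order(!res$significant, -abs(res$slope) * res$significant,
                   res$p_value), ]
  rownames(res) <- NULL
  list(results = res, n_tested = nrow(res), skipped = skipped)
}
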