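#' Randomize the codon usage of a coding sequence
#'
#' Replaces each codon by a synonymous codon sampled uniformly, keeping the
#' amino-acid sequence identical. The start codon is preserved; stop codons
#' are preserved as-is.
#'
#' @param seq DNA coding sequence.
#' @param code a \code{genetic_code}.
#' @param seed optional integer seed for reproducibility.
#' @return randomized DNA string with identical translation.
#' @export
randomize_codons <- function(seq, code = genetic_code(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codons <- split_codons(seq)
  if (length(codons) == 0) return(seq)
  aa <- code$table[codons]
  if (anyNA(aa))
    stop("untranslatable codons: ",
         paste(unique(codons[is.na(aa)]), collapse = ", "))
  fams <- synonym_families(code, include_stops = TRUE)
  new <- vapply(aa, function(a) {
    f <- fams[[a]]
    f[sample.int(length(f), 1L)]
  }, character(1), USE.NAMES = FALSE)
  new[1L] <- codons[1L]                       # start codon preserved
  new[aa == "*"] <- codons[aa == "*"]
  paste(new, collapse = "")
}

#' Random-codon null distribution for an optimization statistic
#'
#' Generates n synonymous randomizations of a gene, computes a statistic
#' for each (gene stAI by default, or any function of the null stAI vector
#' such as a PGLS growth prediction), and locates the observed statistic
#' within the null distribution: its percentile (fraction of nulls strictly
#' below), and whether it falls outside the central 95% and 99% intervals
#' (with the side) as well as beyond the one-sided 95th/99th percentiles.
#'
#' @param seq observed DNA coding sequence.
#' @param wi \code{relative_adaptiveness} for the species.
#' @param code a \code{genetic_code}.
#' @param statistic_fn optional function mapping a numeric vector of stAI
#'   values to the statistic of interest (applied to both nulls and
#'   observed); default identity (the statistic is stAI itself).
#' @param n number of null replicates (>= 100; default 1000).
#' @param seed integer seed.
#' @return object of class \code{null_distribution}: nulls, observed,
#'   percentile, outside_95/outside_99 (central), side, above_p95/above_p99
#'   (one-sided), n.
#' @export
null_test <- function(seq, wi, code = genetic_code(), statistic_fn = NULL,
                      n = 1000L, seed = NULL) {
  if (n < 100L) stop("need at least 100 null replicates")
  if (!is.null(seed)) set.seed(seed)
  w <- if (inherits(wi, "relative_adaptiveness")) wi$wi else wi
  codons <- split_codons(seq)
  if (length(codons) < 2L) stop("sequence too short for a null test")
  aa <- code$table[codons]
  body <- seq_along(codons)[-1L]
  body <- body[!(aa[body] == "*")]
  fams <- synonym_families(code)
  logw_by_aa <- lapply(fams, function(f) log(w[f]))
  # sample synonymous log-wi per position for all replicates at once
  null_logmean <- numeric(n)
  draws <- matrix(0, nrow = n, ncol = length(body))
  for (j in seq_along(body)) {
    lw <- logw_by_aa[[aa[body[j]]]]
    draws[, j] <- lw[sample.int(length(lw), n, replace = TRUE)]
  }
  null_stai <- exp(rowMeans(draws))
  obs_stai <- compute_stai(seq, w, code)
  stat <- if (is.null(statistic_fn)) identity else statistic_fn
  nulls <- stat(null_stai)
  observed <- stat(obs_stai)
  q <- stats::quantile(nulls, c(0.005, 0.025, 0.95, 0.975, 0.99, 0.995),
                       names = FALSE, type = 7)
  side <- if (observed > stats::median(nulls)) "high" else "low"
  structure(
    list(nulls = nulls, observed = observed,
         percentile = mean(nulls < observed),
         outside_95 = observed < q[2] || observed > q[4],
         outside_99 = observed < q[1] || observed > q[6],
         above_p95 = observed > q[3], above_p99 = observed > q[5],
         side = side, n = n),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Null distribution (n = ", x$n, "): observed ",
      format(x$observed, digits = 4), " at percentile ",
      format(x$percentile, digits = 3),
      if (x$outside_99) " (outside central 99%)"
      else if (x$outside_95) " (outside central 95%)" else "", "\n", sep = "")
  invisible(x)
}
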