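#' Default wobble-pairing table
#'
#' Codon:anticodon pairing classes at the codon third position / anticodon
#' position 34, each with a selective penalty s in [0, 1] (0 = perfect
#' pairing). Watson-Crick pairings carry s = 0; the four wobble classes
#' (G:U, I:C, I:A, U:G, with inosine arising from A34) carry the standard
#' tAI literature defaults. Anticodons are written in DNA alphabet.
#'
#' @param s_wobble optional named numeric overriding the wobble penalties;
#'   names among "GU", "IC", "IA", "UG".
#' @return data frame with columns class, anticodon_wobble (base at
#'   position 34), codon_third, s.
#' @export
default_wobble_rules <- function(s_wobble = NULL) {
  rules <- data.frame(
    class           = c("WC", "WC", "WC", "WC", "GU", "IC", "IA", "UG"),
    anticodon_wobble = c("A",  "G",  "C",  "T",  "G",  "A",  "A",  "T"),
    codon_third      = c("T",  "C",  "G",  "A",  "T",  "C",  "A",  "G"),
    s = c(0, 0, 0, 0, 0.41, 0.28, 0.9999, 0.68),
    stringsAsFactors = FALSE
  )
  if (!is.null(s_wobble)) {
    stopifnot(all(names(s_wobble) %in% c("GU", "IC", "IA", "UG")),
              all(s_wobble >= 0 & s_wobble <= 1))
    m <- match(rules$class, names(s_wobble))
    rules$s[!is.na(m)] <- s_wobble[m[!is.na(m)]]
  }
  rules
}

#' The 61 sense codons of the standard code
#' @return character vector, sorted.
#' @export
sense_codons <- function() {
  code <- genetic_code()
  sort(setdiff(ALL_CODONS, code$stop_codons))
}

#' Per-codon relative adaptiveness (wi) from a tRNA pool
#'
#' For each sense codon c the raw weight is
#' W(c) = sum over anticodons a that decode c of (1 - s(a:c)) * tGCN(a),
#' where decoding anticodons share the reverse complement of the codon's
#' first two bases at positions 35-36 and pair the third codon base at
#' position 34 according to the wobble table. Weights are normalized so the
#' best codon has wi = 1; codons with W = 0 are imputed with the geometric
#' mean of the non-zero wi and flagged.
#'
#' @param pool named integer vector: anticodon (DNA) -> tRNA gene copies.
#' @param rules wobble table from \code{default_wobble_rules}.
#' @param species optional species id carried in the result.
#' @return object of class \code{relative_adaptiveness}: list with
#'   \code{wi} (named numeric over the 61 sense codons), \code{imputed}
#'   (logical, same names), and \code{species} (optional id).
#' @export
compute_wi <- function(pool, rules = default_wobble_rules(), species = NA_character_) {
  if (length(pool) == 0 || all(pool == 0)) stop("empty or all-zero tRNA pool")
  codons <- sense_codons()
  W <- stats::setNames(numeric(length(codons)), codons)
  prefix <- substr(codons, 1, 2)
  third <- substr(codons, 3, 3)
  tail34 <- reverse_complement(prefix)  # anticodon positions 35-36
  for (i in seq_len(nrow(rules))) {
    hit <- third == rules$codon_third[i]
    ac <- paste0(rules$anticodon_wobble[i], tail34[hit])
    cnt <- pool[ac]
    cnt[is.na(cnt)] <- 0L
    W[hit] <- W[hit] + (1 - rules$s[i]) * cnt
  }
  if (all(W == 0)) stop("uninformative tRNA pool: all codon weights are zero")
  wi <- W / max(W)
  imputed <- wi == 0
  if (any(imputed))
    wi[imputed] <- exp(mean(log(wi[!imputed])))
  structure(list(wi = wi, imputed = imputed, species = species),
            class = "relative_adaptiveness")
}

#' @export
print.relative_adaptiveness <- function(x, ...) {
  cat("Relative adaptiveness (wi) over", length(x$wi), "sense codons;",
      sum(x$imputed), "imputed\n")
  invisible(x)
}

#' Species-specific tRNA adaptation index (stAI) of a gene
#'
#' The geometric mean of wi over a gene's codons, excluding the start codon
#' and any stop codons, computed in log space.
#'
#' @param seq DNA coding sequence (string), length divisible by 3.
#' @param wi a \code{relative_adaptiveness} object (or named numeric).
#' @param code a \code{genetic_code} (used only to identify stop codons).
#' @return stAI in (0, 1].
#' @export
compute_stai <- function(seq, wi, code = genetic_code()) {
  w <- if (inherits(wi, "relative_adaptiveness")) wi$wi else wi
  codons <- split_codons(seq)
  if (length(codons) >= 1) codons <- codons[-1L]        # start codon excluded
  codons <- codons[!(codons %in% code$stop_codons)]
  if (length(codons) == 0) stop("no codons left after start/stop exclusion")
  lw <- log(w[codons])
  if (anyNA(lw))
    stop("codons without wi values: ",
         paste(unique(codons[is.na(lw)]), collapse = ", "))
  exp(mean(lw))
}

#' stAI for every gene in a CDS table
#' @param df CDS data frame (gene_id, seq).
#' @param wi a \code{relative_adaptiveness}.
#' @param code a \code{genetic_code}.
#' @return data frame gene_id, stai (plus species/contig columns if present).
#' @export
genome_stai <- function(df, wi, code = genetic_code()) {
  stai <- vapply(df$seq, compute_stai, numeric(1), wi = wi, code = code,
                 USE.NAMES = FALSE)
  out <- df[, intersect(c("gene_id", "species", "contig"), names(df)),
            drop = FALSE]
  out$stai <- stai
  out
}

#' Frequency of the CTG codon in a coding sequence
#'
#' The CUG codon is reassigned (Ser or Ala) in two yeast clades; wi/stAI
#' computation deliberately ignores the reassignment, and this frequency is
#' the materiality check for that choice.
#'
#' @param seq DNA coding sequence.
#' @return count of CTG codons divided by total codons.
#' @export
cug_frequency <- function(seq) {
  codons <- split_codons(seq)
  if (length(codons) == 0) return(0)
  mean(codons == "CTG")
}

# Gene x sense-codon count matrix, start codon and stops excluded --
# the stAI of every gene is then exp(C %*% log(wi) / rowSums(C)).
codon_count_matrix <- function(seqs, code = genetic_code()) {
  codons <- sense_codons()
  counts <- t(vapply(seqs, function(s) {
    cod <- split_codons(s)[-1L]
    cod <- cod[!(cod %in% code$stop_codons)]
    tabulate(match(cod, codons), nbins = length(codons))
  }, numeric(length(codons))))
  colnames(counts) <- codons
  counts
}

#' Genome-wide translational-selection score (s-value)
#'
#' Rank correlation between gene stAI and a gene-level expression proxy.
#' For a binary proxy (membership in a reference set of highly expressed
#' genes, the default design) the appropriate rank correlation is the
#' rank-biserial correlation, 2 * AUC - 1, where AUC is the
#' Mann-Whitney probability that a reference gene out-ranks a background
#' gene: 1 when the reference set is fully top-ranked, 0 under no
#' selection, in [-1, 1] always. For a continuous proxy the Spearman
#' correlation is used.
#'
#' @param stai numeric vector of gene stAI values.
#' @param proxy numeric vector, same length; binary (two distinct values)
#'   or continuous.
#' @return s-value in [-1, 1].
#' @export
selection_s_value <- function(stai, proxy) {
  stopifnot(length(stai) == length(proxy))
  lv <- sort(unique(proxy))
  if (length(lv) == 2) {
    x <- stai[proxy == lv[2]]; y <- stai[proxy == lv[1]]
    r <- rank(c(x, y))
    u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    2 * u / (length(x) * length(y)) - 1
  } else {
    suppressWarnings(stats::cor(stai, proxy, method = "spearman"))
  }
}

#' Optimize wobble penalties against an expression proxy (S-test)
#'
#' Coordinate-wise grid search over the four wobble-class penalties in
#' [0, 1] (step \code{grid_step}, Watson-Crick pairings fixed at 0),
#' maximizing the rank correlation (\code{selection_s_value}) between gene
#' stAI and a gene-level expression proxy (by default membership in a
#' reference set of highly expressed genes such as ribosomal-protein
#' genes, scored 1 vs 0).
#' The achieved correlation is the genome-wide translational-selection
#' score (s-value); species with s-value >= \code{threshold} are treated as
#' under selection on codon usage. Deterministic: fixed evaluation order,
#' ties keep the current value.
#'
#' @param df CDS data frame (gene_id, seq) with at least 50 genes.
#' @param pool tRNA pool (anticodon -> tGCN).
#' @param proxy named numeric: gene_id -> expression proxy.
#' @param code a \code{genetic_code}.
#' @param threshold s-value pass threshold (default 0.5).
#' @param grid_step grid resolution for the penalties (default 0.01).
#' @param max_sweeps maximum coordinate sweeps (default 50).
#' @return list with \code{rules} (optimized wobble table), \code{s_value},
#'   \code{pass}, \code{converged}, and \code{wi} at the optimum.
#' @export
optimize_wobble_weights <- function(df, pool, proxy, code = genetic_code(),
                                    threshold = 0.5, grid_step = 0.01,
                                    max_sweeps = 50L) {
  if (nrow(df) < 50) stop("need at least 50 genes for the S-test")
  proxy <- proxy[df$gene_id]
  if (anyNA(proxy)) stop("proxy missing for some genes")
  counts <- codon_count_matrix(df$seq, code)
  totals <- rowSums(counts)
  if (any(totals == 0)) stop("gene with no scorable codons")
  objective <- function(svec) {
    rules <- default_wobble_rules(svec)
    wi <- tryCatch(compute_wi(pool, rules)$wi, error = function(e) NULL)
    if (is.null(wi)) return(-Inf)
    stai <- exp(drop(counts %*% log(wi)) / totals)
    selection_s_value(stai, proxy)
  }
  grid <- seq(0, 1, by = grid_step)
  svec <- c(GU = 0.41, IC = 0.28, IA = 0.9999, UG = 0.68)
  best <- objective(svec)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (cl in names(svec)) {
      vals <- vapply(grid, function(g) {
        cand <- svec; cand[cl] <- g; objective(cand)
      }, numeric(1))
      if (max(vals, na.rm = TRUE) > best + 1e-12) {
        svec[cl] <- grid[which.max(vals)]
        best <- max(vals, na.rm = TRUE)
        changed <- TRUE
      }
    }
    if (!changed) { converged <- TRUE; break }
  }
  if (!converged) warning("wobble-weight optimization did not converge in ",
                          max_sweeps, " sweeps; returning best so far")
  rules <- default_wobble_rules(svec)
  list(rules = rules, s_value = best, pass = !is.na(best) && best >= threshold,
       converged = converged, wi = compute_wi(pool, rules))
}
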