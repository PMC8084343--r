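#' Normalize stAI to genome-percentile estAI
#'
#' A gene's estAI is the fraction of genes in the same genome with stAI
#' strictly below its own (the empirical CDF rank): an estAI of 0.4 means
#' 40% of the genes in the genome are less optimized. Ties share the estAI
#' of the lowest tied member. Values range over {0, 1/N, ..., (N-1)/N}.
#'
#' @param genes data frame with columns gene_id and stai (>= 2 rows).
#' @param species optional species id.
#' @param selection optional S-test result (from
#'   \code{optimize_wobble_weights}) carried along for filtering.
#' @return object of class \code{species_profile}: list with \code{genes}
#'   (the input plus an \code{estai} column), \code{species},
#'   \code{s_value}, \code{pass}.
#' @export
estai_normalize <- function(genes, species = NA_character_, selection = NULL) {
  if (nrow(genes) < 2) stop("need at least 2 genes to build an estAI profile")
  n <- nrow(genes)
  genes$estai <- (rank(genes$stai, ties.method = "min") - 1) / n
  structure(
    list(genes = genes, species = species,
         s_value = if (is.null(selection)) NA_real_ else selection$s_value,
         pass = if (is.null(selection)) NA else selection$pass),
    class = "species_profile"
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat("Species profile", if (!is.na(x$species)) paste0("(", x$species, ")"),
      "-", nrow(x$genes), "genes; s-value:",
      format(x$s_value, digits = 3), "\n")
  invisible(x)
}

#' Representative copy of a multi-copy gene family
#'
#' When a genome carries several copies of a pathway gene, the copy with
#' the highest estAI represents the family; exact ties are broken by the
#' lexicographically smallest gene id. Also reports the max - min estAI gap
#' across copies.
#'
#' @param copies data frame with columns gene_id, estai (and optionally
#'   contig), one row per copy.
#' @return list with \code{representative} (one-row data frame) and
#'   \code{gap}.
#' @export
representative_copy <- function(copies) {
  if (nrow(copies) == 0) stop("no copies supplied")
  ord <- order(-copies$estai, copies$gene_id)
  list(representative = copies[ord[1L], , drop = FALSE],
       gap = max(copies$estai) - min(copies$estai))
}

#' Pathway completeness call
#' @param present character vector of gene families found in the genome.
#' @param required character vector of families defining the pathway
#'   (default the Leloir galactose pathway: GAL1, GAL10, GAL7).
#' @return "complete", "partial", or "absent".
#' @export
pathway_completeness <- function(present,
                                 required = c("GAL1", "GAL10", "GAL7")) {
  hit <- sum(required %in% present)
  if (hit == length(required)) "complete"
  else if (hit == 0) "absent"
  else "partial"
}

#' Assemble a per-species pathway assignment
#'
#' @param profile a \code{species_profile}.
#' @param family_table data frame mapping gene_id to family for this
#'   species's pathway genes.
#' @param required families defining the pathway.
#' @return object of class \code{pathway_assignment}: species, per-family
#'   copy tables, representative estAI per family, completeness, clustered
#'   flag (NA unless complete), and per-family estAI gap.
#' @export
pathway_profile <- function(profile, family_table,
                            required = c("GAL1", "GAL10", "GAL7")) {
  genes <- profile$genes
  fam_rows <- merge(family_table, genes, by = "gene_id")
  fams <- split(fam_rows, fam_rows$family)
  reps <- lapply(fams, representative_copy)
  assignment <- structure(
    list(species = profile$species,
         families = fams,
         representative = vapply(reps, function(r) r$representative$estai,
                                 numeric(1)),
         gap = vapply(reps, `[[`, numeric(1), "gap"),
         completeness = pathway_completeness(names(fams), required),
         required = required,
         clustered = NA),
    class = "pathway_assignment"
  )
  if (assignment$completeness == "complete")
    assignment$clustered <- detect_cluster(assignment)
  assignment
}

#' Detect a contig-colocalized pathway cluster
#'
#' TRUE iff some combination of one copy per required family shares a
#' single contig — equivalently, some contig appears in every family's
#' contig set. Requires a complete pathway.
#'
#' @param assignment a \code{pathway_assignment}.
#' @return logical.
#' @export
detect_cluster <- function(assignment) {
  if (assignment$completeness != "complete")
    stop("cluster detection requires a complete pathway")
  contig_sets <- lapply(assignment$families[assignment$required],
                        function(f) unique(stats::na.omit(f$contig)))
  if (any(vapply(contig_sets, length, integer(1)) == 0)) return(FALSE)
  length(Reduce(intersect, contig_sets)) > 0
}

#' Per-species pathway report rows
#' @param assignment a \code{pathway_assignment}.
#' @return data frame: species, family, representative estAI, gap, n
#'   copies, completeness, clustered.
#' @export
pathway_report <- function(assignment) {
  fams <- names(assignment$families)
  data.frame(
    species = assignment$species,
    family = fams,
    estai = unname(assignment$representative[fams]),
    gap = unname(assignment$gap[fams]),
    n_copies = vapply(assignment$families, nrow, integer(1)),
    completeness = assignment$completeness,
    clustered = assignment$clustered,
    stringsAsFactors = FALSE
  )
}
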