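#' Read and validate coding sequences from a FASTA file
#'
#' Record descriptions follow the convention \code{"geneid contig=CONTIG"};
#' a sidecar data frame (columns \code{gene_id}, \code{contig}) can override
#' or supply contig assignments. Sequences failing validation (length not a
#' multiple of 3, ambiguity codes, internal stop codons) are reported, not
#' silently dropped.
#'
#' @param path FASTA file of coding sequences for one species.
#' @param species species identifier attached to every record.
#' @param code a \code{genetic_code} used to locate internal stops.
#' @param contig_table optional data frame with columns gene_id, contig.
#' @param on_invalid "warn" (default) drops offending records with a
#'   warning; "error" stops. Length-not-divisible-by-3 is always an error.
#' @return data frame with columns gene_id, species, contig, seq.
#' @export
read_cds_fasta <- function(path, species, code = genetic_code(),
                           contig_table = NULL,
                           on_invalid = c("warn", "error")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) {
    warning("empty FASTA: ", path)
    return(data.frame(gene_id = character(0), species = character(0),
                      contig = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  hdr <- names(ss)
  gene_id <- vapply(strsplit(hdr, "\\s+"), `[`, character(1), 1L)
  contig <- sub(".*contig=(\\S+).*", "\\1", hdr)
  contig[!grepl("contig=", hdr)] <- NA_character_
  if (!is.null(contig_table)) {
    m <- match(gene_id, contig_table$gene_id)
    contig[!is.na(m)] <- contig_table$contig[m[!is.na(m)]]
  }
  seqs <- normalize_dna(as.character(ss))
  df <- data.frame(gene_id = gene_id, species = species, contig = contig,
                   seq = seqs, stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  validate_cds(df, code = code, on_invalid = on_invalid)
}

#' Validate a coding-sequence table
#'
#' @param df data frame with at least gene_id and seq columns.
#' @param code a \code{genetic_code}.
#' @param on_invalid "warn" drops records with ambiguity codes or internal
#'   stops (with a warning naming them); "error" stops instead.
#' @return the validated (possibly reduced) data frame.
#' @export
validate_cds <- function(df, code = genetic_code(),
                         on_invalid = c("warn", "error")) {
  on_invalid <- match.arg(on_invalid)
  len <- nchar(df$seq)
  bad_len <- df$gene_id[len %% 3L != 0L]
  if (length(bad_len) > 0)
    stop("sequence length not divisible by 3 for: ",
         paste(bad_len, collapse = ", "))
  ambiguous <- grepl("[^ACGT]", df$seq)
  internal_stop <- vapply(df$seq, function(s) {
    cods <- split_codons(s)
    any(cods[-length(cods)] %in% code$stop_codons)
  }, logical(1), USE.NAMES = FALSE)
  drop <- ambiguous | internal_stop
  if (any(drop)) {
    msg <- paste0("excluded ", sum(drop), " invalid CDS (",
                  sum(ambiguous), " with ambiguity codes, ",
                  sum(internal_stop), " with internal stops): ",
                  paste(utils::head(df$gene_id[drop], 10), collapse = ", "))
    if (on_invalid == "error") stop(msg)
    warning(msg)
  }
  df[!drop, , drop = FALSE]
}

#' Drop coding sequences shorter than a nucleotide threshold
#'
#' Sequences shorter than \code{min_nt} are removed (a sequence of exactly
#' \code{min_nt} is retained); the number removed is reported via message.
#'
#' @param df CDS data frame (gene_id, seq, ...).
#' @param min_nt minimum length in nucleotides, >= 3. Default 500, the
#'   cutoff used when scoring newly annotated genomes.
#' @return the filtered data frame.
#' @export
filter_min_length <- function(df, min_nt = 500L) {
  stopifnot(min_nt >= 3L)
  keep <- nchar(df$seq) >= min_nt
  if (any(!keep))
    message(sum(!keep), " CDS shorter than ", min_nt, " nt removed")
  df[keep, , drop = FALSE]
}

#' Read per-species tRNA gene copy numbers
#'
#' @param path TSV with columns species, anticodon, count. Anticodons may be
#'   in RNA or DNA alphabet; they are normalized to DNA. Duplicate
#'   (species, anticodon) rows are summed.
#' @return named list: species -> named integer vector (anticodon -> tGCN).
#' @export
read_trna_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("species", "anticodon", "count")
  if (!all(required %in% names(df)))
    stop("tRNA count table must have columns: ",
         paste(required, collapse = ", "))
  trna_pool_from_table(df)
}

#' Build tRNA pools from a long table
#' @param df data frame with columns species, anticodon, count.
#' @return named list of pools, as in \code{read_trna_counts}.
#' @export
trna_pool_from_table <- function(df) {
  df$anticodon <- normalize_dna(df$anticodon)
  bad <- grepl("[^ACGT]", df$anticodon) | nchar(df$anticodon) != 3L
  if (any(bad))
    stop("invalid anticodons: ", paste(unique(df$anticodon[bad]), collapse = ", "))
  if (any(df$count < 0))
    stop("negative tRNA gene copy numbers for: ",
         paste(unique(df$species[df$count < 0]), collapse = ", "))
  pools <- lapply(split(df, df$species), function(d) {
    v <- tapply(d$count, d$anticodon, sum)
    counts <- stats::setNames(as.integer(v), names(v))
    if (all(counts == 0))
      stop("tRNA pool with no positive copy number for species ",
           d$species[[1]])
    counts
  })
  pools
}

#' Write tRNA pools back to a long TSV-shaped table
#' @param pools named list as returned by \code{read_trna_counts}.
#' @return data frame with columns species, anticodon, count.
#' @export
trna_pool_to_table <- function(pools) {
  do.call(rbind, lapply(names(pools), function(sp) {
    data.frame(species = sp, anticodon = names(pools[[sp]]),
               count = as.integer(pools[[sp]]), stringsAsFactors = FALSE)
  }))
}

#' Write a CDS table to FASTA
#' @param df data frame with gene_id, contig, seq.
#' @param path output FASTA path.
#' @export
write_cds_fasta <- function(df, path) {
  ss <- Biostrings::DNAStringSet(df$seq)
  names(ss) <- ifelse(is.na(df$contig), df$gene_id,
                      paste0(df$gene_id, " contig=", df$contig))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
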