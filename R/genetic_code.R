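#' Genetic code tables with CUG-clade variants
#'
#' Builds a codon -> amino-acid table over the 64 DNA codons. Two yeast
#' clades translate CTG as serine (CUG-Ser) or alanine (CUG-Ala) instead of
#' leucine; the corresponding variants differ from the standard code only at
#' CTG. Stop codons are kept in the table (mapped to "*").
#'
#' @param variant one of "standard", "CUG-Ser", "CUG-Ala".
#' @return an object of class \code{genetic_code}: a list with
#'   \code{table} (named character vector of length 64, DNA codons),
#'   \code{variant}, and \code{stop_codons}.
#' @export
genetic_code <- function(variant = c("standard", "CUG-Ser", "CUG-Ala")) {
  variant <- match.arg(variant)
  tab <- Biostrings::GENETIC_CODE
  tab <- stats::setNames(as.character(tab), names(tab))
  if (variant == "CUG-Ser") tab[["CTG"]] <- "S"
  if (variant == "CUG-Ala") tab[["CTG"]] <- "A"
  structure(
    list(table = tab, variant = variant,
         stop_codons = names(tab)[tab == "*"]),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (", x$variant, "), ",
      sum(x$table != "*"), " sense codons, stops: ",
      paste(x$stop_codons, collapse = ", "), "\n", sep = "")
  invisible(x)
}

ALL_CODONS <- sort(names(Biostrings::GENETIC_CODE))

#' Split a DNA string into codons
#' @param seq a single DNA string, length divisible by 3.
#' @return character vector of 3-mers.
#' @export
split_codons <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3: ", n)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence
#' @param seq DNA string, length divisible by 3.
#' @param code a \code{genetic_code}.
#' @return amino-acid string ("*" for stops).
#' @export
translate_cds <- function(seq, code = genetic_code()) {
  codons <- split_codons(seq)
  bad <- setdiff(unique(codons), names(code$table))
  if (length(bad) > 0)
    stop("untranslatable codons: ", paste(bad, collapse = ", "))
  paste(code$table[codons], collapse = "")
}

#' Synonymous codon families of a genetic code
#' @param code a \code{genetic_code}.
#' @param include_stops keep the stop "family"?
#' @return named list: amino acid -> character vector of codons.
#' @export
synonym_families <- function(code = genetic_code(), include_stops = FALSE) {
  tab <- code$table
  if (!include_stops) tab <- tab[tab != "*"]
  split(names(tab), tab)
}

reverse_complement <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

normalize_dna <- function(x) chartr("Uu", "Tt", toupper(x))
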