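#' Genetic code with synonymous-family structure
#'
#' Builds a genetic-code object from an NCBI translation table, augmented with
#' the synonymous-family (degeneracy-class) partition that underlies Wright's
#' effective number of codons: every amino acid defines one family, with the
#' three six-fold amino acids (Leu, Ser, Arg) kept as single six-codon
#' families. The default is the bacterial/archaeal table 11 with start codons
#' ATG, GTG and TTG, which covers the common alternative initiators of
#' high-GC Actinobacteria.
#'
#' @param table_id NCBI genetic-code table identifier (default 11).
#' @param start_codons character vector of accepted initiation codons.
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character of all 64 codons, `"*"` for
#'   stop), `start_codons`, `stop_codons`, and `families` — a data.frame with
#'   one row per sense codon (`codon`, `aa`, `k` = family size).
#' @examples
#' code <- genetic_code()
#' table(unique(code$families[c("aa", "k")])$k)  # 2,9,1,5,3 families by class
#' @export
genetic_code <- function(table_id = 11L, start_codons = c("ATG", "GTG", "TTG")) {
  tab <- Biostrings::getGeneticCode(as.character(table_id))
  codon_to_aa <- as.character(tab)
  names(codon_to_aa) <- names(tab)
  stopifnot(length(codon_to_aa) == 64L)

  stop_codons <- names(codon_to_aa)[codon_to_aa == "*"]
  sense <- codon_to_aa[codon_to_aa != "*"]
  fam_size <- table(sense)
  families <- data.frame(
    codon = names(sense),
    aa = unname(sense),
    k = as.integer(fam_size[sense]),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      table_id = as.integer(table_id),
      codon_to_aa = codon_to_aa,
      start_codons = start_codons,
      stop_codons = stop_codons,
      families = families
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  classes <- table(unique(x$families[c("aa", "k")])$k)
  cat(sprintf("Genetic code table %d: %d sense codons, %d stops; families by class: %s\n",
              x$table_id, nrow(x$families), length(x$stop_codons),
              paste(sprintf("%sx%s", classes, names(classes)), collapse = ", ")))
  invisible(x)
}

# Split a nucleotide string into its codons (all of them, including any
# terminal stop; callers strip stops as needed).
split_codons <- function(nt) {
  n <- nchar(nt)
  if (n < 3L) return(character(0))
  n3 <- n - n %% 3L
  substring(nt, seq(1L, n3 - 2L, by = 3L), seq(3L, n3, by = 3L))
}
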