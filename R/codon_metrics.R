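# Per-gene codon usage statistics: Wright's family-homozygosity estimator of
# the effective number of codons (Nc), GC3/GC3s, Kyte-Doolittle GRAVY and the
# mutation-only Nc expectation curve.

#' Kyte-Doolittle hydropathy values
#'
#' The standard per-residue hydropathy scale, named by one-letter amino-acid
#' code. Positive = hydrophobic.
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Sense-codon counts for a valid CDS: every codon except the terminal stop,
# initiator included (it is a sense codon of its family, as codon-usage
# software counts it).
sense_codon_counts <- function(seq, code) {
  if (!isTRUE(seq$valid) || is_16s(seq))
    cub_stop("INVALID_CDS", sprintf("'%s' is not a valid protein CDS", seq$id))
  codons <- split_codons(seq$nucleotides)
  codons <- codons[-length(codons)]              # drop terminal stop
  counts <- table(factor(codons, levels = code$families$codon))
  stats::setNames(as.integer(counts), names(counts))
}

#' Synonymous-family homozygosity of a gene
#'
#' For each amino-acid family with codon observations \eqn{n \ge 2} and
#' within-family codon frequencies \eqn{\hat p_i}, the homozygosity estimate
#' is \eqn{\hat F = (n \sum \hat p_i^2 - 1)/(n - 1)}: 0 at perfect evenness
#' (n = 2), 1 at fixation. Families with \eqn{n < 2} are unusable and carry
#' `NA`. Class means \eqn{\bar F_k} average the usable families of each
#' degeneracy class \eqn{k \in \{2,3,4,6\}}.
#'
#' @param seq a valid [coding_sequence()].
#' @param code a [genetic_code()].
#' @return list with `families` (data.frame: `aa`, `k`, `n`, `sum_p2`,
#'   `F_hat`), `F_bar` (named numeric by class), and `usable_families`
#'   (named integer by class).
#' @export
family_homozygosity <- function(seq, code = genetic_code()) {
  counts <- sense_codon_counts(seq, code)
  fam <- code$families
  byaa <- split(counts[fam$codon], fam$aa)
  ks <- vapply(split(fam$k, fam$aa), `[`, integer(1), 1L)
  aa <- names(byaa)
  n <- vapply(byaa, sum, numeric(1))
  sum_p2 <- vapply(byaa, function(cts) {
    tot <- sum(cts)
    if (tot == 0) return(NA_real_)
    sum((cts / tot)^2)
  }, numeric(1))
  F_hat <- ifelse(n >= 2, (n * sum_p2 - 1) / (n - 1), NA_real_)
  families <- data.frame(aa = aa, k = ks[aa], n = n, sum_p2 = sum_p2,
                         F_hat = F_hat, row.names = NULL,
                         stringsAsFactors = FALSE)
  classes <- c(2L, 3L, 4L, 6L)
  F_bar <- vapply(classes, function(k) {
    f <- families$F_hat[families$k == k]
    f <- f[!is.na(f)]
    if (length(f) == 0L) NA_real_ else mean(f)
  }, numeric(1))
  usable <- vapply(classes, function(k)
    sum(!is.na(families$F_hat[families$k == k])), integer(1))
  list(families = families,
       F_bar = stats::setNames(F_bar, classes),
       usable_families = stats::setNames(usable, classes))
}

#' Effective number of codons (Nc)
#'
#' Wright's estimator by degeneracy-class decomposition:
#' \deqn{N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6}
#' (2 one-fold families, 9 two-fold, 1 three-fold, 5 four-fold, 3 six-fold in
#' the bacterial code). A class mean built from no usable family is imputed
#' as \eqn{(\bar F_2 + \bar F_4)/2} for the three-fold (and, in degenerate
#' short genes, the six-fold) class; if \eqn{\bar F_2} or \eqn{\bar F_4} is
#' itself unavailable the result is `NA` (MISSING). Raw values above the
#' theoretical maximum of 61 — a finite-sample artifact near perfectly even
#' usage — are capped at exactly 61, so results lie in [20, 61].
#'
#' @inheritParams family_homozygosity
#' @return Nc in [20, 61], or `NA` when not computable.
#' @export
effective_number_of_codons <- function(seq, code = genetic_code()) {
  fh <- family_homozygosity(seq, code)
  nc_from_fbar(fh$F_bar)
}

# class-weight decomposition; F_bar named by class ("2","3","4","6")
nc_from_fbar <- function(F_bar) {
  f2 <- F_bar[["2"]]; f3 <- F_bar[["3"]]; f4 <- F_bar[["4"]]; f6 <- F_bar[["6"]]
  if (is.na(f2) || is.na(f4)) return(NA_real_)
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  if (is.na(f6)) f6 <- (f2 + f4) / 2
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  if (!is.finite(nc) || nc > 61) nc <- 61
  nc
}

#' GC content at third codon positions
#'
#' `gc3()` is the fraction of G or C at the third position over all sense
#' codons (terminal stop excluded). `gc3s()` restricts to codons belonging to
#' synonymous families (degeneracy class \eqn{k \ge 2}, i.e. excluding Met
#' and Trp), the variant reported by CodonW; it is `NA` for a gene composed
#' solely of one-fold codons.
#'
#' @inheritParams family_homozygosity
#' @return fraction in [0, 1] (or `NA` for an empty gc3s denominator).
#' @export
gc3 <- function(seq, code = genetic_code()) {
  counts <- sense_codon_counts(seq, code)
  third <- substr(names(counts), 3L, 3L)
  sum(counts[third %in% c("G", "C")]) / sum(counts)
}

#' @rdname gc3
#' @export
gc3s <- function(seq, code = genetic_code()) {
  counts <- sense_codon_counts(seq, code)
  keep <- code$families$k >= 2L
  counts <- counts[code$families$codon[keep]]
  tot <- sum(counts)
  if (tot == 0L) return(NA_real_)
  third <- substr(names(counts), 3L, 3L)
  sum(counts[third %in% c("G", "C")]) / tot
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy of the translated protein (stop excluded,
#' initiator included and translated by the code table). Values below zero
#' indicate a hydrophilic product, above zero a hydrophobic one.
#'
#' @inheritParams family_homozygosity
#' @return dimensionless mean hydropathy.
#' @seealso [kyte_doolittle_gravy()] for the protein-level computation.
#' @export
gravy <- function(seq, code = genetic_code()) {
  counts <- sense_codon_counts(seq, code)
  aa <- code$codon_to_aa[names(counts)]
  sum(counts * KYTE_DOOLITTLE[aa]) / sum(counts)
}

#' @param aa amino-acid sequence, as a single string or character vector of
#'   one-letter codes.
#' @rdname gravy
#' @export
kyte_doolittle_gravy <- function(aa) {
  if (length(aa) == 1L && nchar(aa) > 1L) aa <- strsplit(aa, "")[[1]]
  v <- KYTE_DOOLITTLE[aa]
  if (anyNA(v)) cub_stop("DOMAIN", "unknown amino-acid code")
  mean(v)
}

#' Mutation-only expectation curve of the Nc plot
#'
#' Expected Nc when codon usage bias is driven solely by mutational GC
#' pressure at silent sites: \eqn{N_c(s) = 2 + s + 29/(s^2 + (1-s)^2)} where
#' `s` is GC3. Symmetric about s = 0.5 with maximum 60.5; genes falling well
#' below the curve indicate selection on codon usage.
#'
#' @param s GC3 value(s) in [0, 1].
#' @return expected Nc (vectorized).
#' @export
nc_null_curve <- function(s) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    cub_stop("DOMAIN", "s must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Per-gene codon usage metrics
#'
#' Computes Nc, GC3, GC3s, GRAVY and gene length (in sense codons, stop
#' excluded) for one valid CDS; `computable` is `FALSE` when Nc is undefined.
#'
#' @inheritParams family_homozygosity
#' @return one-row data.frame with columns `gene_id`, `gene_symbol`,
#'   `length_codons`, `nc`, `gc3`, `gc3s`, `gravy`, `computable`.
#' @export
gene_metrics <- function(seq, code = genetic_code()) {
  counts <- sense_codon_counts(seq, code)
  nc <- effective_number_of_codons(seq, code)
  data.frame(
    gene_id = seq$id,
    gene_symbol = seq$gene_symbol,
    length_codons = sum(counts),
    nc = nc,
    gc3 = gc3(seq, code),
    gc3s = gc3s(seq, code),
    gravy = gravy(seq, code),
    computable = !is.na(nc),
    stringsAsFactors = FALSE
  )
}

#' Codon usage metrics for every valid protein CDS of a genome
#'
#' @param genome a [genome_record()] (or plain list of [coding_sequence()]
#'   records). Invalid records and 16S rRNA entries are skipped.
#' @param code a [genetic_code()].
#' @return data.frame, one row per gene, as in [gene_metrics()].
#' @export
genome_metrics <- function(genome, code = genetic_code()) {
  cds <- if (inherits(genome, "genome_record")) genome$cds else genome
  keep <- vapply(cds, function(s) isTRUE(s$valid) && !is_16s(s), logical(1))
  rows <- lapply(cds[keep], gene_metrics, code = code)
  if (length(rows) == 0L) cub_stop("NO_DATA", "no valid protein CDS")
  do.call(rbind, rows)
}
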