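#' Construct a coding-sequence record
#'
#' Normalizes the nucleotide string (uppercase, RNA `U` mapped to `T`) and
#' stores the gene symbol when known. Validation state is filled in by
#' [validate_cds()].
#'
#' @param id record identifier.
#' @param nucleotides nucleotide string.
#' @param gene_symbol optional gene symbol (e.g. `"rpoB"`, `"16S"`).
#' @return An object of class `coding_sequence`.
#' @export
coding_sequence <- function(id, nucleotides, gene_symbol = NA_character_) {
  nt <- chartr("u", "U", toupper(as.character(nucleotides)))
  nt <- gsub("U", "T", nt, fixed = TRUE)
  structure(
    list(id = as.character(id), gene_symbol = as.character(gene_symbol),
         nucleotides = nt, valid = NA, rejection_reasons = character(0)),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s%s: %d nt, valid=%s%s\n", x$id,
              if (!is.na(x$gene_symbol)) paste0(" [", x$gene_symbol, "]") else "",
              nchar(x$nucleotides), x$valid,
              if (length(x$rejection_reasons))
                paste0(" (", paste(x$rejection_reasons, collapse = ","), ")")
              else ""))
  invisible(x)
}

is_16s <- function(seq) {
  !is.na(seq$gene_symbol) && toupper(seq$gene_symbol) %in% c("16S", "16S_RRNA", "RRS")
}

#' Validate a coding sequence against a genetic code
#'
#' A CDS is valid when its length is a multiple of three, its first codon is
#' an accepted initiation codon, its last codon is a stop, it contains no
#' internal stop and no ambiguity letters. All applicable rejection reasons
#' are recorded (`AMBIGUOUS`, `FRAME`, `BAD_START`, `NO_STOP`,
#' `INTERNAL_STOP`); validation is idempotent. Records carrying the gene
#' symbol `16S` are ribosomal-RNA sequences, not protein CDS, and bypass the
#' start/stop/frame checks (only the alphabet is checked).
#'
#' @param seq a [coding_sequence()].
#' @param code a [genetic_code()].
#' @return the record with `valid` and `rejection_reasons` filled in.
#' @export
validate_cds <- function(seq, code = genetic_code()) {
  nt <- seq$nucleotides
  if (nchar(nt) == 0L) cub_stop("DOMAIN", "empty nucleotide sequence")
  reasons <- character(0)
  clean <- !grepl("[^ACGT]", nt)
  if (!clean) reasons <- c(reasons, "AMBIGUOUS")

  if (!is_16s(seq)) {
    if (nchar(nt) %% 3L != 0L) reasons <- c(reasons, "FRAME")
    if (clean && nchar(nt) >= 3L) {
      codons <- split_codons(nt)
      if (!(codons[1L] %in% code$start_codons)) reasons <- c(reasons, "BAD_START")
      if (nchar(nt) %% 3L == 0L) {
        is_stop <- codons %in% code$stop_codons
        n <- length(codons)
        if (!is_stop[n]) reasons <- c(reasons, "NO_STOP")
        if (n > 1L && any(is_stop[-n])) reasons <- c(reasons, "INTERNAL_STOP")
      }
    }
  }
  seq$valid <- length(reasons) == 0L
  seq$rejection_reasons <- sort(unique(reasons))
  seq
}

parse_gene_symbol <- function(header) {
  m <- regmatches(header, regexec("\\[gene=([^]]+)\\]", header, ignore.case = TRUE))[[1]]
  if (length(m) == 2L) return(m[2])
  m <- regmatches(header, regexec("(?:^|[[:space:];])gene=([^][[:space:];]+)", header,
                                  ignore.case = TRUE))[[1]]
  if (length(m) == 2L) return(m[2])
  fields <- strsplit(header, "|", fixed = TRUE)[[1]]
  hit <- which(tolower(fields) == "gene")
  if (length(hit) && hit[1] < length(fields)) return(fields[hit[1] + 1L])
  NA_character_
}

#' Read a CDS set from a nucleotide FASTA file
#'
#' One [coding_sequence()] per record. Gene symbols are parsed
#' case-insensitively from `gene=<symbol>` or `[gene=<symbol>]` header tokens
#' or a `|gene|<symbol>` field (first match wins). Every record is validated
#' with [validate_cds()]; records containing ambiguity letters come back with
#' `valid = FALSE` and reason `AMBIGUOUS`.
#'
#' @param path FASTA file path.
#' @param code a [genetic_code()].
#' @param quiet suppress the per-file validation summary on stderr.
#' @return list of validated `coding_sequence` records.
#' @export
read_cds_fasta <- function(path, code = genetic_code(), quiet = FALSE) {
  if (!file.exists(path)) cub_stop("IO", sprintf("cannot read '%s'", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) cub_stop("EMPTY_INPUT",
                    sprintf("no FASTA records in '%s' (%s)", path, conditionMessage(e))))
  if (length(set) == 0L) cub_stop("EMPTY_INPUT", sprintf("no FASTA records in '%s'", path))
  headers <- names(set)
  seqs <- as.character(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    id <- sub("[[:space:]].*$", "", headers[i])
    cds <- coding_sequence(id, seqs[i], parse_gene_symbol(headers[i]))
    out[[i]] <- validate_cds(cds, code)
  }
  if (!quiet) {
    nv <- sum(vapply(out, `[[`, logical(1), "valid"))
    cub_log("read_cds_fasta: %s: %d records, %d valid, %d rejected",
            basename(path), length(out), nv, length(out) - nv)
  }
  out
}

#' Write coding sequences to FASTA
#'
#' Headers carry the record id and, when present, a `gene=<symbol>` token, so
#' that [read_cds_fasta()] round-trips sequences and symbols exactly.
#'
#' @param cds list of [coding_sequence()] records.
#' @param path output file.
#' @export
write_cds_fasta <- function(cds, path) {
  headers <- vapply(cds, function(s) {
    if (!is.na(s$gene_symbol)) sprintf("%s gene=%s", s$id, s$gene_symbol) else s$id
  }, character(1))
  seqs <- vapply(cds, `[[`, character(1), "nucleotides")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a genome record
#'
#' @param species,strain identity (unique within a collection).
#' @param gram `"negative"` or `"positive"`.
#' @param genome_length_bp genome length in base pairs.
#' @param cds list of validated [coding_sequence()] records.
#' @param taxon_labels named character vector (rank -> name).
#' @return object of class `genome_record`.
#' @export
genome_record <- function(species, strain, gram, genome_length_bp, cds = list(),
                          taxon_labels = character(0)) {
  gram <- match.arg(gram, c("negative", "positive"))
  structure(
    list(species = species, strain = strain, gram = gram,
         taxon_labels = taxon_labels,
         genome_length_bp = as.numeric(genome_length_bp), cds = cds),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  nv <- sum(vapply(x$cds, `[[`, logical(1), "valid"))
  cat(sprintf("<genome_record> %s %s (Gram %s): %d CDS (%d valid), %.3g bp\n",
              x$species, x$strain, x$gram, length(x$cds), nv, x$genome_length_bp))
  invisible(x)
}

#' Extract housekeeping genes from a genome
#'
#' For each requested gene symbol returns the unique valid CDS carrying it
#' (matched case-insensitively), or `NULL` when absent. When several valid
#' copies exist the longest is chosen and a warning is logged.
#'
#' @param genome a [genome_record()].
#' @param names gene symbols to extract (non-empty).
#' @return named list, one entry per requested symbol (`NULL` when absent).
#' @export
extract_housekeeping <- function(genome,
                                 names = c("rpoB", "atpD", "infB", "trpB")) {
  if (length(names) == 0L) cub_stop("DOMAIN", "no gene symbols requested")
  syms <- vapply(genome$cds, `[[`, character(1), "gene_symbol")
  valid <- vapply(genome$cds, `[[`, logical(1), "valid")
  out <- stats::setNames(vector("list", length(names)), names)
  for (g in names) {
    hit <- which(valid & !is.na(syms) & tolower(syms) == tolower(g))
    if (length(hit) == 0L) next
    if (length(hit) > 1L) {
      lens <- vapply(genome$cds[hit], function(s) nchar(s$nucleotides), numeric(1))
      warning(sprintf("%s %s: %d valid copies of %s; keeping the longest (%d nt)",
                      genome$species, genome$strain, length(hit), g, max(lens)),
              call. = FALSE)
      hit <- hit[which.max(lens)]
    }
    out[[g]] <- genome$cds[[hit]]
  }
  out
}

METADATA_COLUMNS <- c("species", "strain", "gram", "phylum", "class",
                      "genome_length_bp", "cds_fasta_path")

#' Read a genome metadata table
#'
#' Tab-separated with mandatory columns `species`, `strain`, `gram`,
#' `phylum`, `class`, `genome_length_bp`, `cds_fasta_path`. Rows with
#' unparseable fields (e.g. a Gram value outside negative/positive) are kept
#' with `NA` and the problem recorded in the `row_errors` attribute.
#'
#' @param path TSV path.
#' @return data.frame of genome stubs with attribute `row_errors`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) cub_stop("IO", sprintf("cannot read '%s'", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(METADATA_COLUMNS, names(df))
  if (length(missing))
    cub_stop("SCHEMA", paste("missing mandatory column(s):",
                             paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) cub_stop("EMPTY_INPUT", "metadata table has no rows")
  errors <- character(0)
  gram <- tolower(trimws(df$gram))
  bad <- which(!gram %in% c("negative", "positive"))
  if (length(bad)) {
    errors <- c(errors, sprintf("row %d: unrecognized gram value '%s'", bad, df$gram[bad]))
    gram[bad] <- NA_character_
  }
  df$gram <- gram
  df$genome_length_bp <- suppressWarnings(as.numeric(df$genome_length_bp))
  nn <- which(is.na(df$genome_length_bp))
  if (length(nn)) errors <- c(errors, sprintf("row %d: bad genome_length_bp", nn))
  key <- paste(df$species, df$strain)
  if (anyDuplicated(key))
    errors <- c(errors, sprintf("duplicate species+strain: %s", key[duplicated(key)]))
  attr(df, "row_errors") <- errors
  df
}

#' Load a full genome record from a metadata stub
#'
#' @param stub one row of [read_metadata()] output (data.frame or list).
#' @param code a [genetic_code()].
#' @param base_dir directory against which relative `cds_fasta_path` values
#'   are resolved.
#' @return a [genome_record()].
#' @export
load_genome <- function(stub, code = genetic_code(), base_dir = ".") {
  p <- stub$cds_fasta_path
  if (!file.exists(p)) p <- file.path(base_dir, p)
  cds <- read_cds_fasta(p, code)
  genome_record(stub$species, stub$strain, stub$gram, stub$genome_length_bp,
                cds = cds,
                taxon_labels = c(phylum = stub$phylum, class = stub$class))
}
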