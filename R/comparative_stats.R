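# Genome-level aggregation, housekeeping-gene contrasts, rank-based tests and
# Nc-plot classification.

#' Genome-level codon usage summary
#'
#' Aggregates per-gene metrics into one summary row: means and sample
#' standard deviations (n-1 denominator) of Nc and GC3 over the computable
#' genes, plus coding statistics — total valid-CDS bases, genome-wide G+C
#' fraction of those coding bases, and coding frequency (coding bases over
#' genome length). 16S rRNA records are not CDS and are excluded from the
#' coding statistics.
#'
#' @param metrics data.frame from [genome_metrics()].
#' @param genome the [genome_record()] the metrics came from.
#' @return one-row data.frame: `species`, `strain`, `gram`, `nc_avg`,
#'   `nc_sd`, `gc3_avg`, `gc3_sd`, `gc_content`, `coding_bases`,
#'   `genome_length_bp`, `coding_frequency`, `n_genes`.
#' @export
summarize_genome <- function(metrics, genome) {
  m <- metrics[metrics$computable, , drop = FALSE]
  if (nrow(m) == 0L) cub_stop("NO_DATA", "no computable genes in genome")
  cds <- Filter(function(s) isTRUE(s$valid) && !is_16s(s), genome$cds)
  nts <- vapply(cds, `[[`, character(1), "nucleotides")
  coding_bases <- sum(nchar(nts))
  gc_bases <- sum(vapply(nts, function(x) {
    sum(strsplit(x, "")[[1]] %in% c("G", "C"))
  }, numeric(1)))
  sdn <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)
  data.frame(
    species = genome$species, strain = genome$strain, gram = genome$gram,
    nc_avg = mean(m$nc), nc_sd = sdn(m$nc),
    gc3_avg = mean(m$gc3), gc3_sd = sdn(m$gc3),
    gc_content = gc_bases / coding_bases,
    coding_bases = coding_bases,
    genome_length_bp = genome$genome_length_bp,
    coding_frequency = coding_bases / genome$genome_length_bp,
    n_genes = length(cds),
    stringsAsFactors = FALSE
  )
}

#' Housekeeping-gene codon usage profile
#'
#' Contrasts each housekeeping gene against its host genome: the genic Nc,
#' GC3 and GRAVY, the deltas `nc_avg - genic_nc` and `gc3_avg - genic_gc3`,
#' and the percentage of the genome's computable genes whose Nc lies below
#' the genic Nc. Absent genes propagate `NA` (MISSING) through every derived
#' field.
#'
#' @param summary one-row data.frame from [summarize_genome()].
#' @param hk_metrics named list (symbol -> one-row [gene_metrics()] data.frame
#'   or `NULL` when absent), e.g. built from [extract_housekeeping()] output.
#' @param all_metrics full [genome_metrics()] table of the same genome.
#' @return data.frame with one row per requested symbol: `species`, `strain`,
#'   `gene`, `genic_nc`, `delta_nc`, `genic_gc3`, `delta_gc3`, `genic_gravy`,
#'   `genic_length`, `pct_below_genic_nc`.
#' @export
housekeeping_profile <- function(summary, hk_metrics, all_metrics) {
  nc_all <- all_metrics$nc[all_metrics$computable]
  rows <- lapply(names(hk_metrics), function(g) {
    gm <- hk_metrics[[g]]
    if (is.null(gm) || nrow(gm) == 0L || is.na(gm$nc)) {
      return(data.frame(species = summary$species, strain = summary$strain,
                        gene = g, genic_nc = NA_real_, delta_nc = NA_real_,
                        genic_gc3 = NA_real_, delta_gc3 = NA_real_,
                        genic_gravy = NA_real_, genic_length = NA_real_,
                        pct_below_genic_nc = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(
      species = summary$species, strain = summary$strain, gene = g,
      genic_nc = gm$nc, delta_nc = summary$nc_avg - gm$nc,
      genic_gc3 = gm$gc3, delta_gc3 = summary$gc3_avg - gm$gc3,
      genic_gravy = gm$gravy, genic_length = gm$length_codons,
      pct_below_genic_nc = 100 * sum(nc_all < gm$nc) / length(nc_all),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

drop_missing_pairs <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  list(x = x[keep], y = y[keep])
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank (mid-rank) tie handling; MISSING pairs
#' are dropped pairwise. The two-sided p-value uses the exact permutation
#' distribution for tie-free samples of n <= 9 and the t approximation
#' otherwise.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p_value`, `n` and `method`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) cub_stop("SCHEMA", "x and y lengths differ")
  d <- drop_missing_pairs(x, y)
  n <- length(d$x)
  if (n < 3L) cub_stop("NO_DATA", "fewer than 3 complete pairs")
  ties <- anyDuplicated(d$x) > 0L || anyDuplicated(d$y) > 0L
  exact <- n <= 9L && !ties
  ct <- suppressWarnings(
    stats::cor.test(d$x, d$y, method = "spearman", exact = exact)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       method = if (exact) "exact_permutation" else "t_approximation")
}

#' Kruskal-Wallis rank test
#'
#' One-way analysis of variance on ranks with tie correction;
#' p from the chi-square approximation with `length(groups) - 1` df.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty,
#'   total n >= 5).
#' @return list with `test`, `statistic` (H), `df`, `p_value`, `group_sizes`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- lengths(groups)
  if (length(groups) < 2L || any(sizes == 0L) || sum(sizes) < 5L)
    cub_stop("NO_DATA", "need >= 2 non-empty groups, total n >= 5")
  kt <- stats::kruskal.test(unlist(groups),
                            factor(rep(seq_along(groups), sizes)))
  list(test = "kruskal_wallis", statistic = unname(kt$statistic),
       df = unname(kt$parameter), p_value = kt$p.value,
       group_sizes = unname(sizes))
}

#' Mann-Whitney rank-sum test
#'
#' Reports U = min(U1, U2). The two-sided p-value is exact (full enumeration
#' of the rank-sum distribution) for tie-free samples with n1*n2 <= 400 and
#' otherwise uses the normal approximation with tie and continuity
#' correction. Two identical constant samples — where neither route is
#' defined — yield U = n1*n2/2 and p = 1.
#'
#' @param a,b numeric vectors (each non-empty).
#' @return list with `test`, `statistic` (U), `p_value`, `group_sizes`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) cub_stop("NO_DATA", "both groups must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(list(test = "mann_whitney", statistic = n1 * n2 / 2, p_value = 1,
                group_sizes = c(n1, n2), method = "degenerate"))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && n1 * n2 <= 400L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  u1 <- unname(wt$statistic)               # wilcox.test W is U for sample a
  u <- min(u1, n1 * n2 - u1)
  list(test = "mann_whitney", statistic = u, p_value = wt$p.value,
       group_sizes = c(n1, n2),
       method = if (exact) "exact_enumeration" else "normal_approximation")
}

#' Nc-plot classification of a genome
#'
#' Labels the aggregation of a genome's genes on the Nc-vs-GC3 plane by mean
#' GC3 — left (< 1/3), mid (1/3 to 2/3) or right (> 2/3) centric, thresholds
#' calibrated to the canonical exemplar regimes at GC3 of roughly 0.10, 0.47
#' and 0.95 — and reports the fraction of genes falling below the
#' mutation-only expectation [nc_null_curve()], the signature of selection on
#' codon usage.
#'
#' @param metrics data.frame from [genome_metrics()].
#' @return list with `label` (`"left"`, `"mid"` or `"right"`),
#'   `fraction_below_null`, `n_genes` and `mean_gc3`.
#' @export
classify_nc_plot <- function(metrics) {
  m <- metrics[metrics$computable, , drop = FALSE]
  if (nrow(m) == 0L) cub_stop("NO_DATA", "no computable genes")
  mean_gc3 <- mean(m$gc3)
  label <- if (mean_gc3 < 1 / 3) "left" else if (mean_gc3 > 2 / 3) "right" else "mid"
  list(label = label,
       fraction_below_null = mean(m$nc < nc_null_curve(m$gc3)),
       n_genes = nrow(m), mean_gc3 = mean_gc3)
}

#' Genome-collection correlation panel
#'
#' The standard cross-genome Spearman comparisons: Nc_avg against genome
#' size, coding bases and coding GC content; genome size against coding
#' frequency; coding frequency against GC content. Pairwise-complete.
#'
#' @param summaries data.frame of [summarize_genome()] rows.
#' @param adjust optional p-value adjustment method passed to
#'   [stats::p.adjust()] (default none, raw p-values).
#' @return data.frame: `comparison`, `rho`, `p_value`, `n`.
#' @export
genome_correlations <- function(summaries, adjust = "none") {
  pairs <- list(
    c("nc_avg", "genome_length_bp"),
    c("nc_avg", "coding_bases"),
    c("nc_avg", "gc_content"),
    c("genome_length_bp", "coding_frequency"),
    c("coding_frequency", "gc_content")
  )
  rows <- lapply(pairs, function(p) {
    r <- spearman_cor(summaries[[p[1]]], summaries[[p[2]]])
    data.frame(comparison = paste(p[1], "vs", p[2]), rho = r$rho,
               p_value = r$p_value, n = r$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out
}
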