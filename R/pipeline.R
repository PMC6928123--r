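# End-to-end orchestration: genome-level summary tables, housekeeping-gene
# tables, the statistics report, Nc-plot classification and the per-gene
# phylogenetics run.

#' Pipeline run configuration
#'
#' Exactly one of `metadata` (path to a [read_metadata()] TSV) or `simulate`
#' (a list of [simulate_collection()] arguments) must be given.
#'
#' @param metadata path to a genome metadata TSV.
#' @param simulate list of arguments for [simulate_collection()].
#' @param housekeeping gene symbols profiled against each genome.
#' @param gc3_variant `"gc3"` (all sense codons, the default) or `"gc3s"`
#'   (synonymous families only).
#' @param model distance model for the phylogenetics stage.
#' @param bootstrap bootstrap replicates (>= 1).
#' @param seed integer seed funnelling all randomness.
#' @param table_parity reproduce the legacy table convention: absent genes
#'   print 0.00 (with delta = nc_avg) and values are rounded to 2 decimals.
#' @param outdir output directory.
#' @param make_plots write PDF Nc plots in [run_ncplot()].
#' @return list of class `run_config`.
#' @export
run_config <- function(metadata = NULL, simulate = NULL,
                       housekeeping = c("rpoB", "atpD", "infB", "trpB"),
                       gc3_variant = c("gc3", "gc3s"),
                       model = "k2p", bootstrap = 1000L, seed = 1L,
                       table_parity = FALSE, outdir = "cubphylo_out",
                       make_plots = TRUE) {
  if (is.null(metadata) == is.null(simulate))
    cub_stop("SCHEMA", "exactly one of 'metadata' or 'simulate' must be given")
  if (bootstrap < 1L) cub_stop("DOMAIN", "bootstrap must be >= 1")
  structure(list(metadata = metadata, simulate = simulate,
                 housekeeping = housekeeping,
                 gc3_variant = match.arg(gc3_variant), model = model,
                 bootstrap = as.integer(bootstrap), seed = as.integer(seed),
                 table_parity = isTRUE(table_parity), outdir = outdir,
                 make_plots = isTRUE(make_plots)),
            class = "run_config")
}

load_config_genomes <- function(config, code = genetic_code()) {
  if (!is.null(config$metadata)) {
    md <- read_metadata(config$metadata)
    lapply(seq_len(nrow(md)), function(i)
      load_genome(md[i, , drop = FALSE], code,
                  base_dir = dirname(config$metadata)))
  } else {
    args <- config$simulate
    args$seed <- args$seed %||% config$seed
    do.call(simulate_collection, args)$genomes
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parity_round <- function(df, cols) {
  for (cc in intersect(cols, names(df))) df[[cc]] <- round(df[[cc]], 2)
  df
}

#' Run the codon-usage profiling stage
#'
#' Computes per-gene metrics, the per-genome summary table (one row per
#' genome, sorted by species), the housekeeping-gene table (one row per
#' genome x gene) and the statistics report: the collection-level Spearman
#' panel, Kruskal-Wallis comparisons of each metric across the four
#' housekeeping genes, and Mann-Whitney comparisons of each housekeeping
#' metric between Gram groups. All tables are written as TSV under
#' `config$outdir` with explicit MISSING sentinels (or legacy 0.00 parity
#' formatting when `table_parity` is set).
#'
#' @param config a [run_config()].
#' @param code a [genetic_code()].
#' @return (invisibly) list with `summaries`, `housekeeping`, `gene_metrics`,
#'   `correlations`, `kruskal`, `mann_whitney`, `genomes`.
#' @export
run_profile <- function(config, code = genetic_code()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cub_log("run_profile: gc3_variant=%s table_parity=%s seed=%d",
          config$gc3_variant, config$table_parity, config$seed)
  genomes <- load_config_genomes(config, code)

  per_gene <- list(); summaries <- list(); hk_rows <- list()
  for (g in genomes) {
    metrics <- genome_metrics(g, code)
    if (config$gc3_variant == "gc3s") metrics$gc3 <- metrics$gc3s
    key <- paste(g$species, g$strain)
    metrics$species <- g$species; metrics$strain <- g$strain
    per_gene[[key]] <- metrics
    summ <- summarize_genome(metrics, g)
    summaries[[key]] <- summ
    hk <- extract_housekeeping(g, config$housekeeping)
    hk_metrics <- lapply(hk, function(s) if (is.null(s)) NULL else gene_metrics(s, code))
    hk_rows[[key]] <- housekeeping_profile(summ, hk_metrics, metrics)
  }
  summaries <- do.call(rbind, summaries)
  summaries <- summaries[order(summaries$species, summaries$strain), ]
  rownames(summaries) <- NULL
  hk_table <- do.call(rbind, hk_rows)
  hk_table <- hk_table[order(hk_table$species, hk_table$strain, hk_table$gene), ]
  rownames(hk_table) <- NULL
  gene_table <- do.call(rbind, per_gene)
  rownames(gene_table) <- NULL

  correlations <- tryCatch(genome_correlations(summaries),
                           NO_DATA = function(e) NULL)

  metrics_by_gene <- function(col) {
    lapply(split(hk_table[[col]], hk_table$gene), function(v) v[!is.na(v)])
  }
  kw <- lapply(c(genic_nc = "genic_nc", genic_gc3 = "genic_gc3",
                 genic_length = "genic_length", genic_gravy = "genic_gravy"),
               function(col) tryCatch(kruskal_wallis(metrics_by_gene(col)),
                                      NO_DATA = function(e) NULL))
  gram_of <- stats::setNames(summaries$gram, paste(summaries$species, summaries$strain))
  hk_gram <- gram_of[paste(hk_table$species, hk_table$strain)]
  mw <- list()
  for (gene in unique(hk_table$gene)) {
    for (col in c("genic_nc", "genic_gc3", "genic_length", "genic_gravy")) {
      sel <- hk_table$gene == gene
      a <- hk_table[[col]][sel & hk_gram == "negative"]
      b <- hk_table[[col]][sel & hk_gram == "positive"]
      mw[[paste(gene, col, sep = ".")]] <-
        tryCatch(mann_whitney(a, b), NO_DATA = function(e) NULL)
    }
  }

  out_summ <- summaries; out_hk <- hk_table
  if (config$table_parity) {
    absent <- is.na(out_hk$genic_nc)
    out_hk$genic_nc[absent] <- 0
    out_hk$genic_gc3[absent] <- 0
    nc_avg <- stats::setNames(summaries$nc_avg,
                              paste(summaries$species, summaries$strain))
    gc3_avg <- stats::setNames(summaries$gc3_avg,
                               paste(summaries$species, summaries$strain))
    keyv <- paste(out_hk$species, out_hk$strain)
    out_hk$delta_nc[absent] <- nc_avg[keyv[absent]]
    out_hk$delta_gc3[absent] <- gc3_avg[keyv[absent]]
    num <- c("genic_nc", "delta_nc", "genic_gc3", "delta_gc3", "genic_gravy",
             "pct_below_genic_nc")
    out_hk <- parity_round(out_hk, num)
    out_summ <- parity_round(out_summ, c("nc_avg", "nc_sd", "gc3_avg",
                                         "gc3_sd", "gc_content",
                                         "coding_frequency"))
  }
  write_cub_tsv(out_summ, file.path(config$outdir, "genome_summary.tsv"))
  write_cub_tsv(out_hk, file.path(config$outdir, "housekeeping_profile.tsv"))
  write_cub_tsv(gene_table, file.path(config$outdir, "gene_metrics.tsv"))
  if (!is.null(correlations))
    write_cub_tsv(correlations, file.path(config$outdir, "correlations.tsv"))
  stats_rows <- c(
    lapply(names(kw), function(k) {
      r <- kw[[k]]
      if (is.null(r)) return(NULL)
      data.frame(test = "kruskal_wallis", comparison = k,
                 statistic = r$statistic, df = r$df, p_value = r$p_value,
                 stringsAsFactors = FALSE)
    }),
    lapply(names(mw), function(k) {
      r <- mw[[k]]
      if (is.null(r)) return(NULL)
      data.frame(test = "mann_whitney", comparison = k,
                 statistic = r$statistic, df = NA_real_, p_value = r$p_value,
                 stringsAsFactors = FALSE)
    })
  )
  stats_df <- do.call(rbind, Filter(Negate(is.null), stats_rows))
  if (!is.null(stats_df))
    write_cub_tsv(stats_df, file.path(config$outdir, "rank_tests.tsv"))

  invisible(list(summaries = summaries, housekeeping = hk_table,
                 gene_metrics = gene_table, correlations = correlations,
                 kruskal = kw, mann_whitney = mw, genomes = genomes))
}

#' Run the Nc-plot classification stage
#'
#' Classifies each genome's aggregation on the Nc-vs-GC3 plane, reports the
#' fraction of genes below the mutation-only expectation curve and the
#' resulting selection-versus-mutation call (selection when the majority of
#' genes fall below the curve), and optionally draws the per-genome and
#' combined Nc plots with the null curve overlaid (PDF).
#'
#' @param config a [run_config()].
#' @param profile optional result of [run_profile()] (recomputed if absent).
#' @param code a [genetic_code()].
#' @return (invisibly) data.frame: per-genome `label`,
#'   `fraction_below_null`, `n_genes`, `mean_gc3`, `pressure_call`.
#' @export
run_ncplot <- function(config, profile = NULL, code = genetic_code()) {
  if (is.null(profile)) profile <- run_profile(config, code)
  gm <- profile$gene_metrics
  keys <- unique(paste(gm$species, gm$strain))
  rows <- lapply(keys, function(k) {
    m <- gm[paste(gm$species, gm$strain) == k, , drop = FALSE]
    cl <- classify_nc_plot(m)
    data.frame(species = m$species[1], strain = m$strain[1],
               label = cl$label, fraction_below_null = cl$fraction_below_null,
               n_genes = cl$n_genes, mean_gc3 = cl$mean_gc3,
               pressure_call = if (cl$fraction_below_null > 0.5) "selection" else "mutation",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write_cub_tsv(out, file.path(config$outdir, "ncplot_classification.tsv"))
  if (config$make_plots) {
    pdf_path <- file.path(config$outdir, "ncplot.pdf")
    grDevices::pdf(pdf_path, width = 7, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
    s <- seq(0, 1, by = 0.005)
    plot_one <- function(m, main) {
      graphics::plot(m$gc3, m$nc, xlim = c(0, 1), ylim = c(15, 63),
                     pch = 20, col = grDevices::adjustcolor("grey30", 0.5),
                     xlab = "GC3", ylab = "Nc", main = main)
      graphics::lines(s, nc_null_curve(s), lty = 2, col = "blue")
    }
    plot_one(gm[gm$computable, ], "All genomes")
    for (k in keys) {
      m <- gm[paste(gm$species, gm$strain) == k & gm$computable, , drop = FALSE]
      plot_one(m, k)
    }
  }
  invisible(out)
}

#' Run the phylogenetics stage
#'
#' Builds one bootstrap consensus tree per gene symbol (housekeeping genes
#' plus 16S) from per-gene alignments — either supplied as aligned FASTA
#' files or simulated via [simulate_clade()] — and writes each tree in
#' Newick format together with the Robinson-Foulds congruence matrix of all
#' gene trees (the 16S tree being the conventional reference). A failing
#' gene (saturation, no data) is reported and skipped without aborting the
#' others.
#'
#' @param config a [run_config()].
#' @param alignments optional named list of alignment matrices (gene ->
#'   matrix); when absent, `config$simulate` arguments are forwarded to
#'   [simulate_clade()].
#' @param code a [genetic_code()].
#' @return (invisibly) list with `trees` (gene -> `phylo`), `congruence`
#'   (data.frame of pairwise RF results) and `failed` (named character of
#'   per-gene error messages).
#' @export
run_phylo <- function(config, alignments = NULL, code = genetic_code()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(alignments)) {
    args <- config$simulate %||% list()
    args$seed <- args$seed %||% config$seed
    args <- args[intersect(names(args),
                           names(formals(simulate_clade)))]
    alignments <- do.call(simulate_clade, c(args, list(code = code)))$alignments
  }
  trees <- list(); failed <- character(0)
  for (g in names(alignments)) {
    res <- tryCatch({
      aln <- complete_deletion(alignments[[g]])
      tr <- bootstrap_consensus(aln, n_reps = config$bootstrap,
                                seed = config$seed, model = config$model)
      write_newick(tr, file.path(config$outdir, paste0("tree_", g, ".nwk")))
      tr
    }, cubphylo_error = function(e) e)
    if (inherits(res, "error")) {
      failed[g] <- conditionMessage(res)
      cub_log("run_phylo: %s failed: %s", g, conditionMessage(res))
    } else trees[[g]] <- res
  }
  cong <- NULL
  if (length(trees) >= 2L) {
    gs <- names(trees)
    rows <- list()
    for (i in seq_along(gs)) for (j in seq_along(gs)) {
      if (i >= j) next
      r <- rf_distance(trees[[gs[i]]], trees[[gs[j]]])
      rows[[length(rows) + 1L]] <-
        data.frame(gene1 = gs[i], gene2 = gs[j], rf = r$rf,
                   rf_normalized = r$rf_normalized,
                   shared_splits = r$shared_splits, stringsAsFactors = FALSE)
    }
    cong <- do.call(rbind, rows)
    write_cub_tsv(cong, file.path(config$outdir, "congruence.tsv"))
  }
  invisible(list(trees = trees, congruence = cong, failed = failed))
}

#' Run every stage
#'
#' @param config a [run_config()].
#' @param code a [genetic_code()].
#' @return (invisibly) list with the three stage results.
#' @export
run_all <- function(config, code = genetic_code()) {
  prof <- run_profile(config, code)
  ncp <- run_ncplot(config, profile = prof, code = code)
  phy <- if (!is.null(config$simulate)) run_phylo(config, code = code) else NULL
  invisible(list(profile = prof, ncplot = ncp, phylo = phy))
}
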