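fake_metrics <- function(nc, gc3 = NULL, ids = NULL) {
  n <- length(nc)
  data.frame(gene_id = ids %||% sprintf("g%d", seq_len(n)),
             gene_symbol = NA_character_, length_codons = 100L,
             nc = nc, gc3 = gc3 %||% rep(0.5, n), gc3s = gc3 %||% rep(0.5, n),
             gravy = 0, computable = !is.na(nc), stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

fake_genome <- function(cds_nt = c("ATGGGGCCCTAA", "ATGAAATTTTAA")) {
  cds <- lapply(seq_along(cds_nt), function(i) cds_of(cds_nt[i], id = paste0("g", i)))
  genome_record("Testus exampli", "T1", "negative", 1e5, cds = cds)
}

test_that("genome summary aggregates means, sample SDs and coding statistics", {
  g <- fake_genome()
  s <- summarize_genome(fake_metrics(c(40, 50)), g)
  expect_equal(s$nc_avg, 45)
  expect_equal(s$nc_sd, 10 / sqrt(2), tolerance = 1e-12)
  expect_equal(s$coding_bases, 24)
  expect_equal(s$gc_content, 8 / 24)    # G+C across both CDS
  expect_equal(s$coding_frequency, 24 / 1e5)
  expect_equal(s$n_genes, 2)

  single <- summarize_genome(fake_metrics(42), g)
  expect_true(is.na(single$nc_sd))
  expect_error(summarize_genome(fake_metrics(NA_real_), g), class = "NO_DATA")
})

test_that("genome summary matches a streaming-mean oracle on simulated genes", {
  set.seed(405)
  nc <- runif(100, 25, 60); gc <- runif(100)
  s <- summarize_genome(fake_metrics(nc, gc), fake_genome())
  sm <- 0; for (v in nc) sm <- sm + v
  expect_equal(s$nc_avg, sm / 100, tolerance = 1e-9)
  expect_equal(s$gc3_avg, mean(gc), tolerance = 1e-9)
  expect_equal(s$nc_sd, sqrt(sum((nc - sm / 100)^2) / 99), tolerance = 1e-9)
})

test_that("housekeeping profile computes deltas and the %-below-genic-Nc statistic", {
  g <- fake_genome()
  all_m <- fake_metrics(30:39)
  s <- summarize_genome(all_m, g)
  hk <- list(rpoB = fake_metrics(35), trpB = NULL)
  prof <- housekeeping_profile(s, hk, all_m)
  r <- prof[prof$gene == "rpoB", ]
  expect_equal(r$delta_nc, s$nc_avg - 35)
  expect_equal(r$pct_below_genic_nc, 50)   # exactly 30..34 fall below 35
  t <- prof[prof$gene == "trpB", ]
  expect_true(all(is.na(t[c("genic_nc", "delta_nc", "genic_gc3", "delta_gc3",
                            "pct_below_genic_nc")])))
})

test_that("Spearman correlation handles monotone, exact and approximate cases", {
  expect_equal(spearman_cor(1:3, c(2, 4, 6))$rho, 1)
  expect_equal(spearman_cor(1:3, c(3, 2, 1))$rho, -1)
  r <- spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  o <- oracle_spearman_exact(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$rho, o$rho, tolerance = 1e-12)
  expect_equal(r$p_value, o$p_value, tolerance = 1e-12)
  expect_equal(r$method, "exact_permutation")
  # MISSING pairs dropped pairwise
  expect_equal(spearman_cor(c(1, 2, NA, 3), c(2, 4, 5, 6))$n, 3)
  expect_error(spearman_cor(1:3, 1:4), class = "SCHEMA")
  expect_error(spearman_cor(c(1, 2), c(3, 4)), class = "NO_DATA")
  # t-approximation branch
  set.seed(406)
  big <- spearman_cor(rnorm(30), rnorm(30))
  expect_equal(big$method, "t_approximation")
})

test_that("Spearman exact p equals full-permutation enumeration on random instances", {
  set.seed(407)
  for (i in 1:100) {
    n <- sample(4:7, 1)
    x <- sample(1000, n); y <- sample(1000, n)
    r <- spearman_cor(x, y)
    o <- oracle_spearman_exact(x, y)
    expect_equal(r$rho, o$rho, tolerance = 1e-12)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis H matches hand-computed ranks and the formula oracle", {
  expect_equal(kruskal_wallis(list(1:3, 1:3))$statistic, 0)
  r <- kruskal_wallis(list(c(1, 2), c(10, 11), c(20, 21)))
  expect_equal(r$statistic, oracle_kw(list(c(1, 2), c(10, 11), c(20, 21))),
               tolerance = 1e-12)
  expect_equal(r$df, 2)
  set.seed(408)
  for (i in 1:100) {
    groups <- lapply(1:3, function(j) rnorm(sample(3:8, 1)))
    expect_equal(kruskal_wallis(groups)$statistic, oracle_kw(groups),
                 tolerance = 1e-9)
  }
  expect_error(kruskal_wallis(list(1:2)), class = "NO_DATA")
})

test_that("Mann-Whitney U and exact p equal the full-enumeration oracle", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(mann_whitney(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  r <- mann_whitney(c(1, 3, 5, 7), c(2, 4, 6, 8))
  o <- oracle_mw(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_equal(r$statistic, o$u)
  expect_equal(r$p_value, o$p_value, tolerance = 1e-9)
  set.seed(409)
  for (i in 1:100) {
    a <- sample(10000, sample(3:8, 1)); b <- sample(10000, sample(3:8, 1))
    r <- mann_whitney(a, b); o <- oracle_mw(a, b)
    expect_equal(r$statistic, o$u)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-9)
    expect_true(r$statistic <= length(a) * length(b))
  }
  expect_error(mann_whitney(numeric(0), 1:3), class = "NO_DATA")
})

test_that("Nc-plot classifier labels by mean GC3 and counts genes below the null curve", {
  expect_equal(classify_nc_plot(fake_metrics(rep(40, 10), rep(0.10, 10)))$label, "left")
  expect_equal(classify_nc_plot(fake_metrics(rep(40, 10), rep(0.47, 10)))$label, "mid")
  expect_equal(classify_nc_plot(fake_metrics(rep(40, 10), rep(0.95, 10)))$label, "right")
  gc <- seq(0.1, 0.9, length.out = 20)
  below <- classify_nc_plot(fake_metrics(nc_null_curve(gc) - 5, gc))
  expect_equal(below$fraction_below_null, 1)
  above <- classify_nc_plot(fake_metrics(pmin(nc_null_curve(gc) + 0.5, 61), gc))
  expect_equal(above$fraction_below_null, 0)
})

test_that("collection correlation panel is pairwise-complete and adjustable", {
  set.seed(410)
  n <- 15
  summ <- data.frame(nc_avg = rnorm(n, 45), genome_length_bp = runif(n, 2e6, 9e6),
                     coding_bases = runif(n, 1e6, 8e6), gc_content = runif(n, .3, .7),
                     coding_frequency = runif(n, .7, .95))
  pan <- genome_correlations(summ)
  expect_equal(nrow(pan), 5)
  expect_true(all(abs(pan$rho) <= 1))
  adj <- genome_correlations(summ, adjust = "BH")
  expect_true(all(adj$p_value >= pan$p_value - 1e-12))
})
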