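rand_aln <- function(n_taxa, n_sites) {
  m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * n_sites, replace = TRUE),
              n_taxa, n_sites)
  rownames(m) <- sprintf("t%02d", seq_len(n_taxa))
  m
}

test_that("complete deletion removes exactly the gap/missing columns", {
  aln <- as_alignment(c(a = "AC-T", b = "ACGT"))
  out <- complete_deletion(aln)
  expect_equal(ncol(out), 3)
  expect_equal(paste(out["a", ], collapse = ""), "ACT")

  clean <- rand_aln(4, 50)
  expect_identical(complete_deletion(clean), clean)

  set.seed(501)
  aln <- rand_aln(10, 100)
  gap_cols <- sample(100, 17)
  for (j in gap_cols) aln[sample(10, 1), j] <- sample(c("-", "N"), 1)
  expect_equal(ncol(complete_deletion(aln)), 100 - 17)

  allgap <- as_alignment(c(a = "--", b = "AC"))
  expect_error(complete_deletion(allgap), class = "NO_DATA")
})

test_that("K2P distance follows its closed form and flags saturation", {
  x <- rep("A", 100); y <- x
  expect_equal(k2p_distance(x, y)$d, 0)
  y[1:10] <- "G"; y[11:15] <- "C"     # P = 0.1, Q = 0.05
  r <- k2p_distance(x, y)
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0.05)
  expect_equal(r$d, -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)

  sat <- rep("A", 100); sat[1:50] <- "G"   # P = 0.5, Q = 0
  expect_error(k2p_distance(x, sat), class = "SATURATED")

  # Jukes-Cantor at 30% raw difference
  y2 <- x; y2[1:30] <- c(rep("G", 15), rep("C", 15))
  expect_equal(jc_distance(x, y2)$d, -0.75 * log(1 - 0.4), tolerance = 1e-12)
  expect_equal(p_distance(x, y2)$d, 0.3)
})

test_that("K2P agrees with an independent closed-form oracle on random pairs", {
  set.seed(502)
  checked <- 0
  while (checked < 200) {
    a <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
    b <- a
    mut <- sample(300, sample(5:90, 1))
    b[mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
    o <- oracle_k2p(a, b)
    if (is.na(o)) {
      expect_error(k2p_distance(a, b), class = "SATURATED")
    } else {
      expect_equal(k2p_distance(a, b)$d, o, tolerance = 1e-12)
    }
    checked <- checked + 1
  }
})

test_that("distance_matrix is consistent entrywise and cross-checks against ape", {
  set.seed(503)
  aln <- rand_aln(3, 40)
  aln[2, ] <- aln[1, ]; aln[3, ] <- aln[1, ]
  expect_true(all(distance_matrix(aln, "k2p") == 0))

  cl <- evolve_clade(ape::rtree(6, br = function(n) runif(n, 0.02, 0.08)),
                     list(g = random_nucleotides(800, 0.5, 7)), kappa = 2, seed = 8)
  aln <- cl$alignments$g
  dm <- distance_matrix(aln, "k2p")
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(dm[i, j], k2p_distance(aln[i, ], aln[j, ])$d, tolerance = 1e-12)
  }
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(aln), model = "K80"))
  expect_equal(unname(dm[rownames(ref), colnames(ref)]), unname(ref),
               tolerance = 1e-9, ignore_attr = TRUE)

  # saturation policy: loud failure by default, imputation on request
  sat <- as_alignment(c(a = strrep("A", 60),
                        b = paste0(strrep("A", 40), strrep("C", 20)),
                        c = strrep("G", 60)))
  expect_error(distance_matrix(sat, "k2p"), class = "SATURATED")
  imp <- distance_matrix(sat, "k2p", allow_saturation = TRUE)
  expect_equal(nrow(attr(imp, "saturated")), 2)
  fin <- k2p_distance(sat["a", ], sat["b", ])$d
  expect_equal(imp["a", "c"], fin * 1.1, tolerance = 1e-9)
  expect_equal(imp["b", "c"], fin * 1.1, tolerance = 1e-9)
})

test_that("NJ recovers additive matrices exactly and is input-order invariant", {
  true <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
  dm <- cophenetic(true)
  tr <- nj_tree(dm)
  expect_equal(rf_distance(tr, ape::unroot(true))$rf, 0)
  expect_equal(sum(tr$edge.length), sum(ape::unroot(true)$edge.length),
               tolerance = 1e-9)
  expect_true(all(tr$edge.length >= 0))

  # three taxa: unique topology, lengths from the pair equations
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  expect_equal(sort(t3$edge.length), c(1, 2, 3))

  set.seed(504)
  for (i in 1:10) {
    true <- ape::rtree(8, br = function(n) runif(n, 0.05, 0.2))
    dm <- cophenetic(true)
    perm <- sample(rownames(dm))
    expect_equal(rf_distance(nj_tree(dm), nj_tree(dm[perm, perm]))$rf, 0)
  }
  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2)), class = "NO_DATA")
})

test_that("bootstrap consensus is seeded, bounded and majority-rule", {
  set.seed(505)
  cl <- simulate_clade(n_taxa = 6, seed = 17)
  aln <- complete_deletion(cl$alignments$rpoB)
  t1 <- bootstrap_consensus(aln, n_reps = 30, seed = 3)
  t2 <- bootstrap_consensus(aln, n_reps = 30, seed = 3)
  expect_identical(write_newick(t1), write_newick(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(all(sup > 50))          # majority-rule keeps only >50% splits
  # strong signal: the true splits are fully supported
  expect_equal(rf_distance(t1, cl$tree)$rf, 0)

  one <- bootstrap_consensus(aln, n_reps = 1, seed = 4)
  expect_equal(length(one$tip.label), 6)
  expect_error(bootstrap_consensus(aln, n_reps = 0), class = "DOMAIN")
})

test_that("RF distance matches split enumeration on canonical and random cases", {
  ta <- read_newick("((A,B),(C,D));")
  tb <- read_newick("((A,C),(B,D));")
  r <- rf_distance(ta, tb)
  expect_equal(r$rf, 2)
  expect_equal(r$rf_normalized, 1)
  expect_equal(r$shared_splits, 0)
  expect_equal(rf_distance(ta, ta)$rf, 0)

  t6 <- read_newick("(((A,B),C),((D,E),F));")
  t6_nni <- read_newick("(((A,C),B),((D,E),F));")
  expect_equal(rf_distance(t6, t6_nni)$rf, 2)

  set.seed(506)
  for (i in 1:50) {
    x <- ape::rtree(sample(5:9, 1))
    y <- ape::rtree(length(x$tip.label))
    y$tip.label <- x$tip.label
    expect_equal(rf_distance(x, y)$rf, oracle_rf(x, y))
  }
  expect_error(rf_distance(ta, read_newick("((A,B),(C,E));")), class = "SCHEMA")
})

test_that("Newick I/O round-trips topology, lengths and supports", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(length(tr$tip.label), 3)
  rt <- read_newick(write_newick(tr))
  expect_equal(rf_distance(tr, rt)$rf, 0)
  expect_equal(sort(rt$edge.length), sort(tr$edge.length))

  sup <- read_newick("((A,B)95,(C,D)80);")
  expect_true(all(c("95", "80") %in% sup$node.label))
  expect_true(all(c("95", "80") %in% read_newick(write_newick(sup))$node.label))

  expect_error(read_newick("((A,B);"), class = "SCHEMA")

  set.seed(507)
  for (i in 1:100) {
    tr <- ape::rtree(sample(4:12, 1))
    expect_equal(rf_distance(read_newick(write_newick(tr)), tr)$rf, 0)
  }
})

test_that("K2P reduces to Jukes-Cantor on equal-rate data", {
  tr <- ape::read.tree(text = "(A:0.08,B:0.08);")
  cl <- evolve_clade(tr, list(g = random_nucleotides(20000, 0.5, 9)),
                     kappa = 1, seed = 10)
  aln <- cl$alignments$g
  dk <- k2p_distance(aln[1, ], aln[2, ])$d
  dj <- jc_distance(aln[1, ], aln[2, ])$d
  expect_equal(dk, dj, tolerance = 0.02)
  expect_equal(dk, 0.16, tolerance = 0.05)   # within sampling noise of the truth
})

test_that("PHYLIP distance output parses back to the same matrix", {
  set.seed(508)
  base <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  aln <- do.call(rbind, lapply(1:4, function(i) {
    s <- base
    mut <- sample(200, 20)
    s[mut] <- sample(c("A", "C", "G", "T"), 20, replace = TRUE)
    s
  }))
  rownames(aln) <- sprintf("t%02d", 1:4)
  dm <- distance_matrix(as_alignment(aln), "jc")
  tmp <- withr::local_tempfile(fileext = ".phy")
  write_phylip_distance(dm, tmp)
  lines <- readLines(tmp)
  expect_equal(as.integer(trimws(lines[1])), 4)
  row2 <- as.numeric(strsplit(trimws(substring(lines[3], 11)), "[[:space:]]+")[[1]])
  expect_equal(row2, unname(round(dm[2, ], 6)), tolerance = 1e-9)
})
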