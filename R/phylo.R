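# Distance-based phylogenetics: complete-deletion gap filtering, K2P/JC/p
# distances with saturation handling, neighbor-joining, bootstrap majority-rule
# consensus, Newick I/O and Robinson-Foulds congruence.

#' Read an aligned FASTA file as a character alignment matrix
#'
#' @param path aligned FASTA (rows must be equal length).
#' @return character matrix, rows = taxa, columns = alignment sites.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) cub_stop("EMPTY_INPUT", sprintf("no records in '%s'", path))
  as_alignment(stats::setNames(as.character(set),
                               sub("[[:space:]].*$", "", names(set))))
}

#' @param x named character vector of equal-length sequences, or a character
#'   matrix.
#' @rdname read_alignment_fasta
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    aln <- toupper(x)
  } else {
    if (length(unique(nchar(x))) != 1L)
      cub_stop("SCHEMA", "aligned sequences must have equal length")
    aln <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(aln) <- names(x)
  }
  if (is.null(rownames(aln)) || anyDuplicated(rownames(aln)))
    cub_stop("SCHEMA", "alignment taxa must be uniquely named")
  aln
}

#' Write an alignment matrix to FASTA
#' @param aln character alignment matrix.
#' @param path output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(apply(aln, 1L, paste, collapse = ""))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Complete-deletion gap filtering
#'
#' Removes every alignment column containing a gap (`-`) or missing datum
#' (`N`/`?`) in any row — the standard complete-deletion policy applied
#' before distance estimation.
#'
#' @param aln character alignment matrix.
#' @return the filtered alignment; errors with `NO_DATA` if nothing remains.
#' @export
complete_deletion <- function(aln) {
  if (ncol(aln) == 0L) cub_stop("NO_DATA", "alignment has no columns")
  bad <- apply(aln, 2L, function(col) any(col %in% c("-", "N", "?")))
  out <- aln[, !bad, drop = FALSE]
  if (ncol(out) == 0L) cub_stop("NO_DATA", "complete deletion removed all columns")
  out
}

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura two-parameter distance between two aligned sequences
#'
#' With transition proportion P and transversion proportion Q over the
#' compared sites, \eqn{d = -\frac12 \ln(1 - 2P - Q) - \frac14 \ln(1 - 2Q)}.
#' When a log argument is non-positive the pair is saturated and the distance
#' undefined (`SATURATED` error).
#'
#' @param a,b character vectors (or single strings) of equal length, gap-free
#'   (apply [complete_deletion()] first).
#' @return list with `d`, `P`, `Q`, `n_sites`.
#' @export
k2p_distance <- function(a, b) {
  s <- pair_sites(a, b)
  P <- mean(s$a != s$b & TRANSITION_PARTNER[s$a] == s$b)
  Q <- mean(s$a != s$b & TRANSITION_PARTNER[s$a] != s$b)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    cub_stop("SATURATED", sprintf("saturated pair (P=%.3f, Q=%.3f)", P, Q))
  list(d = -0.5 * log(w1) - 0.25 * log(w2), P = P, Q = Q, n_sites = length(s$a))
}

#' @rdname k2p_distance
#' @export
jc_distance <- function(a, b) {
  s <- pair_sites(a, b)
  p <- mean(s$a != s$b)
  w <- 1 - 4 * p / 3
  if (w <= 0) cub_stop("SATURATED", sprintf("saturated pair (p=%.3f)", p))
  list(d = -0.75 * log(w), p = p, n_sites = length(s$a))
}

#' @rdname k2p_distance
#' @export
p_distance <- function(a, b) {
  s <- pair_sites(a, b)
  list(d = mean(s$a != s$b), n_sites = length(s$a))
}

pair_sites <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) cub_stop("SCHEMA", "sequences differ in length")
  if (length(a) == 0L) cub_stop("NO_DATA", "no sites to compare")
  list(a = toupper(a), b = toupper(b))
}

#' Pairwise distance matrix under a substitution model
#'
#' Computes all pairwise distances of an alignment under the Kimura
#' two-parameter, Jukes-Cantor or raw p-distance model, with per-pair
#' transition/transversion diagnostics attached. Saturated pairs abort with a
#' `SATURATED` error by default; with `allow_saturation = TRUE` they are
#' imputed as 1.1 times the largest finite distance (and listed in the
#' `saturated` attribute).
#'
#' @param aln character alignment matrix (complete-deleted).
#' @param model one of `"k2p"`, `"jc"`, `"p_distance"`.
#' @param allow_saturation impute saturated pairs instead of failing.
#' @return symmetric numeric matrix of distances with attributes `model`,
#'   `P`, `Q` (for k2p) and `saturated` (data.frame of imputed pairs).
#' @export
distance_matrix <- function(aln, model = c("k2p", "jc", "p_distance"),
                            allow_saturation = FALSE) {
  model <- match.arg(model)
  taxa <- rownames(aln)
  n <- length(taxa)
  if (n < 2L) cub_stop("NO_DATA", "need at least 2 taxa")
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  Pm <- Qm <- matrix(NA_real_, n, n, dimnames = list(taxa, taxa))
  sat <- list()
  fn <- switch(model, k2p = k2p_distance, jc = jc_distance,
               p_distance = p_distance)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      res <- tryCatch(fn(aln[i, ], aln[j, ]), SATURATED = function(e) e)
      if (inherits(res, "error")) {
        sat[[length(sat) + 1L]] <- data.frame(taxon1 = taxa[i], taxon2 = taxa[j],
                                              stringsAsFactors = FALSE)
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- res$d
        if (model == "k2p") {
          Pm[i, j] <- Pm[j, i] <- res$P
          Qm[i, j] <- Qm[j, i] <- res$Q
        }
      }
    }
  }
  sat <- if (length(sat)) do.call(rbind, sat) else NULL
  if (!is.null(sat)) {
    if (!allow_saturation)
      cub_stop("SATURATED", sprintf("%d saturated pair(s); rerun with allow_saturation = TRUE to impute",
                                    nrow(sat)))
    fin <- max(d[is.finite(d)], na.rm = TRUE)
    d[is.na(d)] <- fin * 1.1
    diag(d) <- 0
  }
  attr(d, "model") <- model
  if (model == "k2p") { attr(d, "P") <- Pm; attr(d, "Q") <- Qm }
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree
#'
#' Canonical neighbor-joining on a distance matrix (via [ape::nj()]), with
#' negative branch lengths set to zero and the deficit transferred to the
#' adjacent edges below, preserving leaf-to-leaf path lengths through that
#' node where possible.
#'
#' @param dm symmetric distance matrix (finite entries).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) cub_stop("NO_DATA", "need at least 3 taxa")
  if (any(!is.finite(dm))) cub_stop("SCHEMA", "non-finite distances")
  tr <- ape::nj(stats::as.dist(dm))
  fix_negative_edges(tr)
}

fix_negative_edges <- function(tr) {
  el <- tr$edge.length
  if (is.null(el) || all(el >= 0)) return(tr)
  # process edges from the root downward so transfers cascade
  ord <- order(tr$edge[, 1L])
  for (e in ord) {
    if (el[e] >= 0) next
    child <- tr$edge[e, 2L]
    below <- which(tr$edge[, 1L] == child)
    if (length(below)) el[below] <- el[below] + el[e]
    el[e] <- 0
  }
  tr$edge.length <- pmax(el, 0)
  tr
}

#' Bootstrap majority-rule consensus tree
#'
#' Resamples alignment columns with replacement, builds a neighbor-joining
#' tree per replicate under the chosen distance model, and returns the
#' majority-rule (> 50%) consensus with per-internal-edge bootstrap support
#' percentages stored as node labels. Saturated pairs inside replicates are
#' imputed so a hard replicate does not abort the run. Reproducible given
#' `seed`.
#'
#' @param aln character alignment matrix.
#' @param n_reps number of bootstrap replicates (>= 1; 1000 is the
#'   conventional default).
#' @param seed integer RNG seed.
#' @param model distance model, see [distance_matrix()].
#' @return a `phylo` consensus tree; `node.label` holds support percentages.
#' @export
bootstrap_consensus <- function(aln, n_reps = 1000L, seed = 1L, model = "k2p") {
  if (n_reps < 1L) cub_stop("DOMAIN", "n_reps must be >= 1")
  if (ncol(aln) == 0L) cub_stop("NO_DATA", "empty alignment")
  trees <- with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      nj_tree(distance_matrix(aln[, cols, drop = FALSE], model = model,
                              allow_saturation = TRUE))
    })
  })
  cons <- ape::consensus(trees, p = 0.5, check.labels = TRUE)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  cons$node.label <- as.character(round(100 * counts / n_reps, 1))
  cons$node.label[1] <- ""                       # root pseudo-split
  cons
}

tree_splits <- function(tree) {
  # canonical non-trivial bipartitions as sorted "smaller side" strings
  tree <- ape::unroot(tree)
  taxa <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- sort(labs[p])
    other <- setdiff(taxa, side)
    if (length(side) < 2L || length(other) < 2L) next
    canon <- if (taxa[1] %in% side) other else side
    out <- c(out, paste(canon, collapse = "\r"))
  }
  unique(out)
}

#' Robinson-Foulds congruence between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions, normalized by
#' `2*(n-3)` (the maximum for two binary trees on n leaves); also reports the
#' number of shared non-trivial splits.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return list with `rf`, `rf_normalized`, `shared_splits`, `n_taxa`.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    cub_stop("SCHEMA", "trees have different leaf sets")
  n <- length(t1$tip.label)
  rf <- phangorn::RF.dist(t1, t2, check.labels = TRUE)
  s1 <- length(tree_splits(t1)); s2 <- length(tree_splits(t2))
  shared <- (s1 + s2 - rf) / 2
  norm <- if (n > 3L) rf / (2 * (n - 3)) else 0
  list(rf = rf, rf_normalized = norm, shared_splits = shared, n_taxa = n)
}

#' Newick input and output
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that preserve
#' internal-node support labels across the round trip and turn parse failures
#' into structured `SCHEMA` errors.
#'
#' @param text Newick string, or `file` a path.
#' @param file optional path to read from / write to.
#' @param tree a `phylo` object.
#' @return `read_newick` returns a `phylo`; `write_newick` returns the Newick
#'   string (invisibly when writing to a file).
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) cub_stop("SCHEMA", "malformed Newick input")
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Write a distance matrix in square PHYLIP format
#' @param dm distance matrix from [distance_matrix()].
#' @param path output file.
#' @export
write_phylip_distance <- function(dm, path) {
  taxa <- rownames(dm)
  lines <- c(sprintf("%5d", length(taxa)),
             vapply(seq_along(taxa), function(i) {
               paste0(formatC(taxa[i], width = -10),
                      paste(sprintf("%.6f", dm[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
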