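# Independent brute-force / enumeration oracles used to cross-check the
# package implementations. Each oracle is written straight from the defining
# formula, separately from the code path it checks.

test_code <- genetic_code()

oracle_split_codons <- function(nt) {
  n <- nchar(nt) %/% 3L
  vapply(seq_len(n), function(i) substr(nt, 3 * i - 2, 3 * i), character(1))
}

# Wright's Nc recomputed from raw codon counts with explicit loops.
oracle_nc <- function(nt, code = test_code) {
  cd <- oracle_split_codons(nt)
  cd <- cd[-length(cd)]                       # strip terminal stop
  aa_map <- code$codon_to_aa
  sense <- names(aa_map)[aa_map != "*"]
  fams <- split(sense, aa_map[sense])
  ks <- numeric(0); Fs <- numeric(0)
  for (a in names(fams)) {
    cnt <- vapply(fams[[a]], function(cc) sum(cd == cc), numeric(1))
    n_a <- sum(cnt)
    if (n_a < 2) next
    p <- cnt / n_a
    ks <- c(ks, length(fams[[a]]))
    Fs <- c(Fs, (n_a * sum(p^2) - 1) / (n_a - 1))
  }
  fbar <- function(k) { v <- Fs[ks == k]; if (length(v)) mean(v) else NA_real_ }
  f2 <- fbar(2); f3 <- fbar(3); f4 <- fbar(4); f6 <- fbar(6)
  if (is.na(f2) || is.na(f4)) return(NA_real_)
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  if (is.na(f6)) f6 <- (f2 + f4) / 2
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  if (!is.finite(nc) || nc > 61) 61 else nc
}

oracle_gc3 <- function(nt) {
  cd <- oracle_split_codons(nt)
  cd <- cd[-length(cd)]
  mean(substr(cd, 3, 3) %in% c("G", "C"))
}

oracle_gc3s <- function(nt, code = test_code) {
  cd <- oracle_split_codons(nt)
  cd <- cd[-length(cd)]
  k_of <- stats::setNames(code$families$k, code$families$codon)
  cd <- cd[k_of[cd] >= 2]
  if (length(cd) == 0) return(NA_real_)
  mean(substr(cd, 3, 3) %in% c("G", "C"))
}

# Kyte-Doolittle values restated independently (order scrambled on purpose).
ORACLE_KD <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
               G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
               H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9,
               R = -4.5)

oracle_gravy <- function(nt, code = test_code) {
  cd <- oracle_split_codons(nt)
  cd <- cd[-length(cd)]
  mean(ORACLE_KD[code$codon_to_aa[cd]])
}

# Random valid CDS with variable codon bias (uses the caller's RNG stream).
random_valid_cds <- function(n_codons, bias_power = NULL) {
  sense <- test_code$families$codon
  if (is.null(bias_power)) bias_power <- stats::runif(1, 0, 4)
  w <- stats::runif(length(sense))^bias_power
  body <- sample(sense, n_codons, replace = TRUE, prob = w / sum(w))
  nt <- paste0("ATG", paste(body, collapse = ""), "TAA")
  validate_cds(coding_sequence("rand", nt), test_code)
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- all_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) out <- rbind(out, cbind(i, p + (p >= i)))
  unname(out)
}

# Exact two-sided Spearman p by full n! enumeration of rank permutations.
oracle_spearman_exact <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  P <- all_perms(length(x))
  rhos <- apply(P, 1, function(pp) stats::cor(rx, ry[pp]))
  obs <- stats::cor(rx, ry)
  p <- min(1, 2 * min(mean(rhos <= obs + 1e-12), mean(rhos >= obs - 1e-12)))
  list(rho = obs, p_value = p)
}

# Exact Mann-Whitney U and two-sided p over all C(n1+n2, n1) labelings.
oracle_mw <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  rk <- rank(c(a, b))
  u_obs1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(n1 + n2, n1)
  Us <- apply(cmb, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  p <- min(1, 2 * min(mean(Us <= u_obs1 + 1e-12), mean(Us >= u_obs1 - 1e-12)))
  list(u = min(u_obs1, n1 * n2 - u_obs1), p_value = p)
}

# Kruskal-Wallis H from the defining rank-sum formula with tie correction.
oracle_kw <- function(groups) {
  N <- sum(lengths(groups))
  rk <- rank(unlist(groups))
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) * sum(tapply(rk, idx, sum)^2 / lengths(groups)) -
    3 * (N + 1)
  tie <- table(unlist(groups))
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# K2P distance straight from the closed form; NA when saturated.
oracle_k2p <- function(a, b) {
  ts_pairs <- c("AG", "GA", "CT", "TC")
  cmp <- paste0(a, b)
  P <- mean(cmp %in% ts_pairs)
  Q <- mean(a != b & !cmp %in% ts_pairs)
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# Non-trivial bipartitions by explicit edge traversal (no ape/phangorn).
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  taxa <- sort(tree$tip.label)
  tips_below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n_tip) next
    side <- sort(tips_below(child))
    other <- setdiff(taxa, side)
    if (length(side) < 2 || length(other) < 2) next
    canon <- if (taxa[1] %in% side) other else side
    out <- c(out, paste(canon, collapse = "\r"))
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# small helper: a validated CDS from a raw string
cds_of <- function(nt, sym = NA_character_, id = "x") {
  validate_cds(coding_sequence(id, nt, sym), test_code)
}
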