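# Seeded synthetic data: codon-usage profiles, whole genomes with tagged
# housekeeping genes, and indel-free sequence evolution on a known tree, so
# every downstream stage can be exercised with known ground truth.

#' Average bacterial amino-acid background frequencies
#'
#' Fixed composition used by [simulate_genome()] when drawing protein
#' sequences; values approximate the average residue usage of bacterial
#' proteomes (normalized to sum to 1). Only stationarity matters to the
#' consumers of the simulated data.
#' @export
AA_BACKGROUND <- local({
  f <- c(A = 0.089, R = 0.055, N = 0.039, D = 0.054, C = 0.011,
         Q = 0.038, E = 0.061, G = 0.074, H = 0.022, I = 0.074,
         L = 0.100, K = 0.058, M = 0.024, F = 0.040, P = 0.044,
         S = 0.060, T = 0.055, W = 0.012, Y = 0.029, V = 0.070)
  f / sum(f)
})

#' Synthetic codon-usage profile
#'
#' Builds a per-family codon probability profile with a target GC3 and a
#' bias-concentration knob. Within each synonymous family, codons get a base
#' weight `s_target` when G/C-ending and `1 - s_target` otherwise; the
#' weight-maximal codon of the family (ties broken by a seeded draw) is then
#' boosted by `exp(beta)` and the family renormalized. `beta = 0` leaves the
#' pure GC3 mixture (uniform within every family at `s_target = 0.5`);
#' increasing `beta` concentrates usage on one codon per family, driving Nc
#' down monotonically at fixed GC3.
#'
#' @param s_target desired GC3 in [0, 1].
#' @param beta bias concentration (>= 0).
#' @param seed integer seed (used only for tie-breaking the preferred codon).
#' @param code a [genetic_code()].
#' @return object of class `codon_usage_profile`: list with `s_target`,
#'   `beta`, `seed`, `family_probs` (list aa -> named probability vector)
#'   and `prob` (flat named vector over all sense codons).
#' @export
make_usage_profile <- function(s_target, beta = 0, seed = 1L,
                               code = genetic_code()) {
  if (!is.finite(s_target) || s_target < 0 || s_target > 1)
    cub_stop("DOMAIN", "s_target must lie in [0, 1]")
  if (!is.finite(beta) || beta < 0) cub_stop("DOMAIN", "beta must be >= 0")
  fam <- code$families
  family_probs <- with_seed(seed, {
    lapply(split(fam$codon, fam$aa), function(codons) {
      gc_end <- substr(codons, 3L, 3L) %in% c("G", "C")
      w <- ifelse(gc_end, s_target, 1 - s_target)
      if (all(w == 0)) w <- rep(1, length(w))   # one-fold family at s in {0,1}
      top <- which(w == max(w))
      pref <- if (length(top) > 1L) sample(top, 1L) else top
      v <- w * exp(beta * (seq_along(w) == pref))
      stats::setNames(v / sum(v), codons)
    })
  })
  structure(
    list(s_target = s_target, beta = beta, seed = as.integer(seed),
         family_probs = family_probs, prob = unlist(unname(family_probs))),
    class = "codon_usage_profile"
  )
}

sample_codons_for_aa <- function(aa_vec, profile) {
  out <- character(length(aa_vec))
  for (a in unique(aa_vec)) {
    idx <- which(aa_vec == a)
    p <- profile$family_probs[[a]]
    out[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
  }
  out
}

#' Simulate a bacterial genome with tagged housekeeping genes
#'
#' Draws `n_genes` i.i.d. genes: an amino-acid sequence from
#' [AA_BACKGROUND], codons sampled per the usage profile, with an ATG start
#' prepended and a TAA stop appended so every record passes CDS validation.
#' Four additional genes are tagged `rpoB`/`atpD`/`infB`/`trpB` with typical
#' lengths (~3500/~1400/~2700/~1200 nt). Deterministic given `seed`.
#'
#' @param profile a [make_usage_profile()] object.
#' @param n_genes number of untagged background genes (>= 1).
#' @param length_range background gene length interval in sense codons
#'   (minimum 50).
#' @param genome_length_bp genome length; default places the coding bases at
#'   87% coding frequency.
#' @param seed integer seed.
#' @param species,strain,gram identity fields for the resulting record.
#' @param housekeeping add the four tagged housekeeping genes.
#' @param code a [genetic_code()].
#' @return a validated [genome_record()].
#' @export
simulate_genome <- function(profile, n_genes = 80L,
                            length_range = c(150L, 500L),
                            genome_length_bp = NULL, seed = 1L,
                            species = "Simulatus synthetica", strain = "sim",
                            gram = "negative", housekeeping = TRUE,
                            code = genetic_code()) {
  if (n_genes < 1L) cub_stop("DOMAIN", "n_genes must be >= 1")
  if (length_range[1] < 50L) cub_stop("DOMAIN", "gene lengths must be >= 50 codons")
  hk_lengths <- c(rpoB = 1166L, atpD = 466L, infB = 900L, trpB = 400L)
  cds <- with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
    ids <- sprintf("gene%04d", seq_len(n_genes))
    syms <- rep(NA_character_, n_genes)
    if (housekeeping) {
      lens <- c(lens, hk_lengths)
      ids <- c(ids, names(hk_lengths))
      syms <- c(syms, names(hk_lengths))
    }
    lapply(seq_along(lens), function(i) {
      aa <- sample(names(AA_BACKGROUND), lens[i], replace = TRUE,
                   prob = AA_BACKGROUND)
      nt <- paste0("ATG", paste(sample_codons_for_aa(aa, profile), collapse = ""),
                   "TAA")
      validate_cds(coding_sequence(ids[i], nt, syms[i]), code)
    })
  })
  coding <- sum(vapply(cds, function(s) nchar(s$nucleotides), numeric(1)))
  if (is.null(genome_length_bp)) genome_length_bp <- round(coding / 0.87)
  genome_record(species, strain, gram, genome_length_bp, cds = cds)
}

#' Simulate a genome collection with GC-structured codon bias
#'
#' Two fixed study designs. `"envelope"` spans GC3 targets 0.10–0.95 with
#' bias growing as `0.8 * s`, producing genome-level GC3 from ~0.10 to ~0.95
#' and Nc_avg from roughly 30 to 55, so every Nc-plot regime is represented.
#' `"gc_coupled"` spans 0.45–0.95 with bias strength increasing linearly in
#' the GC3 target (strength set by `coupling`) and gene count growing with
#' GC, the regime in which codon bias, genome size and coding frequency all
#' rise with genomic GC — the structure assumed by the collection-level
#' correlation analyses.
#'
#' @param n_genomes number of genomes (default 12).
#' @param preset `"envelope"` or `"gc_coupled"`.
#' @param coupling bias-to-GC coupling strength for `"gc_coupled"`.
#' @param seed integer seed.
#' @param base_genes baseline background gene count per genome.
#' @param code a [genetic_code()].
#' @return list with `genomes` (list of [genome_record()]), `metadata`
#'   (data.frame in the [read_metadata()] schema minus file paths) and
#'   `truth` (s targets, betas, per-genome seeds).
#' @export
simulate_collection <- function(n_genomes = 12L,
                                preset = c("envelope", "gc_coupled"),
                                coupling = 1.5, seed = 1L, base_genes = 60L,
                                code = genetic_code()) {
  preset <- match.arg(preset)
  s <- switch(preset,
              envelope = seq(0.10, 0.95, length.out = n_genomes),
              gc_coupled = seq(0.45, 0.95, length.out = n_genomes))
  beta <- switch(preset,
                 envelope = 0.8 * s,
                 gc_coupled = coupling * (s - min(s)) / (max(s) - min(s)))
  seeds <- with_seed(seed, sample.int(1e9L, n_genomes))
  genomes <- lapply(seq_len(n_genomes), function(i) {
    prof <- make_usage_profile(s[i], beta[i], seed = seeds[i], code = code)
    ng <- as.integer(round(base_genes * (1 + s[i])))
    g <- simulate_genome(prof, n_genes = ng, seed = seeds[i],
                         species = sprintf("Simulatus genomicus%02d", i),
                         strain = sprintf("SIM%02d", i),
                         gram = if (i %% 2L == 0L) "positive" else "negative",
                         code = code)
    # coding frequency rises with GC (0.80 -> 0.90 across the GC span), the
    # trend observed in real bacterial collections
    coding <- sum(vapply(g$cds, function(x) nchar(x$nucleotides), numeric(1)))
    g$genome_length_bp <- round(coding / (0.80 + 0.10 * s[i]))
    g
  })
  metadata <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(species = g$species, strain = g$strain, gram = g$gram,
               phylum = "Simulobacteria", class = "Synthetica",
               genome_length_bp = g$genome_length_bp,
               stringsAsFactors = FALSE)
  }))
  list(genomes = genomes, metadata = metadata,
       truth = list(preset = preset, s_target = s, beta = beta,
                    seeds = seeds, seed = as.integer(seed)))
}

#' Write a simulated collection to disk
#'
#' Emits one CDS FASTA per genome plus a metadata TSV in the
#' [read_metadata()] schema and a `truth.json` ground-truth file (seeds,
#' profiles) for test assertions.
#'
#' @param collection output of [simulate_collection()].
#' @param dir output directory (created if needed).
#' @return the metadata TSV path, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(collection$genomes), function(i) {
    p <- file.path(dir, sprintf("genome%02d.fasta", i))
    write_cds_fasta(collection$genomes[[i]]$cds, p)
    p
  }, character(1))
  md <- collection$metadata
  md$cds_fasta_path <- basename(paths)
  write_cub_tsv(md, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(collection$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "metadata.tsv"))
}

#' Random nucleotide sequence at a target GC content
#'
#' Convenience generator for rRNA-like (non-CDS) root sequences.
#'
#' @param n_sites length.
#' @param gc target G+C fraction.
#' @param seed integer seed.
#' @return single nucleotide string.
#' @export
random_nucleotides <- function(n_sites, gc = 0.54, seed = 1L) {
  with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n_sites, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
}

BASES <- c("A", "C", "G", "T")
TS_PARTNER_INT <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T
TV1_INT <- c(2L, 1L, 2L, 1L)
TV2_INT <- c(4L, 3L, 4L, 3L)

# One branch of K2P site evolution: `x` integer-coded bases, `d` expected
# substitutions/site, `kappa` transition/transversion rate ratio.
mutate_k2p <- function(x, d, kappa) {
  b <- 1 / (kappa + 2)                 # per-target transversion rate
  a <- kappa * b                       # transition rate (a + 2b = 1)
  e4 <- exp(-4 * b * d)
  e2 <- exp(-2 * (a + b) * d)
  p_ts <- 0.25 + 0.25 * e4 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e4             # each of the two transversion targets
  u <- stats::runif(length(x))
  out <- x
  ts <- u < p_ts
  tv1 <- !ts & u < p_ts + p_tv
  tv2 <- !ts & !tv1 & u < p_ts + 2 * p_tv
  out[ts] <- TS_PARTNER_INT[x[ts]]
  out[tv1] <- TV1_INT[x[tv1]]
  out[tv2] <- TV2_INT[x[tv2]]
  out
}

evolve_along_tree <- function(tree, root_int, kappa) {
  tree <- stats::reorder(tree, "cladewise")    # parents before children
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[n_tip + 1L]] <- root_int
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    seqs[[child]] <- mutate_k2p(seqs[[p]], tree$edge.length[e], kappa)
  }
  out <- do.call(rbind, lapply(seqs[seq_len(n_tip)], function(s) BASES[s]))
  rownames(out) <- tree$tip.label
  out
}

#' Evolve orthologous genes on a known tree
#'
#' Each site evolves independently down the tree under the Kimura
#' two-parameter substitution process with transition/transversion rate
#' ratio `kappa`; branch lengths are in expected substitutions per site.
#' Evolution is indel-free, so the per-gene ortholog sets are natively
#' aligned and [complete_deletion()] is the identity on them.
#'
#' @param tree a `phylo` with branch lengths in substitutions/site.
#' @param root_genes named list (gene symbol -> [coding_sequence()] or
#'   nucleotide string) of root sequences.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param seed integer seed.
#' @return list with `tree`, `kappa`, `alignments` (gene -> character
#'   matrix), `true_distances` (patristic path-length matrix) and `seed`.
#' @export
evolve_clade <- function(tree, root_genes, kappa = 2, seed = 1L) {
  if (!is.finite(kappa) || kappa <= 0) cub_stop("DOMAIN", "kappa must be > 0")
  if (is.null(tree$edge.length)) cub_stop("DOMAIN", "tree needs branch lengths")
  alignments <- with_seed(seed, {
    lapply(root_genes, function(g) {
      nt <- if (inherits(g, "coding_sequence")) g$nucleotides else as.character(g)
      root_int <- match(strsplit(toupper(nt), "")[[1]], BASES)
      if (anyNA(root_int)) cub_stop("DOMAIN", "root sequence must be ACGT only")
      evolve_along_tree(tree, root_int, kappa)
    })
  })
  structure(
    list(tree = tree, kappa = kappa, alignments = alignments,
         true_distances = stats::cophenetic(tree), seed = as.integer(seed)),
    class = "simulated_clade"
  )
}

#' Simulate a clade of housekeeping-gene orthologs
#'
#' High-level wrapper: draws a random tree, builds a root genome with the
#' four housekeeping genes plus a 16S-like sequence, and evolves every gene
#' on that tree under K2P — except the symbols in `perturb_genes`, which
#' evolve on a tree one random NNI away (a controlled source of conflicting
#' phylogenetic signal).
#'
#' @param n_taxa number of taxa (>= 4).
#' @param branch_range branch-length interval, substitutions/site.
#' @param kappa transition/transversion rate ratio.
#' @param perturb_genes gene symbols evolved on the NNI-perturbed tree.
#' @param seed integer seed.
#' @param code a [genetic_code()].
#' @return list with `tree`, `perturbed_tree`, `kappa`, `alignments`,
#'   `true_distances`, `perturb_genes`, `seed`.
#' @export
simulate_clade <- function(n_taxa = 8L, branch_range = c(0.03, 0.10),
                           kappa = 2, perturb_genes = character(0),
                           seed = 1L, code = genetic_code()) {
  if (n_taxa < 4L) cub_stop("DOMAIN", "need at least 4 taxa")
  parts <- with_seed(seed, {
    tree <- ape::rtree(n_taxa, br = function(n) stats::runif(n, branch_range[1],
                                                             branch_range[2]))
    tree$tip.label <- sprintf("taxon%02d", seq_len(n_taxa))
    ptree <- tree
    if (length(perturb_genes)) {
      repeat {
        ptree <- phangorn::rNNI(tree, moves = 1L)
        if (phangorn::RF.dist(tree, ptree) > 0) break
      }
    }
    prof <- make_usage_profile(0.5, 0.3, seed = sample.int(1e9L, 1L), code = code)
    root <- simulate_genome(prof, n_genes = 1L, seed = sample.int(1e9L, 1L),
                            code = code)
    hk <- extract_housekeeping(root)
    root_genes <- c(hk, list(`16S` = random_nucleotides(1500L, 0.54,
                                                        sample.int(1e9L, 1L))))
    list(tree = tree, ptree = ptree, root_genes = root_genes,
         seeds = sample.int(1e9L, 2L))
  })
  alns <- list()
  for (g in names(parts$root_genes)) {
    tr <- if (g %in% perturb_genes) parts$ptree else parts$tree
    alns[[g]] <- evolve_clade(tr, parts$root_genes[g], kappa,
                              seed = parts$seeds[1] + match(g, names(parts$root_genes))
                              )$alignments[[1]]
  }
  list(tree = parts$tree, perturbed_tree = parts$ptree, kappa = kappa,
       alignments = alns, true_distances = stats::cophenetic(parts$tree),
       perturb_genes = perturb_genes, seed = as.integer(seed))
}
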