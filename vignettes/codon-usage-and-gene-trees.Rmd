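---
title: "Codon usage bias profiling and housekeeping-gene trees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias profiling and housekeeping-gene trees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubphylo)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical edge cases, and what the synthetic data
do and do not demonstrate.

## The measurement model

Synonymous codon usage in bacteria is shaped by two forces: mutational GC
pressure, which acts on all positions and is most visible at silent third
positions, and translational selection, which concentrates usage on
preferred codons. The package quantifies per-gene bias with Wright's
effective number of codons. Within each amino-acid family, from $n$ codon
observations with within-family frequencies $\hat p_i$, the homozygosity
estimate is

$$\hat F = \frac{n\sum_i \hat p_i^2 - 1}{n-1},$$

zero at perfect evenness (attainable at $n = 2$) and one at fixation. With
$\bar F_k$ the mean over usable families of degeneracy class $k$, the
bacterial code (table 11: 2 one-fold, 9 two-fold, 1 three-fold, 5 four-fold
and 3 six-fold families, the six-fold amino acids Leu/Ser/Arg kept whole)
gives

$$N_c = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} + \frac{5}{\bar F_4} + \frac{3}{\bar F_6}.$$

Numerical choices, all of which matter only for short or degenerate genes:

* a family with $n < 2$ is dropped from its class mean;
* an empty three-fold class (no usable Ile family) is imputed as
  $(\bar F_2 + \bar F_4)/2$, the standard convention; we apply the same
  imputation to an empty six-fold class, a case the convention does not
  cover, because leaving it undefined would discard otherwise healthy genes
  over the rarest class while the two-/four-fold average is the best
  available proxy;
* if $\bar F_2$ or $\bar F_4$ is unavailable, Nc is reported as MISSING
  (`NA` in memory, the literal token `MISSING` in TSV output);
* raw values above 61 — a finite-sample artifact near even usage, where
  $1/\bar F$ terms overshoot — are capped at exactly 61, keeping reported
  values in the analytic range $[20, 61]$.

GC3 is the G/C fraction at third positions over all sense codons (terminal
stop excluded, initiator included). Whether published "GC3" figures are this
plain variant or the synonymous-families-only variant is often unstated;
both are computed (`gc3()`, `gc3s()`), plain GC3 being the default used in
summaries. Hydrophobicity is the Kyte–Doolittle GRAVY of the translated
product; the initiator codon is translated by the table (so a GTG start
counts as Val), matching how codon-usage software counts codons rather than
post-translational reality.

The Nc plot compares each gene to the mutation-only expectation
$N_c(s) = 2 + s + 29/(s^2 + (1-s)^2)$: if bias comes solely from mutational
GC pressure, genes sit on the curve; selection pulls them below it. A genome
is labeled by its mean GC3 as left- (< 1/3), mid- (1/3–2/3) or
right-centric (> 2/3) aggregation. The thresholds are ours: the boundaries
are calibrated so that the three canonical regimes near GC3 0.10, 0.47 and
0.95 land in separate classes; hybrid labels ("mid with right shift") are
not formalized. The selection call in `run_ncplot()` is majority-vote:
"selection" when more than half the genes fall below the curve. Note that an
entirely bias-free genome still places roughly half its genes below the
curve — the curve is a central expectation, not an upper envelope — so the
call is informative only away from the boundary.

## Validation rules for input CDS

A gene enters the analysis only if its length is a multiple of three, it
starts with ATG/GTG/TTG (table-11 initiators; GTG/TTG starts are common in
high-GC Actinobacteria, so ATG-only filtering would bias exactly the most
interesting genomes), ends with a stop, and contains no internal stop and no
ambiguity codes. Ambiguous bases invalidate a record rather than being
resampled, because count-based statistics would be biased by imputation.
16S rRNA records (gene symbol `16S`) are not protein CDS: they bypass the
structural checks, are excluded from codon metrics and coding-base
statistics, and exist solely for the phylogenetics stage. When a genome
carries several valid copies of a housekeeping symbol the longest is used
and a warning logged; the choice is arbitrary but deterministic.

## Rank-based comparisons

Cross-genome relations (Nc_avg against genome size, coding bases, GC
content; coding frequency against both) use Spearman's rank correlation
with mid-rank ties, exact permutation p-values for tie-free $n \le 9$ and
the t approximation otherwise. Housekeeping-gene signatures use
Kruskal–Wallis across the four genes and Mann–Whitney between Gram groups;
the Mann–Whitney U reported is $\min(U_1, U_2)$, with exact enumeration for
tie-free $n_1 n_2 \le 400$, a tie- and continuity-corrected normal
approximation otherwise, and the fully degenerate all-equal case defined as
$U = n_1 n_2/2$, $p = 1$. All p-values are two-sided and unadjusted by
default (Benjamini–Hochberg available via `genome_correlations(adjust =`
`"BH")`). Exactness claims are backed by full-enumeration oracles in the
test suite.

## Distance phylogenetics

Tree building is deliberately distance-based: Kimura two-parameter (or
Jukes–Cantor/p) distances, neighbor-joining, and bootstrap majority-rule
consensus. Likelihood tree search and model selection are out of scope —
the congruence questions asked here are topological, NJ is deterministic
and fast at this scale, and NJ trees are the standard starting points of
likelihood searches anyway.

Gap handling is complete deletion: every column containing `-`, `N` or `?`
in any row is removed before distances. Pairs for which the K2P (or JC)
logarithm is undefined are *saturated*; a saturated pair aborts matrix
construction loudly by default, and only under `allow_saturation = TRUE` is
it imputed as 1.1 times the largest finite distance (inside bootstrap
replicates this imputation is always on, so one degenerate resample cannot
abort a run). Negative NJ branch lengths are set to zero with the deficit
pushed onto the edges below, preserving downstream path lengths. Bootstrap
resampling, like every stochastic step in the package, is a pure function
of an integer seed. Consensus trees keep only splits with > 50% support and
carry support percentages as node labels; like any majority-rule consensus
they have no meaningful branch lengths. Congruence is quantified by the
Robinson–Foulds distance, normalized by $2(n-3)$, with the 16S tree as the
conventional reference.

## The synthetic-data generator

The simulator exists so that every stage has inputs with known truth.

* `make_usage_profile(s_target, beta, seed)` sets within-family codon
  weights to `s_target` for G/C-ending codons and `1 - s_target` otherwise,
  then multiplies the weight-maximal codon of each family (seeded tie-break)
  by `exp(beta)` and renormalizes. A pure power transform of the weights
  cannot concentrate a family whose weights tie (at `s_target = 0.5` it
  leaves every family uniform no matter how large the exponent), so
  concentration is implemented as the preferred-codon boost; `beta = 0`
  recovers the pure GC3 mixture and expected Nc decreases strictly in
  `beta` at fixed GC3.
* `simulate_genome()` draws amino-acid sequences from a fixed average
  bacterial composition (`AA_BACKGROUND`; only stationarity matters),
  samples codons from the profile, appends valid start/stop, and tags four
  housekeeping genes at typical lengths (~3.5/1.4/2.7/1.2 kb). Background
  genes default to 150–500 codons.
* `simulate_collection()` fixes two study designs. The *envelope* preset
  (12 genomes, GC3 targets 0.10–0.95, `beta = 0.8 s`) reproduces the
  observed genomic envelope — GC3_avg from ~0.10 to ~0.97 and Nc_avg from
  ~30 to ~58 — so every classifier branch is exercised. Because the null
  curve bounds attainable Nc, an AT-rich genome cannot exceed Nc ≈ 37 even
  when unbiased; across the full GC range Nc_avg is therefore necessarily
  non-monotone in GC. The *gc_coupled* preset (GC3 0.45–0.95, bias rising
  linearly with GC, gene count and coding frequency rising with GC) encodes
  the regime in which codon bias strengthens with genomic GC; on it the
  collection-level Spearman signs (Nc_avg negatively correlated with GC,
  coding bases and genome size; coding frequency positively with GC) are
  recovered. Problem sizes — 12 genomes of ~60–120 genes — keep a full
  collection analysis under a minute.
* `evolve_clade()` evolves each site independently down a tree under the
  two-parameter process, implemented directly from the closed-form branch
  transition probabilities with rates normalized so branch lengths are
  expected substitutions per site ($\alpha + 2\beta = 1$,
  $\alpha/\beta = \kappa$). Evolution is indel-free, so ortholog sets are
  natively aligned and `complete_deletion()` is the identity on them — a
  property the tests assert. `simulate_clade()` adds a root genome, a
  16S-like root sequence (1.5 kb, GC 0.54), and optional genes evolved on a
  tree one NNI move away, the controlled analogue of a gene with
  conflicting phylogenetic signal.

What the simulator does **not** emulate: operon/gene-order structure,
horizontal transfer, among-site rate heterogeneity, indels, amino-acid
composition differences between genomes, or intra-genomic heterogeneity of
mutational pressure. Passing tests on simulated collections therefore
demonstrate correctness of the estimators and the recoverability of the
designed effects — not that real soil-bacterial collections will show
effects of the same magnitude.

## Determinism and output conventions

All randomness flows through integer seeds; reruns with the same seed and
configuration produce byte-identical TSV and Newick outputs (PDF plots embed
a creation timestamp and are excluded from that guarantee; no quantitative
result is read from a plot). Tables use the explicit `MISSING` token for
undefined values by default; the `table_parity` switch instead prints 0.00
for absent housekeeping genes with delta equal to the genomic average — a
convention some published tables use, in which absence is coded as zero in
the arithmetic — and rounds to two decimals, for byte-comparable output.
Both conventions are supported because published tables are ambiguous on
the intent; analysis code should prefer the MISSING form.

## Known limitations

* Nc variants that correct for background nucleotide composition are not
  implemented, nor are RSCU/CAI/correspondence-analysis diagnostics.
* The Mann–Whitney "exact" route narrows to tie-free samples (the
  enumeration distribution is otherwise undefined in the classical sense).
* Saturation imputation (×1.1 of the largest finite distance) is a
  pragmatic device for bootstrap robustness, not a statistical estimator.
* The centric-aggregation thresholds are calibration constants, not
  estimated quantities; genomes near 1/3 or 2/3 mean GC3 are labeled
  arbitrarily precisely at the boundary.
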