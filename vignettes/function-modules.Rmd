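---
title: "Function-module discovery and lineage-plasticity scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function-module discovery and lineage-plasticity scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasticmod)
```

# The problem

Prostate cancer cells can escape androgen-receptor-directed therapy by
shifting differentiation state — lineage plasticity — up to a
neuroendocrine, AR-independent phenotype. Evidence for the processes behind
this shift is scattered across omics layers: differential expression,
prognostic lncRNAs, extraprostatic-extension genes, SNV-associated genes,
CNV-associated genes, and methylation-driven genes each nominate a gene
set. `plasticmod` implements the integrative machinery that turns those six
gene sets into *function modules* (clusters of enriched GO/KEGG-like
terms), scores individual samples for a plasticity phenotype, and follows
the downstream threads: copy-number state, mutation-stratum enrichment, a
fixed prognostic lncRNA score, and regulon-based transcription-factor
activity.

Every stage is exercised against synthetic data with planted structure, so
the pipeline is testable end to end without external cohort downloads.

# Enrichment

Over-representation uses the hypergeometric upper tail. With a universe of
$N$ genes, a term of $M$ genes, a query of $n$ genes and $k$ hits,

$$P(X = k) = \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}},
\qquad p = \sum_{k' \ge k} P(X = k').$$

Choices that the enrichment literature leaves open:

* **Tail, not point mass.** The point probability alone is not a test;
  "enriched" means the upper tail $P(X \ge k)$.
* **q-values** are Benjamini–Hochberg adjusted p-values, the dominant
  convention in enrichment tooling; the retention filter is
  `p < alpha_p` **and** `q < alpha_q` (defaults 0.05/0.05).
* **Universe** is the supplied gene universe (all measurable genes), not
  the union of term genes; an explicit argument so callers can switch.
* Terms with $k = 0$ get $p = 1$ and stay in the table until the filter,
  keeping BH denominators equal to the number of terms tested.

# Kappa agreement and module clustering

Two enriched terms are compared as binary gene-membership classifications
over the universe. With the 2×2 table $(a, b, c, d)$ (both / first only /
second only / neither), observed agreement $p_o = (a+d)/N$ and chance
agreement $p_e = \big((a{+}b)(a{+}c) + (c{+}d)(b{+}d)\big)/N^2$ give
Cohen's kappa $(p_o - p_e)/(1 - p_e)$. When $p_e = 1$ (both sets empty or
both the whole universe) the limit is taken as 1 for identical sets, 0
otherwise. The clustering dissimilarity is $d = 1 - \kappa \in [0, 2]$.

The tree is built by the bottom-up neighbor-joining agglomeration
(Saitou–Nei): join the pair minimizing
$Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$, assign branch lengths by the
standard formulas, reduce with
$d(u,k) = \tfrac12\big(d(i,k) + d(j,k) - d(i,j)\big)$. Numerical
conventions:

* Negative branch-length estimates (possible on non-additive input) are
  clamped to zero with the deficit moved to the sibling branch, the usual
  practice; on additive matrices the generating tree is recovered exactly
  (tested to 1e-9 over random 4–6-leaf trees).
* Q ties break by column-major matrix order, so the output Newick string
  is a deterministic function of the input.

**Tree cut.** The source material fixes the outcome (six modules), not the
rule. We remove the $K-1$ longest *internal* branches and read modules off
the connected leaf components, with $K$ a parameter defaulting to 6. If a
tree has fewer internal branches than $K-1$ (a star), the longest terminal
branches are removed next; a removed terminal branch may isolate a leaf
that was already alone, so $K$ is an upper bound in degenerate cases.
Modules are numbered by size descending, ties by lexicographically
smallest member — arbitrary but fixed for reproducibility. Terms enriched
in several omics sources enter the matrix once; their source multiplicity
is kept for the per-module source-count summaries.

# Sample scoring

**ssGSEA.** Per sample, genes are ranked by expression (descending, ties
by gene id); the score integrates the difference between the
rank-weighted ECDF of the gene set (weight $|\mathrm{rank}|^\alpha$,
$\alpha = 0.25$, the single-sample convention) and the uniform ECDF of the
other genes, then min–max normalizes across samples to $[0, 1]$. Because
the weight depends only on rank position, the score is *exactly* invariant
under any strictly monotone per-sample transform of expression — a tested
identity, not an approximation.

**Gene–trait correlation.** The WGCNA-derived step implemented here is the
gene-significance correlation: Pearson correlation of each module gene
against the per-sample plasticity score, retaining positives (the full
signed table is also emitted for audit). Full WGCNA network construction
(soft-thresholding, TOM, eigengenes) is deliberately out of scope.

**Preranked GSEA.** The classic weighted running sum: hits increment by
$|s|^{w}$ ($w = 1$) normalized over set hits, misses decrement by
$1/(N - N_{hit})$; ES is the extremum; the leading edge is the hit genes
at or before the extremum (after it, for negative ES). The null
permutes gene labels (size-matched random sets) because the preranked
setting has no phenotype labels to permute. The permutation p compares
magnitudes, $p = (1 + \#\{|ES_{null}| \ge |ES|\})/(1 + n_{perm})$: this
form is uniform on a $(0,1]$ lattice under the null (probability integral
transform of $|ES|$ against its own permutation distribution) and attains
$1/(1+n_{perm})$ for a maximally enriched set. Conditioning the count on
the observed sign while dividing by all permutations — a formulation one
sometimes sees — concentrates null p-values below ~0.5 and is not
calibrated; our test suite checks calibration by Kolmogorov–Smirnov
against the uniform. NES divides ES by the mean |null ES| of the same
sign. The plasticity pipeline splits samples at the median score
("high" vs "low"), ranks genes by difference of group means, and runs
preranked GSEA per pathway set.

# CNV and SNV

Copy number is $CN = 2^{\mathrm{Segment}+1}$, reading Segment as the
log2-ratio segment mean — the only reading under which the printed
thresholds align with integer copy states. Categories:
$CN > 3.5 \to 2$; $2.5 < CN \le 3.5 \to 1$; $CN < 0.5 \to -2$;
$0.5 \le CN < 1.5 \to -1$; else 0. Boundaries are exact and tested at
$CN \in \{0.5, 1.5, 2.5, 3.5\}$.

Association tests: a chi-square test of category × tumor/normal per gene
(zero-count categories dropped; when > 20% of expected cells are below 5,
a seeded 2000-resample Monte-Carlo chi-square replaces the asymptotic p —
sparse CNV categories are common); and a Kruskal–Wallis test of expression
across category levels (needs ≥ 2 levels with ≥ 2 samples each). Both
families are BH-adjusted and both hold their nominal type-I error within
±2% at $\alpha = 0.05$ in the null simulations of the acceptance suite.
Prevalence reports, per significant gene, the most frequent *non-zero*
category among tumor samples (ties: larger |category|, then amplification
over deletion) as a fraction of tumor samples. Mutation-stratum enrichment
reuses the hypergeometric machinery with samples as the population.
Gleason grade groups and the T-stage extraprostatic/intraprostatic split
are implemented as labeled utilities following the standard grading rules.

# Survival risk score

The five-lncRNA model is applied as printed constants — coefficients
(−0.56041, 0.81588, 1.234135, 0.511379, 0.297335) for AC106881.1,
PRRT3-AS1, AC004148.2, AP000844.2, AL354710.2, threshold 0.8789252 — with
no refitting: Cox estimation, lncRNA selection and ROC validation are out
of scope, and the expression normalization behind the constants is
unstated upstream, so the module is deliberately unit-blind. A score
exactly at the threshold is classified "low" (strict inequality for
"high"); the boundary convention is documented and tested. Discrimination
is Harrell's C over permissible pairs (earlier observed event vs longer
follow-up; tied scores count 0.5; tied times are not permissible),
verified pairwise against the `survival` package's estimator.

# TF activity

Full VIPER aREA (three-tailed, likelihood-weighted) requires regulon
construction data that is not an input here, so activity is the simplified
signed rank-mean that preserves its rank-based, mode-signed character:
signature scores are rank-transformed to $(0,1)$ and a TF's statistic is
$\mathrm{mean}_t\, m_t\,(2 r_t - 1)$ over targets $t$ with modes
$m_t \in [-1, 1]$. The null resamples size-matched random target sets with
random ±1 modes under a fixed seed; z-scores over null regulons are
approximately standard normal (tested). Knockdown-signature enrichment is
a hypergeometric overlap against the target set, with the "> 14 hits"
retention filter as a configurable `min_hits = 14` default.

# The synthetic world

The generator's defaults state one fixed world: 1000 genes, 60 terms in 6
blocks of 10 (mirroring the six function modules), within-block Jaccard ≥
0.6, term sizes 20–50, 100 samples, unit expression shift against unit
Gaussian noise, 30% amp/del rates on planted CNV genes, 5% background
mutation rate, 30% censoring. One root seed derives every sub-stage seed,
so stages are individually reproducible and identical seeds give
byte-identical outputs.

Construction notes and the reasoning behind them:

* **Blocked terms.** Each block has a shared core and per-term unique
  genes; the core size $c = \lceil 2 s_{max} j/(1+j)\rceil$ makes the
  worst same-block pair clear the Jaccard floor $j$ exactly. Cores are
  drawn *disjointly* across blocks (a single shuffled draw of the
  universe): if cores were drawn independently, a chance core–core
  overlap would place the same genes in *every* term of two blocks and
  systematically blur block identity in the enrichment tables. Unique
  parts are drawn outside all cores, so between-block overlap is that of
  independent random draws from the non-core universe.
* **Expression noise is Gaussian** because the downstream operations are
  rank- and correlation-based (distribution-light) and Gaussianity gives
  analytic power checks (d = 1 at 50/group ⇒ t-test power ≈ 0.94, tested).
* **CNV segments.** Baseline Segment ~ Normal(0, 0.05) keeps the null
  case strictly in category 0 (the single-gain boundary sits at 6.4 SD);
  planted amplifications draw Segment ~ Normal(1.3, 0.1) so
  $CN = 2^{S+1} > 3.5$ with margin, deletions Normal(−2.6, 0.2) so
  $CN < 0.5$.
* **Survival** times are exponential with rate
  $\exp(\text{scale} \times \text{linear score})$ — the simplest
  proportional-hazards generator; a Binomial(censoring_rate) subset of
  samples is censored at a Uniform(0,1) multiple of its event time, which
  hits the configured censoring fraction in expectation while keeping
  censoring times positive and below the event time.
* **Regulons**: 50 TFs × 20 signed targets; the planted active TF's +1
  targets are shifted up and −1 targets down by 3 noise SDs in the
  returned signature.

What a green test does *not* establish: the generator makes no attempt to
mimic real TCGA marginal distributions, library-size effects, batch
structure, gene–gene correlation, or read-level data. Recovery of planted
structure demonstrates the algorithms' correctness and calibration, not
their performance on cohort data.

# Known limitations

* The tree-cut rule guarantees *at most* K modules on degenerate trees
  (see above); on the blocked synthetic world it recovers exactly K.
* The chi-square Monte-Carlo fallback makes that p-value seeded-stochastic
  rather than closed-form; the seed is a documented argument.
* The risk model inherits the unstated normalization of its printed
  coefficients; applying it to arbitrarily scaled expression shifts the
  score scale, not the ordering (C-index is transform-invariant).
* Pipeline configs are JSON, not YAML, because no YAML parser is part of
  the supported dependency footprint.
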