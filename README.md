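# plasticmod

Multi-omics function-module discovery and lineage-plasticity scoring for
prostate-cancer-style analyses.

Prostate cancer cells can escape androgen-receptor-directed therapy by
shifting lineage — up to a neuroendocrine, AR-independent state. Evidence
for the processes involved arrives layer by layer: differentially
expressed genes, prognostic lncRNAs, extraprostatic-extension genes, and
SNV-, CNV- and methylation-associated genes. `plasticmod` provides the
integrative machinery to

1. **enrich** each omics gene set against a term database
   (hypergeometric upper tail, $p = \sum_{k' \ge k}
   \binom{M}{k'}\binom{N-M}{n-k'}/\binom{N}{n}$, BH q-values,
   p/q < 0.05 filters);
2. **cluster** the pooled enriched terms into *function modules*:
   Cohen's kappa agreement $\kappa = (p_o - p_e)/(1 - p_e)$ between term
   gene memberships, neighbor joining on $d = 1 - \kappa$, and a
   longest-internal-branch tree cut into K modules (default 6);
3. **score samples** for a plasticity phenotype with ssGSEA
   (rank weight $|\mathrm{rank}|^{0.25}$, min–max normalized), correlate
   module genes with the score (positives retained), and run preranked
   GSEA with leading-edge extraction on a high-vs-low median split;
4. **categorize CNV** ($CN = 2^{\mathrm{Segment}+1}$; states −2…2 at the
   0.5/1.5/2.5/3.5 copy-number boundaries), test associations
   (chi-square, Kruskal–Wallis), summarize prevalence, and test
   mutation-stratum enrichment;
5. **apply the five-lncRNA risk score**
   (−0.56041·AC106881.1 + 0.81588·PRRT3-AS1 + 1.234135·AC004148.2 +
   0.511379·AP000844.2 + 0.297335·AL354710.2, threshold 0.8789252) and
   evaluate Harrell's C;
6. **infer TF activity** from signed regulons by a VIPER-style signed
   rank-mean with an empirical permutation null, plus
   knockdown-signature overlap with a `min_hits = 14` filter.

A first-class synthetic-data generator plants every structure the
pipeline is supposed to find (term blocks, a shifted sample subgroup,
amplified/deleted genes, a stratum-enriched mutation, a hazard-linked
score, an active TF), so the whole analysis is testable offline.

## Worked example

```r
library(plasticmod)

cfg     <- sim_config(seed = 7)                 # the stated synthetic world
world   <- gen_universe_and_terms(cfg)          # 1000 genes, 60 terms, 6 blocks
sources <- gen_omics_gene_sets(world$universe, world$terms, world$blocks, cfg)

tabs <- lapply(sources, enrich_terms,
               terms = world$terms, universe = world$universe)
sapply(tabs, nrow)
#> 10 10 10 10 10 10          # each source retains its block's 10 terms

dm        <- build_kappa_distance_matrix(tabs, world$terms, world$universe)
partition <- cut_tree(nj_tree(dm), 6)
table(partition)
#> 10 10 10 10 10 10          # six modules of ten terms
adjusted_rand_index(partition, world$blocks[names(partition)])
#> 1                          # planted blocks recovered exactly

mod6 <- unique(unlist(world$terms[names(world$blocks)[world$blocks == 6]]))
e    <- gen_expression_with_phenotype(world$universe, mod6, cfg)
sc   <- ssgsea_score(e$expr, mod6)
round(c(shifted = mean(sc[e$labels == "shifted"]),
        null    = mean(sc[e$labels == "null"])), 3)
#> shifted  null
#>   0.837 0.220               # the planted subgroup scores high

sr <- gen_survival_and_regulons(sim_config(seed = 11, n_samples = 200))
concordance_index(sr$true_score, sr$survival$time, sr$survival$event)
#> 0.8960362                  # the linear score discriminates survival

head(risk_score(sr$survival[, risk_model()$covariates]), 3)
#>   sample      score stratum
#> 1   s001  1.0163580    high
#> 2   s002 -0.1629002     low
#> 3   s003 -3.4310278     low
```

The enrichment counts say each omics source's retained terms come from
its planted block; the Adjusted Rand Index of 1 says the kappa/NJ/cut
chain reassembled those blocks perfectly; the ssGSEA means show the
planted phenotype separating; the C-index ≈ 0.9 and the risk table show
the shipped linear model scoring and stratifying samples.

## End-to-end pipeline and CLI

```r
run_all(pipeline_config(seed = 7), "out/")   # 7 stages + manifest.json
```

or from a shell (the CLI lives under `inst/cli/`, so after installation
use `system.file("cli", "plasticmod.R", package = "plasticmod")`):

```sh
Rscript inst/cli/plasticmod.R simulate --seed 7 --outdir out
Rscript inst/cli/plasticmod.R enrich --query out/sources.gmt \
    --terms out/terms.gmt --universe out/universe.txt --out enr.tsv
Rscript inst/cli/plasticmod.R cluster --enrichment-tables enr.tsv \
    --terms out/terms.gmt --universe out/universe.txt --k 6 --outdir out
Rscript inst/cli/plasticmod.R risk --covariates cov.tsv --out risk.tsv
Rscript inst/cli/plasticmod.R tf-activity --regulons out/regulons.gmt \
    --signature sig.tsv --n-perm 1000 --seed 1 --out tf.tsv
```

Rerunning any stage with the same seed reproduces byte-identical outputs;
`manifest.json` records parameters and md5 checksums per stage.

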