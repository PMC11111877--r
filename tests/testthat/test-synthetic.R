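test_that("term generation respects the configured counts and blocks", {
  w <- tiny_world(seed = 7, n_genes = 1000, n_terms = 60, n_blocks = 6)
  expect_length(w$terms, 60)
  expect_equal(unname(table(w$blocks)), rep(10L, 6), ignore_attr = TRUE)
  expect_true(all(unlist(w$terms) %in% w$universe))
  expect_false(anyDuplicated(w$universe) > 0)
})

test_that("within_block_jaccard = 1 forces identical sets per block", {
  w <- tiny_world(seed = 3, n_terms = 12, n_blocks = 3,
                  within_block_jaccard = 1)
  for (b in 1:3) {
    sets <- w$terms[names(w$blocks)[w$blocks == b]]
    expect_true(all(vapply(sets, identical, TRUE, y = sets[[1]])))
  }
})

test_that("planted Jaccard structure verified by brute-force pairwise", {
  w <- tiny_world(seed = 7, n_genes = 1000, n_terms = 60, n_blocks = 6,
                  within_block_jaccard = 0.6)
  bj <- block_jaccard(w$terms, w$blocks)
  expect_gte(bj$within, 0.6)
  expect_lt(bj$between, 0.1)
  # the guarantee is pairwise, not just on the mean
  for (b in c(1, 6)) {
    idx <- which(w$blocks == b)
    for (i in head(idx, -1)) for (j in idx[idx > i]) {
      expect_gte(jaccard(w$terms[[i]], w$terms[[j]]), 0.6)
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(term_size_range = c(10, 2000)), "universe")
  expect_error(sim_config(n_blocks = 10, n_terms = 5), "n_blocks")
  expect_error(sim_config(within_block_jaccard = 1.5), "rates|fractions")
  expect_error(sim_config(n_genes = 1), "at least 2")
})

test_that("identical seeds reproduce byte-identical outputs", {
  cfg <- sim_config(seed = 11, n_genes = 200, n_terms = 12, n_blocks = 3,
                    n_samples = 20)
  expect_identical(gen_universe_and_terms(cfg), gen_universe_and_terms(cfg))
  w <- gen_universe_and_terms(cfg)
  expect_identical(
    gen_omics_gene_sets(w$universe, w$terms, w$blocks, cfg),
    gen_omics_gene_sets(w$universe, w$terms, w$blocks, cfg))
  expect_identical(
    gen_expression_with_phenotype(w$universe, w$terms[[1]], cfg),
    gen_expression_with_phenotype(w$universe, w$terms[[1]], cfg))
  expect_identical(gen_cnv_and_mutations(w$universe, cfg),
                   gen_cnv_and_mutations(w$universe, cfg))
  expect_identical(gen_survival_and_regulons(cfg),
                   gen_survival_and_regulons(cfg))
})

test_that("six omics sources are produced with universe-bound members", {
  w <- tiny_world(seed = 7, n_genes = 300, n_terms = 18, n_blocks = 6,
                  term_size_range = c(10, 20))
  sources <- gen_omics_gene_sets(w$universe, w$terms, w$blocks, w$config)
  expect_length(sources, 6)
  expect_setequal(vapply(sources, function(s) s$source, ""),
                  c("DEG", "lncRNA", "extraprostatic", "SNV", "CNV",
                    "methylation"))
  for (s in sources) {
    expect_true(all(s$genes %in% w$universe))
    expect_length(s$logfc, length(s$genes))
  }
  expect_error(
    gen_omics_gene_sets(w$universe, w$terms, w$blocks, w$config,
                        assignment = list(bogus = 1)), "unknown source")
})

test_that("noise-free single-block source stays inside its block's terms", {
  w <- tiny_world(seed = 5, n_genes = 300, n_terms = 12, n_blocks = 3,
                  term_size_range = c(10, 20))
  src <- gen_omics_gene_sets(w$universe, w$terms, w$blocks, w$config,
                             assignment = list(DEG = 1),
                             noise_fraction = 0)[[1]]
  block1_genes <- unique(unlist(w$terms[names(w$blocks)[w$blocks == 1]]))
  expect_true(all(src$genes %in% block1_genes))
})

test_that("expression shift lands on module genes in the shifted group", {
  w0 <- tiny_world(seed = 3, n_genes = 200, n_samples = 40,
                   signal_effect = 0, n_terms = 12, n_blocks = 3,
                   term_size_range = c(10, 20))
  mod <- w0$terms[[1]]
  e0 <- gen_expression_with_phenotype(w0$universe, mod, w0$config)
  shifted <- names(e0$labels)[e0$labels == "shifted"]
  nulls <- names(e0$labels)[e0$labels == "null"]
  delta <- mean(e0$expr[mod, shifted]) - mean(e0$expr[mod, nulls])
  se <- sqrt(2 / (length(mod) * 20))
  expect_lt(abs(delta), 3 * se)

  w10 <- tiny_world(seed = 3, n_genes = 200, n_samples = 40,
                    signal_effect = 10, n_terms = 12, n_blocks = 3,
                    term_size_range = c(10, 20))
  e10 <- gen_expression_with_phenotype(w10$universe, mod, w10$config)
  delta10 <- mean(e10$expr[mod, shifted]) - mean(e10$expr[mod, nulls])
  expect_equal(delta10, 10, tolerance = 0.05)

  expect_error(
    gen_expression_with_phenotype(w0$universe, character(0), w0$config),
    "non-empty")
})

test_that("planted shift gives the analytically expected t-test power", {
  # d = 1, n = 50/group: power of the two-sided t at alpha = .05 is ~0.94
  cfg <- sim_config(seed = 3, n_genes = 500, n_samples = 100,
                    signal_effect = 1, noise_sd = 1)
  w <- gen_universe_and_terms(cfg)
  mod <- unique(unlist(w$terms[names(w$blocks)[w$blocks == 1]]))
  e <- gen_expression_with_phenotype(w$universe, mod, cfg)
  grp <- e$labels == "shifted"
  pvals <- apply(e$expr[mod, , drop = FALSE], 1, function(x)
    t.test(x[grp], x[!grp])$p.value)
  expect_gte(mean(pvals < 0.05), 0.9)
})

test_that("cnv generator honours null and planted configurations", {
  cfg0 <- sim_config(seed = 5, n_genes = 100, n_samples = 30,
                     cnv_amp_rate = 0, cnv_del_rate = 0)
  universe <- sprintf("g%04d", 1:100)
  c0 <- gen_cnv_and_mutations(universe, cfg0)
  expect_true(all(segment_to_category(c0$segments) == 0))

  cfg <- sim_config(seed = 5, n_genes = 100, n_samples = 100,
                    mutation_rate = 0.05)
  cm <- gen_cnv_and_mutations(universe, cfg)
  expect_setequal(unique(cm$strata), c("A", "B"))
  # planted mutation enrichment: rate 0.6 in A vs 0.05 in B, n = 50/50
  res <- mutation_strata_enrichment(cm$mutations, cm$strata, cm$mut_gene,
                                    "A")
  expect_lt(res$p, 1e-6)
  expect_equal(res$p,
               enum_upper_tail(res$counts$N, res$counts$M, res$counts$n,
                               res$counts$k), tolerance = 1e-12)

  cfg_bad <- sim_config(seed = 5, cnv_amp_rate = 0.6, cnv_del_rate = 0.6)
  expect_error(gen_cnv_and_mutations(universe, cfg_bad), "exceed 1")
})

test_that("survival generator rejects full censoring and plants a TF", {
  cfg <- sim_config(seed = 9, n_samples = 60, censoring_rate = 0.99)
  cfg$censoring_rate <- 1
  expect_error(gen_survival_and_regulons(cfg), "censoring_rate")
  cfg$censoring_rate <- 0.3
  sr <- gen_survival_and_regulons(cfg, tf_shift = 3, tf_noise = 1)
  expect_length(sr$regulons, 50)
  expect_true(sr$active_tf %in% names(sr$regulons))
  expect_equal(names(sr$signature),
               names(sort(sr$signature, decreasing = TRUE)))
  act <- regulon_activity(sr$signature, sr$regulons, n_perm = 300, seed = 1)
  expect_equal(act$tf[1], sr$active_tf)
})
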