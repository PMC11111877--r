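universe10 <- sprintf("g%02d", 1:10)

test_that("kappa_pair reproduces the direct 2x2 computation", {
  A <- universe10[1:3]; B <- universe10[2:4]
  # a=2, b=1, c=1, d=6 -> po=0.8, pe=0.58, kappa=0.22/0.42
  expect_equal(kappa_pair(A, B, universe10), direct_kappa(2, 1, 1, 6),
               tolerance = 1e-14)
  expect_equal(kappa_pair(A, B, universe10), 0.22 / 0.42, tolerance = 1e-12)
  expect_equal(kappa_pair(A, A, universe10), 1)
  expect_equal(kappa_pair(universe10[1:5], universe10[6:10], universe10), -1)
  expect_equal(kappa_pair(A, B, universe10), kappa_pair(B, A, universe10))
  expect_error(kappa_pair(c(A, "alien"), B, universe10), "subsets")
})

test_that("kappa degenerate cases take the pe = 1 limit", {
  expect_equal(kappa_pair(universe10, universe10, universe10), 1)
  expect_equal(kappa_pair(character(0), character(0), universe10), 1)
  expect_equal(kappa_pair(universe10, character(0), universe10), 0)
})

test_that("kappa matches the 2x2 oracle on random pairs", {
  set.seed(99)
  universe <- sprintf("g%03d", 1:200)
  for (i in 1:200) {
    A <- sample(universe, sample(1:100, 1))
    B <- sample(universe, sample(1:100, 1))
    a <- length(intersect(A, B)); b <- length(setdiff(A, B))
    c <- length(setdiff(B, A)); d <- 200 - a - b - c
    expect_equal(kappa_pair(A, B, universe), direct_kappa(a, b, c, d),
                 tolerance = 1e-12)
  }
})

test_that("kappa distance matrix is symmetric with the right structure", {
  terms <- list(t1 = universe10[1:4], t2 = universe10[1:4],
                t3 = universe10[1:4])
  tab <- data.frame(term = names(terms), source = "DEG",
                    stringsAsFactors = FALSE)
  dm <- build_kappa_distance_matrix(tab, terms, universe10)
  expect_true(all(dm$distance == 0))            # identical terms
  expect_equal(diag(dm$kappa), rep(1, 3), ignore_attr = TRUE)

  terms2 <- list(t1 = universe10[1:4], t2 = universe10[3:7],
                 t3 = universe10[6:9], t4 = universe10[1:2])
  tab2 <- data.frame(term = names(terms2), source = "DEG")
  dm2 <- build_kappa_distance_matrix(tab2, terms2, universe10)
  expect_lt(max(abs(dm2$distance - t(dm2$distance))), 1e-12)
  expect_equal(diag(dm2$distance), rep(0, 4), ignore_attr = TRUE)
  expect_true(all(dm2$distance >= 0))

  expect_error(build_kappa_distance_matrix(tab2[1:2, ], terms2, universe10),
               "at least 3")
})

test_that("duplicated terms across sources collapse to one matrix row", {
  terms <- list(t1 = universe10[1:4], t2 = universe10[3:7],
                t3 = universe10[6:9])
  tabs <- list(data.frame(term = c("t1", "t2"), source = "DEG"),
               data.frame(term = c("t2", "t3"), source = "CNV"))
  dm <- build_kappa_distance_matrix(tabs, terms, universe10)
  expect_equal(dm$labels, c("t1", "t2", "t3"))
  expect_equal(sum(dm$term_sources$term == "t2"), 2)  # multiplicity kept
})

test_that("nj_tree recovers the canonical 4-leaf topology", {
  d <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  tree <- nj_tree(d)
  expect_s3_class(tree, "phylo")
  # topology: (A,B) vs (C,D); path distances reproduce the additive input
  pd <- cophenetic(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pd, d, tolerance = 1e-9)
  ref <- ape::read.tree(text = "((A:1,B:1):1,C:2,D:2);")
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("3-leaf star branch lengths solve the pairwise equations", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  expect_equal(length(tree$tip.label), 3)
  pd <- cophenetic(tree)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(pd, d, tolerance = 1e-12)
})

test_that("nj_tree is exact on additive matrices from random trees", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    d <- cophenetic(ref)
    tree <- nj_tree(d)
    expect_equal(cophenetic(tree)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
    expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(ref)), 0)
  }
})

test_that("nj_tree validates its input", {
  d <- matrix(runif(9), 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d), "symmetric")
  d2 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d2[1, 2] <- d2[2, 1] <- -1
  expect_error(nj_tree(d2), "non-negative")
})

test_that("cut_tree produces valid partitions at the extremes", {
  set.seed(4)
  ref <- ape::rtree(8, br = function(k) runif(k, 0.5, 2))
  tree <- nj_tree(cophenetic(ref))
  p1 <- cut_tree(tree, 1)
  expect_true(all(p1 == 1))
  expect_setequal(names(p1), tree$tip.label)
  pk <- cut_tree(tree, 8)
  # on a general NJ tree a removed terminal branch may isolate a leaf that
  # was already alone, so K is an upper bound on the module count
  expect_lte(max(pk), 8)
  expect_gte(max(pk), 4)
  expect_setequal(names(pk), tree$tip.label)
  p3 <- cut_tree(tree, 3)
  expect_setequal(names(p3), tree$tip.label)   # partition covers all terms
  expect_true(all(p3 %in% 1:3))
  expect_error(cut_tree(tree, 0), "between")
  expect_error(cut_tree(tree, 9), "between")
})

test_that("cut_tree splits a star tree into singletons via leaf branches", {
  star <- ape::read.tree(text = "(A:1,B:2,C:3,D:4);")
  p <- cut_tree(star, 4)
  expect_equal(sort(unique(p)), 1:4)
})

test_that("module numbering is size-descending then lexicographic", {
  # two cherries of sizes 3 and 2 joined by one long internal branch
  tree <- ape::read.tree(
    text = "((A:1,B:1):5,(C:1,(D:1,E:1):1):5);")
  p <- cut_tree(tree, 2)
  expect_equal(unname(p[c("C", "D", "E")]), c(1, 1, 1))  # larger first
  expect_equal(unname(p[c("A", "B")]), c(2, 2))
})

test_that("pipeline determinism: identical inputs, identical Newick", {
  w <- tiny_world(seed = 7, n_genes = 300, n_terms = 18, n_blocks = 3,
                  term_size_range = c(10, 20))
  sources <- gen_omics_gene_sets(w$universe, w$terms, w$blocks, w$config)
  tabs <- lapply(sources, enrich_terms, terms = w$terms,
                 universe = w$universe)
  dm <- build_kappa_distance_matrix(tabs, w$terms, w$universe)
  t1 <- ape::write.tree(nj_tree(dm))
  t2 <- ape::write.tree(nj_tree(dm))
  expect_identical(t1, t2)
  expect_identical(cut_tree(nj_tree(dm), 3), cut_tree(nj_tree(dm), 3))
})

test_that("synthetic blocks separate: within-block < between-block distance", {
  w <- tiny_world(seed = 7, n_genes = 500, n_terms = 24, n_blocks = 4)
  tab <- data.frame(term = names(w$terms), source = "DEG")
  dm <- build_kappa_distance_matrix(tab, w$terms, w$universe)
  b <- w$blocks[dm$labels]
  same <- outer(b, b, `==`) & upper.tri(dm$distance)
  diff_b <- outer(b, b, `!=`) & upper.tri(dm$distance)
  expect_lt(mean(dm$distance[same]), mean(dm$distance[diff_b]))
})

test_that("summarize_modules counts sources and ranks genes by logFC", {
  w <- tiny_world(seed = 5, n_genes = 300, n_terms = 12, n_blocks = 3,
                  term_size_range = c(10, 20))
  sources <- gen_omics_gene_sets(w$universe, w$terms, w$blocks, w$config,
                                 assignment = list(DEG = 1, CNV = 3),
                                 noise_fraction = 0)
  tabs <- lapply(sources, enrich_terms, terms = w$terms,
                 universe = w$universe)
  dm <- build_kappa_distance_matrix(tabs, w$terms, w$universe)
  partition <- cut_tree(nj_tree(dm), 2)
  summ <- summarize_modules(partition, sources, w$terms, dm$term_sources)
  expect_length(summ, 2)
  for (m in summ) {
    expect_equal(sum(lengths(list(m$terms))), m$n_terms)
    # source count never exceeds the module's term count
    expect_true(all(m$source_counts <= m$n_terms))
    # per-source ranked lists are logFC-descending and inside union genes
    for (rk in m$ranked_by_source) {
      if (nrow(rk)) {
        expect_true(all(diff(rk$logfc) <= 1e-12))
        expect_true(all(rk$gene %in% m$union_genes))
      }
    }
  }
  # the module capturing block-3 terms is dominated by the CNV source
  b3_terms <- names(w$blocks)[w$blocks == 3]
  mod_of_b3 <- unique(partition[names(partition) %in% b3_terms])
  if (length(mod_of_b3) == 1) {
    s <- summ[[mod_of_b3]]
    expect_gte(s$source_counts[["CNV"]], s$source_counts[["DEG"]])
  }
})
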