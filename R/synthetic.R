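#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults describe a
#' desk-scale prostate-cancer-like world: 1000 genes, 60 terms in 6 planted
#' blocks of 10 (mirroring the six function modules), within-block Jaccard
#' 0.6, 100 samples, a unit expression shift against unit noise, 30%
#' amplification/deletion rates for planted CNV genes, 5% background
#' mutation rate, and 30% censoring.
#'
#' @param seed root integer seed; all sub-stage seeds derive from it.
#' @param n_genes universe size.
#' @param n_terms number of terms in the term database.
#' @param n_blocks number of planted term blocks (function modules).
#' @param term_size_range c(min, max) genes per term.
#' @param within_block_jaccard minimum pairwise Jaccard overlap of terms in
#'   the same block, in [0, 1].
#' @param n_samples sample count for expression/CNV/mutation/survival data.
#' @param signal_effect expression shift added to module genes in the
#'   shifted sample group (arbitrary units).
#' @param noise_sd expression noise standard deviation.
#' @param cnv_amp_rate,cnv_del_rate per-tumor-sample rates of planted
#'   amplification / deletion.
#' @param mutation_rate background mutation probability per gene and sample.
#' @param censoring_rate fraction of survival times censored, in [0, 1).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L, n_terms = 60L,
                       n_blocks = 6L, term_size_range = c(20L, 50L),
                       within_block_jaccard = 0.6, n_samples = 100L,
                       signal_effect = 1, noise_sd = 1,
                       cnv_amp_rate = 0.3, cnv_del_rate = 0.3,
                       mutation_rate = 0.05, censoring_rate = 0.3) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_terms = as.integer(n_terms), n_blocks = as.integer(n_blocks),
              term_size_range = as.integer(term_size_range),
              within_block_jaccard = within_block_jaccard,
              n_samples = as.integer(n_samples),
              signal_effect = signal_effect, noise_sd = noise_sd,
              cnv_amp_rate = cnv_amp_rate, cnv_del_rate = cnv_del_rate,
              mutation_rate = mutation_rate, censoring_rate = censoring_rate)
  fr <- c(cfg$within_block_jaccard, cfg$cnv_amp_rate, cfg$cnv_del_rate,
          cfg$mutation_rate, cfg$censoring_rate)
  if (any(fr < 0 | fr > 1)) stop("all rates/fractions must lie in [0, 1]")
  if (cfg$n_blocks > cfg$n_terms) stop("n_blocks must not exceed n_terms")
  if (length(cfg$term_size_range) != 2 ||
      cfg$term_size_range[1] > cfg$term_size_range[2]) {
    stop("term_size_range must be c(min, max) with min <= max")
  }
  if (cfg$n_genes < 2) stop("universe needs at least 2 genes")
  if (cfg$term_size_range[2] > cfg$n_genes) {
    stop("maximum term size exceeds the universe size")
  }
  structure(cfg, class = "sim_config")
}

#' An omics gene set with per-gene effect sizes
#'
#' @param source source name (e.g. "DEG", "CNV").
#' @param genes unique gene ids.
#' @param logfc signed per-gene effect sizes, aligned with `genes`.
#' @return an `omics_gene_set` object.
#' @export
omics_gene_set <- function(source, genes, logfc = NULL) {
  .check_ids(genes, "gene set members")
  if (is.null(logfc)) logfc <- rep(0, length(genes))
  stopifnot(length(logfc) == length(genes))
  names(logfc) <- genes
  structure(list(source = source, genes = genes, logfc = logfc),
            class = "omics_gene_set")
}

#' Generate a gene universe and a blocked term database
#'
#' Terms are partitioned into `n_blocks` blocks. Each block has a core gene
#' set shared by all of its terms; each term adds its own unique genes. Core
#' size is chosen so that the pairwise Jaccard of two same-block terms (core
#' over union) is at least `within_block_jaccard`. Block cores are drawn
#' independently, so between-block overlap is that of independent random
#' draws. Block labels are returned as ground truth.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with `universe` (character vector), `terms` (named list of
#'   gene vectors), `blocks` (named integer vector: term -> block).
#' @export
gen_universe_and_terms <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(derive_seed(config$seed, 1L), {
    universe <- sprintf("g%04d", seq_len(config$n_genes))
    n_terms <- config$n_terms
    block <- rep(seq_len(config$n_blocks), length.out = n_terms)
    block <- sort(block)
    j <- config$within_block_jaccard
    # per-block term sizes and core sizes; a same-block pair of sizes s1, s2
    # has Jaccard >= c / (2 max(sizes) - c), so c = ceil(2 max(sizes)
    # j / (1 + j)) makes the worst pair clear j (c <= max(sizes) since
    # 2j/(1+j) <= 1); smaller terms are raised to the core size.
    sizes <- vector("list", config$n_blocks)
    core_sizes <- integer(config$n_blocks)
    smin <- config$term_size_range[1]; smax <- config$term_size_range[2]
    for (b in seq_len(config$n_blocks)) {
      n_b <- sum(block == b)
      s <- if (smin == smax) rep(smax, n_b) else {
        sample(smin:smax, n_b, replace = TRUE)
      }
      core_sizes[b] <- ceiling(2 * max(s) * j / (1 + j))
      sizes[[b]] <- pmax(s, core_sizes[b])
    }
    if (sum(core_sizes) > config$n_genes) {
      stop("universe too small for disjoint block cores; increase n_genes ",
           "or lower within_block_jaccard / term sizes")
    }
    # block cores are disjoint (a shared core gene would sit in every term
    # of two blocks, blurring the planted structure); unique parts are
    # drawn outside all cores, so between-block overlap is that of
    # independent random draws from the non-core universe
    shuffled <- sample(universe)
    core_of <- split(shuffled[seq_len(sum(core_sizes))],
                     rep(seq_len(config$n_blocks), core_sizes))
    non_core <- shuffled[-seq_len(sum(core_sizes))]
    terms <- vector("list", n_terms)
    for (b in seq_len(config$n_blocks)) {
      idx <- which(block == b)
      for (t in seq_along(idx)) {
        uniq <- sample(non_core, sizes[[b]][t] - core_sizes[b])
        terms[[idx[t]]] <- sort(c(core_of[[b]], uniq))
      }
    }
    names(terms) <- sprintf("term%03d", seq_len(n_terms))
    names(block) <- names(terms)
    list(universe = universe, terms = terms, blocks = block)
  })
}

#' Generate six omics gene sets tied to planted term blocks
#'
#' Emulates the six multi-omics input datasets (differential expression,
#' prognostic-lncRNA neighborhood, extraprostatic-extension genes, SNV-,
#' CNV- and methylation-associated genes). Each source draws most of its
#' genes from its assigned blocks' term genes plus a configurable fraction
#' of background noise genes; signed logFC values are attached (block genes
#' get a positive shift, noise genes are centered at zero).
#'
#' @param universe gene ids from \code{\link{gen_universe_and_terms}}.
#' @param terms term database.
#' @param blocks ground-truth term -> block labels.
#' @param config a \code{\link{sim_config}}.
#' @param assignment named list mapping source name -> block ids; defaults
#'   to the six canonical sources mapped to blocks 1..6 (recycled).
#' @param coverage fraction of the assigned blocks' gene pool sampled into
#'   each source set.
#' @param noise_fraction fraction of each set drawn from background genes.
#' @return list of `omics_gene_set` objects.
#' @export
gen_omics_gene_sets <- function(universe, terms, blocks, config,
                                assignment = NULL, coverage = 0.6,
                                noise_fraction = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  canonical <- c("DEG", "lncRNA", "extraprostatic", "SNV", "CNV",
                 "methylation")
  if (is.null(assignment)) {
    assignment <- as.list(rep_len(seq_len(config$n_blocks),
                                  length(canonical)))
    names(assignment) <- canonical
  }
  if (!all(names(assignment) %in% canonical)) {
    stop("unknown source name(s): ",
         paste(setdiff(names(assignment), canonical), collapse = ", "))
  }
  .with_seed(derive_seed(config$seed, 2L), {
    lapply(names(assignment), function(src) {
      pool <- sort(unique(unlist(
        terms[names(blocks)[blocks %in% assignment[[src]]]],
        use.names = FALSE)))
      core <- sample(pool, max(2, round(coverage * length(pool))))
      n_noise <- round(noise_fraction * length(core) / (1 - noise_fraction))
      noise <- if (n_noise > 0) {
        sample(setdiff(universe, core), n_noise)
      } else character(0)
      genes <- c(core, noise)
      lfc <- c(stats::rnorm(length(core), mean = 2, sd = 0.5),
               stats::rnorm(length(noise), mean = 0, sd = 1))
      omics_gene_set(src, genes, lfc)
    })
  })
}

#' Generate expression with a planted group shift on module genes
#'
#' Gaussian noise throughout; the first half of samples ("shifted" group)
#' receives +signal_effect on the module gene rows.
#'
#' @param universe gene ids.
#' @param module_genes genes carrying the planted up-signal; must be a
#'   non-empty subset of the universe.
#' @param config a \code{\link{sim_config}}.
#' @return list with `expr` (genes x samples matrix) and `labels` (named
#'   character vector, "shifted"/"null" per sample).
#' @export
gen_expression_with_phenotype <- function(universe, module_genes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(module_genes)) stop("module_genes must be non-empty")
  if (length(setdiff(module_genes, universe))) {
    stop("module_genes must be a subset of the universe")
  }
  .with_seed(derive_seed(config$seed, 3L), {
    n <- config$n_samples
    samples <- sprintf("s%03d", seq_len(n))
    expr <- matrix(stats::rnorm(length(universe) * n, sd = config$noise_sd),
                   nrow = length(universe),
                   dimnames = list(universe, samples))
    shifted <- samples[seq_len(n %/% 2)]
    expr[module_genes, shifted] <- expr[module_genes, shifted] +
      config$signal_effect
    labels <- ifelse(samples %in% shifted, "shifted", "null")
    names(labels) <- samples
    list(expr = expr, labels = labels)
  })
}

#' Generate CNV segments, mutations, and clinical strata
#'
#' Segment values (log2-ratio scale) are Normal(0, 0.05) baseline, so the
#' copy number 2^(Segment + 1) sits near the diploid 2. Planted amplified
#' genes draw Segment ~ Normal(1.3, 0.1) (CN > 3.5 with margin) in a
#' cnv_amp_rate fraction of tumor samples; planted deletions draw
#' Segment ~ Normal(-2.6, 0.2) (CN < 0.5). The binary mutation matrix has a
#' background Bernoulli(mutation_rate); one planted gene is mutated at rate
#' 0.6 in stratum "A" versus 0.05 in stratum "B".
#'
#' @param universe gene ids.
#' @param config a \code{\link{sim_config}}.
#' @param n_cnv_genes number of planted amplified and deleted genes (each).
#' @return list with `segments` (matrix), `sample_groups` (tumor/normal),
#'   `mutations` (0/1 matrix), `strata` (named "A"/"B"), and ground truth
#'   `amp_genes`, `del_genes`, `mut_gene`.
#' @export
gen_cnv_and_mutations <- function(universe, config, n_cnv_genes = 5L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$cnv_amp_rate + config$cnv_del_rate > 1) {
    stop("cnv_amp_rate + cnv_del_rate must not exceed 1")
  }
  .with_seed(derive_seed(config$seed, 4L), {
    n <- config$n_samples
    samples <- sprintf("s%03d", seq_len(n))
    tumor <- samples[seq_len(n %/% 2)]
    groups <- ifelse(samples %in% tumor, "tumor", "normal")
    names(groups) <- samples
    segments <- matrix(stats::rnorm(length(universe) * n, sd = 0.05),
                       nrow = length(universe),
                       dimnames = list(universe, samples))
    planted <- sample(universe, 2L * n_cnv_genes)
    amp_genes <- planted[seq_len(n_cnv_genes)]
    del_genes <- planted[n_cnv_genes + seq_len(n_cnv_genes)]
    for (g in amp_genes) {
      hit <- tumor[stats::runif(length(tumor)) < config$cnv_amp_rate]
      segments[g, hit] <- stats::rnorm(length(hit), 1.3, 0.1)
    }
    for (g in del_genes) {
      hit <- tumor[stats::runif(length(tumor)) < config$cnv_del_rate]
      segments[g, hit] <- stats::rnorm(length(hit), -2.6, 0.2)
    }
    strata <- rep(c("A", "B"), length.out = n)
    names(strata) <- samples
    mutations <- matrix(
      as.integer(stats::runif(length(universe) * n) < config$mutation_rate),
      nrow = length(universe), dimnames = list(universe, samples))
    mut_gene <- sample(setdiff(universe, planted), 1L)
    rate <- ifelse(strata == "A", 0.6, 0.05)
    mutations[mut_gene, ] <- as.integer(stats::runif(n) < rate)
    list(segments = segments, sample_groups = groups, mutations = mutations,
         strata = strata, amp_genes = amp_genes, del_genes = del_genes,
         mut_gene = mut_gene)
  })
}

#' Generate survival data under a linear risk model, plus regulons
#'
#' Covariate expression is standard normal per sample; event times are
#' exponential with rate exp(effect_scale * linear score), so the hazard is
#' proportional to the score. A censoring_rate fraction of samples is
#' censored at a Uniform(0,1) multiple of its event time. Regulons are 50
#' TFs with 20 signed targets each; one TF is planted active: its +1
#' targets are up-shifted and its -1 targets down-shifted in the returned
#' ranked signature.
#'
#' @param config a \code{\link{sim_config}}.
#' @param model a \code{\link{risk_model}} (defaults to the shipped
#'   five-lncRNA model).
#' @param effect_scale multiplier on the linear score in the log-hazard
#'   ("strong effect" ~ 2).
#' @param n_regulons,regulon_size regulon count and targets per regulon.
#' @param tf_shift,tf_noise planted-TF target shift and signature noise sd.
#' @return list with `survival` (data.frame sample/time/event + covariates),
#'   `regulons` (list of `regulon` objects), `signature` (named numeric,
#'   sorted descending), and ground truth `active_tf`, `true_score`.
#' @export
gen_survival_and_regulons <- function(config, model = risk_model(),
                                      effect_scale = 2,
                                      n_regulons = 50L, regulon_size = 20L,
                                      tf_shift = 3, tf_noise = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (length(model$coefficients) != 5) {
    stop("risk model must have 5 coefficients")
  }
  if (config$censoring_rate >= 1) stop("censoring_rate must be < 1")
  .with_seed(derive_seed(config$seed, 5L), {
    n <- config$n_samples
    samples <- sprintf("s%03d", seq_len(n))
    covs <- matrix(stats::rnorm(n * 5), nrow = n,
                   dimnames = list(samples, model$covariates))
    score <- drop(covs %*% model$coefficients)
    time <- stats::rexp(n, rate = exp(effect_scale * score))
    event <- rep(1L, n)
    cens <- stats::runif(n) < config$censoring_rate
    time[cens] <- time[cens] * stats::runif(sum(cens))
    event[cens] <- 0L
    surv <- data.frame(sample = samples, time = time, event = event,
                       covs, stringsAsFactors = FALSE, check.names = FALSE)

    sig_genes <- sprintf("r%04d", seq_len(config$n_genes))
    regulons <- lapply(seq_len(n_regulons), function(i) {
      targets <- sample(sig_genes, regulon_size)
      modes <- sample(c(-1, 1), regulon_size, replace = TRUE)
      regulon(sprintf("TF%02d", i), targets, modes)
    })
    names(regulons) <- vapply(regulons, function(r) r$tf, "")
    active_tf <- sample(names(regulons), 1L)
    sig <- stats::rnorm(length(sig_genes), sd = tf_noise)
    names(sig) <- sig_genes
    act <- regulons[[active_tf]]
    sig[act$targets] <- sig[act$targets] + tf_shift * act$modes
    sig <- sort(sig, decreasing = TRUE)
    list(survival = surv, regulons = regulons, signature = sig,
         active_tf = active_tf, true_score = score)
  })
}
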