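#' Pipeline configuration
#'
#' Parameters for \code{\link{run_all}}. The default pipeline simulates its
#' inputs (the synthetic world with planted structure), then runs
#' enrichment, module clustering, plasticity scoring, CNV/SNV analysis, the
#' risk model, and TF activity.
#'
#' @param seed root integer seed for every stage.
#' @param k_modules number of function modules cut from the NJ tree.
#' @param alpha_p,alpha_q enrichment retention thresholds.
#' @param n_perm permutation count for GSEA and TF activity.
#' @param sim a \code{\link{sim_config}}; its seed is overridden by `seed`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 7L, k_modules = 6L, alpha_p = 0.05,
                            alpha_q = 0.05, n_perm = 200L,
                            sim = sim_config()) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), k_modules = as.integer(k_modules),
                 alpha_p = alpha_p, alpha_q = alpha_q,
                 n_perm = as.integer(n_perm), sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with any subset of the \code{\link{pipeline_config}}
#'   and \code{\link{sim_config}} fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- raw$sim %||% list()
  sim <- do.call(sim_config, sim_args)
  top <- raw[setdiff(names(raw), "sim")]
  do.call(pipeline_config, c(top, list(sim = sim)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes simulate -> enrich (per source) -> cluster -> plasticity scoring
#' -> CNV/SNV -> risk -> TF activity, writing every stage's outputs under
#' `outdir` and a JSON manifest listing stage parameters, output files and
#' their md5 checksums. The manifest carries no timestamps, so two runs
#' with an identical config are byte-identical.
#'
#' @param config a \code{\link{pipeline_config}} or path to a JSON config.
#' @param outdir output directory (created if absent).
#' @return the manifest, invisibly (also written to manifest.json).
#' @export
run_all <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(outdir, ...)
  manifest <- list(seed = config$seed, k_modules = config$k_modules,
                   stages = list())
  note <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      stage = stage, parameters = params,
      outputs = lapply(files, function(f) {
        list(file = basename(f), md5 = unname(tools::md5sum(f)))
      }))
  }
  scfg <- scoring_config(n_perm = config$n_perm,
                         seed = derive_seed(config$seed, 10L))

  ## stage 1: simulate
  sim <- config$sim
  world <- gen_universe_and_terms(sim)
  sources <- gen_omics_gene_sets(world$universe, world$terms, world$blocks,
                                 sim)
  module_genes <- sort(unique(unlist(
    world$terms[names(world$blocks)[world$blocks == sim$n_blocks]])))
  exprsim <- gen_expression_with_phenotype(world$universe, module_genes, sim)
  cnvsim <- gen_cnv_and_mutations(world$universe, sim)
  survsim <- gen_survival_and_regulons(sim)
  write_universe(world$universe, path("universe.txt"))
  write_gmt(world$terms, path("terms.gmt"))
  write_gmt(stats::setNames(lapply(sources, `[[`, "genes"),
                            vapply(sources, `[[`, "", "source")),
            path("sources.gmt"))
  write_matrix_tsv(exprsim$expr, path("expression.tsv"))
  write_matrix_tsv(cnvsim$segments, path("segments.tsv"))
  write_matrix_tsv(cnvsim$mutations, path("mutations.tsv"))
  utils::write.table(survsim$survival, path("survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(stats::setNames(
    lapply(survsim$regulons, function(r) list(targets = r$targets,
                                              modes = r$modes)),
    names(survsim$regulons)), path("regulons.gmt"))
  truth <- list(blocks = as.list(world$blocks),
                shifted = names(exprsim$labels)[exprsim$labels == "shifted"],
                amp_genes = cnvsim$amp_genes, del_genes = cnvsim$del_genes,
                mut_gene = cnvsim$mut_gene, active_tf = survsim$active_tf)
  jsonlite::write_json(truth, path("ground_truth.json"), auto_unbox = TRUE)
  note("simulate", unclass(sim),
       path(c("universe.txt", "terms.gmt", "sources.gmt", "expression.tsv",
              "segments.tsv", "mutations.tsv", "survival.tsv",
              "regulons.gmt", "ground_truth.json")))

  ## stage 2: enrichment per source
  tables <- lapply(sources, enrich_terms, terms = world$terms,
                   universe = world$universe, alpha_p = config$alpha_p,
                   alpha_q = config$alpha_q)
  enr_files <- vapply(seq_along(tables), function(i) {
    f <- path(sprintf("enrichment_%s.tsv", sources[[i]]$source))
    utils::write.table(tables[[i]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }, "")
  note("enrich", list(alpha_p = config$alpha_p, alpha_q = config$alpha_q),
       enr_files)

  ## stage 3: kappa + NJ clustering into modules
  dm <- build_kappa_distance_matrix(tables, world$terms, world$universe)
  tree <- nj_tree(dm)
  partition <- cut_tree(tree, config$k_modules)
  summaries <- summarize_modules(partition, sources, world$terms,
                                 dm$term_sources)
  ape::write.tree(tree, path("tree.nwk"))
  utils::write.table(
    data.frame(term = names(partition), module = partition),
    path("partition.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(dm$distance, path("distance.tsv"))
  write_gmt(stats::setNames(lapply(summaries, `[[`, "union_genes"),
                            sprintf("module%d", vapply(summaries, `[[`, 0,
                                                       "module"))),
            path("modules.gmt"))
  ari <- adjusted_rand_index(partition[names(world$blocks)[
    names(world$blocks) %in% names(partition)]],
    world$blocks[names(world$blocks) %in% names(partition)])
  jsonlite::write_json(
    list(n_modules = length(summaries), ari_vs_truth = ari,
         source_counts = lapply(summaries, `[[`, "source_counts")),
    path("cluster_summary.json"), auto_unbox = TRUE, digits = NA)
  note("cluster", list(k = config$k_modules),
       path(c("tree.nwk", "partition.tsv", "distance.tsv", "modules.gmt",
              "cluster_summary.json")))

  ## stage 4: plasticity scoring
  pathway_sets <- list(planted = module_genes,
                       background = utils::head(
                         setdiff(world$universe, module_genes), 50))
  plast <- plasticity_pipeline(exprsim$expr, list(module_genes),
                               module_genes, pathway_sets, scfg)
  utils::write.table(
    data.frame(sample = names(plast$scores), score = plast$scores),
    path("plasticity_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    lapply(plast$gsea, function(g) list(es = g$es, nes = g$nes, p = g$p,
                                        leading_edge = g$leading_edge)),
    path("plasticity_gsea.json"), auto_unbox = TRUE, digits = NA)
  note("plasticity", list(n_perm = scfg$n_perm, alpha = scfg$alpha),
       path(c("plasticity_scores.tsv", "plasticity_gsea.json")))

  ## stage 5: CNV / SNV
  categories <- segment_to_category(cnvsim$segments)
  cnv_genes <- c(cnvsim$amp_genes, cnvsim$del_genes)
  assoc <- cnv_association_tests(categories[cnv_genes, , drop = FALSE],
                                 cnvsim$sample_groups, exprsim$expr,
                                 mc_seed = derive_seed(config$seed, 11L))
  prev <- cnv_prevalence(categories, cnv_genes, cnvsim$sample_groups)
  mut <- mutation_strata_enrichment(cnvsim$mutations, cnvsim$strata,
                                    cnvsim$mut_gene, "A")
  write_matrix_tsv(categories, path("cnv_categories.tsv"))
  utils::write.table(assoc, path("cnv_association.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(prev, path("cnv_prevalence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(gene = cnvsim$mut_gene, stratum = "A",
                            N = mut$counts$N, M = mut$counts$M,
                            n = mut$counts$n, k = mut$counts$k, p = mut$p),
                       path("mutation_enrichment.json"), auto_unbox = TRUE,
                       digits = NA)
  note("cnv_snv", list(),
       path(c("cnv_categories.tsv", "cnv_association.tsv",
              "cnv_prevalence.tsv", "mutation_enrichment.json")))

  ## stage 6: risk model
  model <- risk_model()
  rs <- risk_score(survsim$survival[, model$covariates], model)
  rs$sample <- survsim$survival$sample
  cidx <- concordance_index(rs$score, survsim$survival$time,
                            survsim$survival$event)
  utils::write.table(rs, path("risk_scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(c_index = cidx, n = nrow(rs),
                            events = sum(survsim$survival$event)),
                       path("risk_cindex.json"), auto_unbox = TRUE,
                       digits = NA)
  note("risk", list(threshold = model$threshold),
       path(c("risk_scores.tsv", "risk_cindex.json")))

  ## stage 7: TF activity
  act <- regulon_activity(survsim$signature, survsim$regulons,
                          n_perm = config$n_perm,
                          seed = derive_seed(config$seed, 12L))
  utils::write.table(act, path("tf_activity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("tf", list(n_perm = config$n_perm), path("tf_activity.tsv"))

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
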