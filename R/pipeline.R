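#' Run the full pipeline on a synthetic cohort
#'
#' End-to-end driver used by the analysis scripts and the reproducibility
#' checks: simulate a paired two-group study, run the moderated paired
#' t-test per group, classify cross-group directions, test gene-set
#' over-representation, build the four per-condition co-expression networks
#' on the combined DE gene set (merging the responder group's six samples
#' to three), and compute DiffK with permutation p-values, sectors and hub
#' calls. Every random stream is derived from `seed`, so the outputs are
#' byte-identical across runs with the same seed.
#'
#' @param seed Integer seed driving the simulation, the gene-set draw and
#'   the permutation streams.
#' @param outdir If non-`NULL`, results are written there as TSVs with
#'   parameter headers.
#' @param spec Optional `SimulationSpec`; the default plants one stable
#'   correlation module (anchor) and one rewired module inside the DE
#'   fraction at the study-shaped cohort (6 + 3 patients).
#' @param config Threshold list from [pipeline_config()].
#' @return List with elements `truth`, `de` (per group), `selected` (per
#'   group), `classes`, `enrichment`, `gene_set`, `diffk` (per group,
#'   sector-classified), `networks` (the four `NetworkState`s), `exports`.
#' @export
run_synthetic_pipeline <- function(seed = 1L, outdir = NULL, spec = NULL,
                                   config = pipeline_config()) {
  if (is.null(spec))
    spec <- simulation_spec(
      n_genes = 500L, n_patients = c(IF = 6L, ID = 3L),
      de_fraction = 0.1, delta = 1.5,
      modules = list(list(size = 15L, r_pre = 0.9, r_post = 0.9),
                     list(size = 15L, r_pre = 0.9, r_post = 0)),
      seed = seed)
  sim <- simulate_expression(spec)
  study <- sim$study
  groups <- names(spec$n_patients)

  de <- list(); selected <- list()
  for (grp in groups) {
    diffs <- paired_differences(study, grp)
    de[[grp]] <- rvm_paired_test(diffs)
    selected[[grp]] <- suppressMessages(
      select_de_genes(de[[grp]], config$p_thr, config$fdr_thr))
  }
  classes <- classify_cross_group(selected[[1L]], selected[[2L]])

  collection <- simulate_gene_sets(rownames(study$matrix),
                                   enriched_in = sim$truth$de$gene,
                                   seed = seed + 1L)
  enrichment <- suppressWarnings(
    enrich(classes$gene, collection, universe = rownames(study$matrix)))

  gene_set <- combine_gene_set(selected[[1L]], selected[[2L]])
  # center within condition so the display networks use the same merge
  # pairing as the permutation machinery (correlations are unaffected)
  merged <- suppressMessages(
    merge_similar_samples(center_within_condition(study), "IF", 3L))

  networks <- list()
  for (grp in groups) for (tp in c("pre", "post"))
    networks[[paste0(grp, "-", tp)]] <-
      suppressWarnings(build_network(merged, grp, tp, gene_set))

  dk <- list(
    IF = diffk_pvalues(study, "IF", gene_set, n_perm = config$n_perm,
                       seed = seed + 2L, merge_to = 3L),
    ID = diffk_pvalues(study, "ID", gene_set, n_perm = config$n_perm,
                       seed = seed + 3L))
  dk <- lapply(dk, classify_sectors,
               diffk_thr = config$diffk_thr, p_thr = config$p_thr)

  exports <- lapply(names(networks), function(cond) {
    grp <- sub("-.*$", "", cond)
    export_network(networks[[cond]], records = dk[[grp]],
                   directions = classes[, c("gene", "class")] |>
                     stats::setNames(c("gene", "direction")),
                   edge_threshold = config$edge_thr)
  })
  names(exports) <- names(networks)

  out <- list(spec = spec, truth = sim$truth, de = de, selected = selected,
              classes = classes, enrichment = enrichment,
              gene_set = gene_set, diffk = dk, networks = networks,
              exports = exports)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    hdr <- c(config, list(seed = seed))
    for (grp in groups)
      write_results_tsv(de[[grp]], file.path(outdir,
                        paste0("de_", grp, ".tsv")), hdr)
    write_results_tsv(classes, file.path(outdir, "direction_classes.tsv"), hdr)
    write_results_tsv(enrichment, file.path(outdir, "enrichment.tsv"), hdr)
    for (grp in groups)
      write_results_tsv(dk[[grp]], file.path(outdir,
                        paste0("diffk_", grp, ".tsv")), hdr)
    for (cond in names(exports)) {
      write_results_tsv(exports[[cond]]$nodes, file.path(outdir,
                        paste0("nodes_", cond, ".tsv")), hdr)
      write_results_tsv(exports[[cond]]$edges, file.path(outdir,
                        paste0("edges_", cond, ".tsv")), hdr)
    }
  }
  out
}
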