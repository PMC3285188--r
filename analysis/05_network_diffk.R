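#!/usr/bin/env Rscript

# Differential co-expression networks on the combined DE gene set: merge
# the six responder samples to three by expression similarity, build the
# four per-condition networks, and compute DiffK with label-flip
# permutation p-values, sectors and hub calls.
#
# At this cohort's size (3 profiles per condition) normalized connectivity
# is extremely noisy and few or no hubs are expected to pass both gates;
# the permutation p-values are what guards against over-reading the n = 3
# correlations (the recovery tests at adequate power live in the test
# suite and acceptance script).

suppressMessages(library(ahstnet))
SEED <- 1L
indir <- "results/synthetic"
outdir <- "results/network"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

study <- read_expression(file.path(indir, "expression.tsv"),
                         file.path(indir, "design.tsv"))
de_if <- read_results_tsv("results/diffexpr/de_IF.tsv")
de_id <- read_results_tsv("results/diffexpr/de_ID.tsv")
classes <- read_results_tsv("results/diffexpr/direction_classes.tsv")
cfg <- pipeline_config()

sel <- function(res) res$gene[res$p < cfg$p_thr & res$q < cfg$fdr_thr]
genes <- combine_gene_set(sel(de_if), sel(de_id))
cat("Combined network gene set:", length(genes), "genes\n")

merged <- merge_similar_samples(center_within_condition(study), "IF", 3L)
write_results_tsv(attr(merged, "merge_map"),
                  file.path(outdir, "merge_map.tsv"), list(seed = SEED))

for (grp in c("IF", "ID")) {
  dk <- diffk_pvalues(study, grp, genes, n_perm = cfg$n_perm,
                      seed = SEED + match(grp, c("IF", "ID")),
                      merge_to = if (grp == "IF") 3L else NULL)
  dk <- classify_sectors(dk, cfg$diffk_thr, cfg$p_thr)
  write_results_tsv(dk, file.path(outdir, paste0("diffk_", grp, ".tsv")),
                    c(cfg, list(seed = SEED)))
  cat(sprintf("%s: mean k pre = %.3f, post = %.3f; %d hub(s); min p = %.3f\n",
              grp, mean(dk$k_pre), mean(dk$k_post), sum(dk$hub), min(dk$p)))

  for (tp in c("pre", "post")) {
    net <- suppressWarnings(build_network(merged, grp, tp, genes))
    ex <- export_network(net, records = dk,
                         directions = setNames(
                           classes[, c("gene", "class")],
                           c("gene", "direction")),
                         edge_threshold = cfg$edge_thr)
    write_results_tsv(ex$nodes,
                      file.path(outdir, sprintf("nodes_%s_%s.tsv", grp, tp)),
                      c(cfg, list(seed = SEED)))
    write_results_tsv(ex$edges,
                      file.path(outdir, sprintf("edges_%s_%s.tsv", grp, tp)),
                      c(cfg, list(seed = SEED)))
  }
}
cat("Network tables written under", outdir, "\n")
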