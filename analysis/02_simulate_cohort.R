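#!/usr/bin/env Rscript

# Generate the synthetic study-shaped cohort (6 + 3 patients, pre/post)
# with known ground truth: planted expression shifts, one stable and one
# rewired co-expression module, random gene sets with one planted
# enrichment, and a simulated clinical table with planted group separation
# in insulin dose.

suppressMessages(library(ahstnet))
SEED <- 1L
outdir <- "results/synthetic"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

spec <- simulation_spec(
  n_genes = 500L, n_patients = c(IF = 6L, ID = 3L),
  de_fraction = 0.1, delta = 1.5,
  modules = list(list(size = 15L, r_pre = 0.9, r_post = 0.9),
                 list(size = 15L, r_pre = 0.9, r_post = 0)),
  seed = SEED)
sim <- simulate_expression(spec)
cat("Simulated", nrow(sim$study$matrix), "genes x",
    ncol(sim$study$matrix), "samples;",
    nrow(sim$truth$de), "planted DE genes,",
    length(sim$truth$modules), "modules\n")

write_expression(sim$study,
                 file.path(outdir, "expression.tsv"),
                 file.path(outdir, "design.tsv"))
write_expression(sim$study,
                 file.path(outdir, "expression.gct"),
                 file.path(outdir, "design.tsv"), format = "gct")

gs <- simulate_gene_sets(rownames(sim$study$matrix),
                         enriched_in = sim$truth$de$gene, seed = SEED + 1L)
write_gmt(gs, file.path(outdir, "gene_sets.gmt"))

clin <- simulate_clinical(seed = SEED, effects = list(insulin_12mo = 0.4))
write_clinical(clin, file.path(outdir, "clinical.tsv"))

write_results_tsv(sim$truth$de, file.path(outdir, "truth_de.tsv"),
                  list(seed = SEED))
write_results_tsv(sim$truth$expected_hubs,
                  file.path(outdir, "truth_hubs.tsv"), list(seed = SEED))
cat("Fixtures written under", outdir, "\n")
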