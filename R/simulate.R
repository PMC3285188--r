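#' Specify a synthetic paired expression study
#'
#' The generator emulates the study design this pipeline targets: two patient
#' groups profiled pre- and post-treatment (defaults: 6 responders, 3
#' non-responders), gene-wise true variances drawn from the inverse-gamma
#' prior of the random variance model (precision `~ Gamma(a, scale b)`),
#' a planted fraction of genes whose post-treatment mean shifts by
#' `+/- delta` log2 units, and planted correlation modules built by
#' latent-factor mixing `x = sqrt(r) f + sqrt(1 - r) eps`, which gives an
#' analytically known pairwise correlation `r` within the module (set
#' per timepoint, so `r_pre != r_post` plants a connectivity rewiring of
#' known sign).
#'
#' Gene layout is deterministic: module genes occupy the leading indices
#' (in list order), and the planted differentially expressed genes are the
#' first `round(de_fraction * n_genes)` genes with alternating +/- effect
#' signs, so modules overlap the DE set whenever the DE fraction covers
#' them (as treatment-responsive co-expression modules should).
#'
#' @param n_genes Number of genes.
#' @param n_patients Named vector of patients per group,
#'   default `c(IF = 6, ID = 3)`.
#' @param prior_a,prior_b Shape and scale of the gamma prior on precisions.
#' @param de_fraction Fraction of genes with a planted pre-to-post shift.
#' @param delta Effect size of the shift in log2 units.
#' @param modules List of `list(size, r_pre, r_post)` correlation blocks
#'   (sizes >= 3, correlations in `[0, 1)`).
#' @param seed RNG seed; the whole study is reproducible from it.
#' @return Object of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_genes = 500L,
                            n_patients = c(IF = 6L, ID = 3L),
                            prior_a = 2, prior_b = 1,
                            de_fraction = 0.1, delta = 1.5,
                            modules = list(), seed = 1L) {
  stopifnot(n_genes >= 1L, all(n_patients >= 2L),
            prior_a > 0, prior_b > 0,
            de_fraction >= 0, de_fraction <= 1, length(seed) == 1L)
  if (is.null(names(n_patients)) || any(names(n_patients) == ""))
    stop("n_patients must be a named vector of group sizes")
  for (mod in modules) {
    stopifnot(is.list(mod), all(c("size", "r_pre", "r_post") %in% names(mod)))
    if (mod$size < 3L) stop("module sizes must be >= 3")
    if (mod$size > n_genes) stop("module larger than n_genes")
    if (mod$r_pre < 0 || mod$r_pre >= 1 || mod$r_post < 0 || mod$r_post >= 1)
      stop("module correlations must lie in [0, 1)")
  }
  if (sum(vapply(modules, `[[`, numeric(1L), "size")) > n_genes)
    stop("modules exceed n_genes in total")
  structure(list(n_genes = as.integer(n_genes), n_patients = n_patients,
                 prior_a = prior_a, prior_b = prior_b,
                 de_fraction = de_fraction, delta = delta,
                 modules = modules, seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Simulate a paired expression study with known ground truth
#'
#' Per gene g a true variance `sigma^2_g` is drawn from the inverse-gamma
#' prior; per-sample noise has SD `sigma_g / sqrt(2)` so the paired
#' difference (post - pre) of a null gene has variance exactly `sigma^2_g`
#' and [rvm_fit()] on the observed difference variances recovers
#' `(prior_a, prior_b)`. Null genes share their mean across timepoints; DE
#' genes have the post mean shifted by the signed effect. Module genes mix
#' in a per-sample latent factor at the timepoint's correlation level
#' before scaling, so their marginal variances still follow the prior.
#'
#' @param spec A `SimulationSpec`.
#' @return List with `study` (an `ExpressionStudy`) and `truth`, a list with
#'   `de` (data frame `gene`, `effect`), `modules` (list of
#'   `list(genes, r_pre, r_post)`), and `expected_hubs` (genes of modules
#'   with `|r_pre - r_post| >= 0.6`, the planted rewired hubs, with the
#'   expected DiffK sign).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  G <- spec$n_genes
  gene_ids <- sprintf("g%04d", seq_len(G))

  design <- do.call(rbind, lapply(names(spec$n_patients), function(grp) {
    pats <- paste0(grp, seq_len(spec$n_patients[[grp]]))
    data.frame(sample_id = c(paste0(pats, "_pre"), paste0(pats, "_post")),
               patient_id = rep(pats, 2L),
               group = grp,
               timepoint = rep(c("pre", "post"), each = length(pats)),
               stringsAsFactors = FALSE)
  }))
  S <- nrow(design)

  lambda <- stats::rgamma(G, shape = spec$prior_a, scale = spec$prior_b)
  sigma <- sqrt(1 / lambda)
  mu <- stats::rnorm(G, mean = 8, sd = 1)

  n_de <- round(spec$de_fraction * G)
  de_idx <- seq_len(n_de)
  effect <- rep(c(spec$delta, -spec$delta), length.out = n_de)

  # module gene indices: leading block, in list order
  mod_info <- list()
  nxt <- 1L
  for (mod in spec$modules) {
    idx <- seq.int(nxt, nxt + mod$size - 1L)
    mod_info[[length(mod_info) + 1L]] <-
      list(idx = idx, r_pre = mod$r_pre, r_post = mod$r_post)
    nxt <- nxt + mod$size
  }

  X <- matrix(stats::rnorm(G * S), G, S)
  for (mod in mod_info) {
    f <- stats::rnorm(S)
    for (s in seq_len(S)) {
      r <- if (design$timepoint[s] == "pre") mod$r_pre else mod$r_post
      X[mod$idx, s] <- sqrt(r) * f[s] + sqrt(1 - r) * X[mod$idx, s]
    }
  }
  X <- X * (sigma / sqrt(2))
  X <- X + mu
  post <- design$timepoint == "post"
  if (n_de > 0L)
    X[de_idx, post] <- X[de_idx, post] + effect

  dimnames(X) <- list(gene_ids, design$sample_id)
  study <- expression_study(X, design)

  truth <- list(
    de = data.frame(gene = gene_ids[de_idx], effect = effect,
                    stringsAsFactors = FALSE),
    modules = lapply(mod_info, function(m)
      list(genes = gene_ids[m$idx], r_pre = m$r_pre, r_post = m$r_post)),
    expected_hubs = do.call(rbind, c(list(
      data.frame(gene = character(), diffk_sign = numeric(),
                 stringsAsFactors = FALSE)),
      lapply(mod_info, function(m) {
        if (abs(m$r_pre - m$r_post) < 0.6) return(NULL)
        data.frame(gene = gene_ids[m$idx],
                   diffk_sign = sign(m$r_post - m$r_pre),
                   stringsAsFactors = FALSE)
      }))))
  list(study = study, truth = truth)
}

#' Simulate random gene sets over a gene list
#'
#' Plain random membership draws, plus (optionally) one set concentrated in
#' a designated gene list so over-representation is planted.
#'
#' @param gene_ids Universe of gene ids.
#' @param n_sets Number of random sets.
#' @param size_range Min/max set size.
#' @param enriched_in Optional gene ids; adds a set `"planted_set"` drawing
#'   80% of its members from this list.
#' @param seed RNG seed.
#' @return A `GeneSetCollection` with `gene_ids` as universe.
#' @export
simulate_gene_sets <- function(gene_ids, n_sets = 50L,
                               size_range = c(5L, 30L),
                               enriched_in = NULL, seed = 1L) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    sz <- sample(seq(size_range[1L], size_range[2L]), 1L)
    sample(gene_ids, sz)
  })
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  if (!is.null(enriched_in)) {
    sz <- min(length(enriched_in), size_range[2L])
    n_in <- ceiling(0.8 * sz)
    sets$planted_set <- unique(c(sample(enriched_in, n_in),
                                 sample(setdiff(gene_ids, enriched_in),
                                        sz - n_in)))
  }
  gene_set_collection(sets, universe = gene_ids)
}

#' Simulate a nine-patient clinical table
#'
#' Draws a cohort with the schema of the packaged clinical table (six
#' responders, three non-responders) from plausible baseline distributions,
#' then applies the requested additive shifts to the non-responder (ID)
#' group so that group separation of designated variables is planted. With
#' all effects zero the two groups are exchangeable and group-comparison
#' p-values are calibrated.
#'
#' @param seed RNG seed.
#' @param effects Named list of additive shifts applied to the ID group,
#'   e.g. `list(insulin_12mo = 0.4)`. Values must be finite.
#' @return A `ClinicalTable` with 9 rows (6 IF / 3 ID).
#' @export
simulate_clinical <- function(seed = 1L, effects = list()) {
  if (length(effects) && any(!is.finite(unlist(effects))))
    stop("effects must be finite")
  bad <- setdiff(names(effects), clinical_variables())
  if (length(bad)) stop("unknown effect variable(s): ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  n <- 9L
  df <- data.frame(
    case = seq_len(n),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = round(stats::runif(n, 14, 25)),
    bmi = round(stats::rnorm(n, 18.5, 1.4), 1),
    cd34_dose = round(stats::rlnorm(n, log(11), 0.4), 2),
    duration = round(stats::runif(n, 1, 4) * 2) / 2,
    fbg = round(stats::rnorm(n, 6, 1.5), 1),
    pbg = round(stats::rnorm(n, 10.5, 2), 1),
    hba1c = round(stats::rnorm(n, 10, 2.2), 1),
    gada = round(stats::rlnorm(n, log(150), 1.3), 1),
    insulin_pre = round(stats::runif(n, 0.4, 0.95), 2),
    insulin_6mo = round(pmax(stats::rnorm(n, 0.05, 0.05), 0), 2),
    insulin_12mo = round(pmax(stats::rnorm(n, 0.02, 0.03), 0), 2),
    cpeptide_pre = round(stats::runif(n, 0.1, 0.8), 2),
    cpeptide_6mo = round(stats::runif(n, 0.2, 1.5), 2),
    cpeptide_12mo = round(stats::runif(n, 0.3, 1.6), 2),
    group = rep(c("IF", "ID"), c(6L, 3L)),
    stringsAsFactors = FALSE)
  id <- df$group == "ID"
  for (v in names(effects))
    df[[v]][id] <- df[[v]][id] + effects[[v]]
  df$gada <- pmax(df$gada, 0.1)  # keep the log transform defined
  class(df) <- c("ClinicalTable", "data.frame")
  df
}
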