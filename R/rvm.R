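#' Per-gene paired differences
#'
#' For every patient of a group, computes `post - pre` per gene, so positive
#' values mean higher expression after treatment.
#'
#' @param study An `ExpressionStudy`.
#' @param group Patient group label.
#' @return Numeric matrix, genes x patients (columns named by patient id).
#' @export
paired_differences <- function(study, group) {
  pre <- condition_slice(study, group, "pre")
  post <- condition_slice(study, group, "post")
  d <- study$design
  pat_pre <- sort(d$patient_id[d$group == group & d$timepoint == "pre"])
  pat_post <- sort(d$patient_id[d$group == group & d$timepoint == "post"])
  if (!identical(pat_pre, pat_post))
    stop("unpaired patient(s) in group ", group)
  if (length(pat_pre) < 2L)
    stop("group ", group, " has fewer than 2 complete patient pairs")
  diffs <- post - pre  # columns of both slices are ordered by patient id
  colnames(diffs) <- pat_pre
  diffs
}

#' Fit the random variance model prior
#'
#' Under the random variance model each gene's true variance is
#' inverse-gamma: the precision `1/sigma^2_g` is Gamma with shape `a` and
#' scale `b`, shared across genes. Marginally the observed sample variances
#' then satisfy `s^2 * a * b ~ F(m, 2a)` where `m` is the per-gene degrees
#' of freedom. `(a, b)` are fitted by maximizing this marginal likelihood
#' (quasi-Newton on the log scale, several starting points).
#'
#' Near-constant variance across genes pushes `a` towards infinity (the
#' prior degenerates to a point mass); the fit is then flagged as
#' non-converged or returns a very large `a` — either way the moderated test
#' approaches the pooled-variance limit.
#'
#' @param variances Per-gene sample variances of the paired differences
#'   (at least 50 finite positive values).
#' @param m Degrees of freedom of each variance (pairs minus one).
#' @return Object of class `RVMPrior`: list with `a`, `b`, `m`,
#'   `converged`, `loglik`.
#' @export
rvm_fit <- function(variances, m) {
  x <- variances[is.finite(variances) & variances > 0]
  if (length(x) < 50L)
    stop("need >= 50 genes with finite positive variances to fit the ",
         "variance prior; use the ordinary paired t test instead")
  if (m < 1L) stop("m must be >= 1")

  nll <- function(par) {
    a <- exp(par[1L]); b <- exp(par[2L])
    val <- -sum(stats::df(a * b * x, df1 = m, df2 = 2 * a, log = TRUE) +
                  log(a) + log(b))
    if (!is.finite(val)) 1e10 else val
  }
  starts <- expand.grid(a = c(0.5, 1, 2, 4, 8),
                        b = c(0.25, 1, 4) / stats::median(x))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(
        stats::optim(log(as.numeric(starts[i, ])), nll, method = "BFGS",
                     control = list(maxit = 500L))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("variance-prior fit failed to evaluate at any starting point")
  a <- exp(best$par[1L])
  b <- exp(best$par[2L])
  converged <- best$convergence == 0L
  if (!converged)
    warning(sprintf(paste0("variance-prior optimizer did not converge ",
                           "(last iterate a = %.3g, b = %.3g)"), a, b))
  structure(list(a = a, b = b, m = m, converged = converged,
                 loglik = -best$value),
            class = "RVMPrior")
}

#' @export
print.RVMPrior <- function(x, ...) {
  cat(sprintf("RVM variance prior: a = %.4g, b = %.4g (m = %d, %s)\n",
              x$a, x$b, x$m,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Moderated paired t test under the random variance model
#'
#' Shrinks each gene's variance towards the inverse-gamma prior:
#' `s2_mod = (m * s^2 + 2/b) / (m + 2a)` with `m + 2a` degrees of freedom
#' (the posterior-mean precision under the fitted prior), then tests
#' `t = dbar / sqrt(s2_mod / n)` two-sided against the t distribution.
#' With `plain = TRUE` (or a `NULL` prior) the ordinary paired t test is
#' run instead. FDR q-values are Benjamini-Hochberg over all genes; by
#' construction `q >= p` genewise.
#'
#' @param differences Genes x patients matrix from [paired_differences()].
#' @param prior An `RVMPrior` from [rvm_fit()], or `NULL` to fit it here.
#' @param plain If `TRUE`, skip moderation (ordinary paired t).
#' @return Data frame of class `DEResult`: `gene`, `mean_diff`, `s2`,
#'   `s2_mod`, `t`, `df`, `p`, `q`, `direction` (`Up` iff `mean_diff > 0`).
#' @export
rvm_paired_test <- function(differences, prior = NULL, plain = FALSE) {
  n <- ncol(differences)
  if (n < 2L) stop("need >= 2 pairs")
  m <- n - 1L
  dbar <- rowMeans(differences)
  s2 <- apply(differences, 1L, stats::var)
  if (plain) {
    s2_mod <- s2
    dfree <- m
  } else {
    if (is.null(prior)) prior <- rvm_fit(s2, m)
    stopifnot(inherits(prior, "RVMPrior"))
    s2_mod <- (m * s2 + 2 / prior$b) / (m + 2 * prior$a)
    dfree <- m + 2 * prior$a
  }
  t_stat <- dbar / sqrt(s2_mod / n)
  p <- 2 * stats::pt(-abs(t_stat), df = dfree)
  res <- data.frame(
    gene = rownames(differences),
    mean_diff = dbar,
    s2 = s2,
    s2_mod = s2_mod,
    t = t_stat,
    df = dfree,
    p = p,
    q = stats::p.adjust(p, method = "BH"),
    direction = ifelse(dbar > 0, "Up", "Down"),
    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Select differentially expressed genes
#'
#' Genes passing both the nominal p and the Benjamini-Hochberg q threshold.
#'
#' @param result A `DEResult`.
#' @param p_thr,q_thr Thresholds in (0, 1].
#' @return Data frame with `gene` and `direction` of the selected genes.
#' @export
select_de_genes <- function(result, p_thr = 0.05, q_thr = 0.05) {
  stopifnot(p_thr > 0, p_thr <= 1, q_thr > 0, q_thr <= 1)
  keep <- result$p < p_thr & result$q < q_thr
  sel <- result[keep, c("gene", "direction")]
  rownames(sel) <- NULL
  message(sum(keep), " gene(s) selected (",
          sum(sel$direction == "Up"), " Up, ",
          sum(sel$direction == "Down"), " Down)")
  sel
}

#' Cross-group direction classes
#'
#' Combines per-group selections into the three classes used for the
#' response workflow: genes moving the same way in both groups keep that
#' direction (`Up`/`Down`), genes moving in opposite directions are
#' `Other`, and group-unique genes keep their single-group direction.
#'
#' @param de_if,de_id Data frames with `gene` and `direction` (from
#'   [select_de_genes()]) for the insulin-free and insulin-dependent groups.
#' @return Data frame with `gene`, `class` (`Up`/`Down`/`Other`) and
#'   `found_in` (`both`/`IF`/`ID`).
#' @export
classify_cross_group <- function(de_if, de_id) {
  all_genes <- union(de_if$gene, de_id$gene)
  if (length(all_genes) == 0L)
    return(data.frame(gene = character(), class = character(),
                      found_in = character(), stringsAsFactors = FALSE))
  dir_if <- de_if$direction[match(all_genes, de_if$gene)]
  dir_id <- de_id$direction[match(all_genes, de_id$gene)]
  cls <- ifelse(is.na(dir_if), dir_id,
         ifelse(is.na(dir_id), dir_if,
         ifelse(dir_if == dir_id, dir_if, "Other")))
  found <- ifelse(is.na(dir_if), "ID", ifelse(is.na(dir_id), "IF", "both"))
  out <- data.frame(gene = all_genes, class = cls, found_in = found,
                    stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}
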