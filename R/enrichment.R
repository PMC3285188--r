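#' Gene-set over-representation analysis
#'
#' For each gene set, builds the 2x2 table of membership vs differential
#' expression over the universe and reports the one-sided Fisher exact
#' p-value (hypergeometric upper tail; `alternative = "two.sided"`
#' available), the chi-square p-value with continuity correction, the
#' Benjamini-Hochberg q over all tested sets (computed on the gating test,
#' Fisher by default), and the enrichment ratio `(k/n) / (K/N)`.
#'
#' The universe should be the genes actually measured (e.g. all genes in
#' the expression matrix), not all annotated genes. DE genes outside the
#' universe are dropped with a warning; sets with no DE overlap are
#' reported with p = 1.
#'
#' @param de_genes Character vector of differentially expressed gene ids.
#' @param collection A `GeneSetCollection`.
#' @param universe Background gene ids; defaults to the collection's
#'   universe.
#' @param alternative Fisher alternative: `"greater"` (over-representation,
#'   default) or `"two.sided"`.
#' @param gate Which p gates the q-value: `"fisher"` (default) or
#'   `"chisq"`.
#' @param top Optional: truncate the ranked table to the top `top` sets.
#' @return Data frame of class `EnrichmentResult`, ranked by the gating p:
#'   `set`, `k`, `K`, `n`, `N`, `fisher_p`, `chisq_p`, `q`, `ratio`.
#' @export
enrich <- function(de_genes, collection, universe = NULL,
                   alternative = c("greater", "two.sided"),
                   gate = c("fisher", "chisq"), top = NULL) {
  alternative <- match.arg(alternative)
  gate <- match.arg(gate)
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (is.null(universe)) universe <- collection$universe
  if (is.null(universe) || length(universe) == 0L)
    stop("an enrichment universe is required")
  universe <- unique(as.character(universe))
  de_genes <- unique(as.character(de_genes))
  outside <- setdiff(de_genes, universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " DE gene(s) outside the universe")
    de_genes <- intersect(de_genes, universe)
  }
  N <- length(universe)
  n <- length(de_genes)

  sets <- lapply(collection$sets, intersect, y = universe)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty),
            " set(s) with no members in the universe")
    sets <- sets[!empty]
  }
  if (length(sets) == 0L) stop("no testable gene sets")

  rows <- lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    K <- length(members)
    k <- length(intersect(members, de_genes))
    if (k == 0L) {
      fp <- 1
    } else {
      tab <- matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2L)
      fp <- stats::fisher.test(tab, alternative = alternative)$p.value
    }
    cp <- tryCatch(
      suppressWarnings(stats::chisq.test(
        matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2L),
        correct = TRUE)$p.value),
      error = function(e) NA_real_)
    ratio <- if (n > 0L) (k / n) / (K / N) else NA_real_
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               fisher_p = fp, chisq_p = cp, ratio = ratio,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  gate_p <- if (gate == "fisher") res$fisher_p else res$chisq_p
  res$q <- stats::p.adjust(gate_p, method = "BH")
  res <- res[order(gate_p, -res$ratio), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(top)) res <- utils::head(res, top)
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}
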