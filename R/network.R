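#' Combine per-group gene selections into one network gene set
#'
#' Union of the two differential-expression lists, sorted by gene id so the
#' result is stable regardless of argument order.
#'
#' @param de_if,de_id Character vectors of gene ids (or data frames with a
#'   `gene` column).
#' @return Sorted character vector.
#' @export
combine_gene_set <- function(de_if, de_id) {
  g1 <- if (is.data.frame(de_if)) de_if$gene else de_if
  g2 <- if (is.data.frame(de_id)) de_id$gene else de_id
  out <- sort(union(as.character(g1), as.character(g2)))
  if (length(out) == 0L)
    stop("empty combined gene set: no network can be built")
  out
}

#' Merge similar samples within a group
#'
#' Reduces a group's samples to `target` profiles per timepoint by greedily
#' merging the closest pair of samples under the 1 - Pearson correlation
#' distance (the leading agglomerations of average-linkage clustering),
#' averaging each pair. Pairing is computed independently per timepoint; the
#' merged study's pseudo-patient ids pair the i-th merged pre profile with
#' the i-th merged post profile (ordered by first original member) and are
#' bookkeeping only — downstream network code consumes condition slices.
#' The merge map is attached as attribute `merge_map` and reported.
#'
#' @param study An `ExpressionStudy`.
#' @param group Group whose samples are merged (the responder group has
#'   twice as many patients as profiles are wanted).
#' @param target Number of merged profiles per timepoint.
#' @return An `ExpressionStudy` in which the group's samples are replaced by
#'   merged profiles; other groups are untouched.
#' @export
merge_similar_samples <- function(study, group = "IF", target = 3L) {
  stopifnot(inherits(study, "ExpressionStudy"))
  d <- study$design
  maps <- list()
  merged_mats <- list()
  for (tp in c("pre", "post")) {
    ids <- d$sample_id[d$group == group & d$timepoint == tp]
    if (length(ids) != 2L * target)
      stop("group ", group, " has ", length(ids), " ", tp,
           " sample(s); cannot pair down to ", target)
    m <- study$matrix[, ids, drop = FALSE]
    pairs <- greedy_pairs(m)
    prof <- vapply(pairs, function(p) rowMeans(m[, p, drop = FALSE]),
                   numeric(nrow(m)))
    # order merged profiles by their first original member for determinism
    ord <- order(vapply(pairs, function(p) min(match(p, ids)), integer(1L)))
    pairs <- pairs[ord]
    prof <- prof[, ord, drop = FALSE]
    colnames(prof) <- paste0(group, "m", seq_len(target), "_", tp)
    merged_mats[[tp]] <- prof
    maps[[tp]] <- data.frame(
      timepoint = tp,
      merged_id = colnames(prof),
      member1 = vapply(pairs, `[[`, character(1L), 1L),
      member2 = vapply(pairs, `[[`, character(1L), 2L),
      stringsAsFactors = FALSE)
  }
  map <- rbind(maps$pre, maps$post)
  message("merged ", group, " samples: ",
          paste(sprintf("%s={%s,%s}", map$merged_id, map$member1,
                        map$member2), collapse = " "))

  keep <- d$sample_id[d$group != group]
  new_mat <- cbind(study$matrix[, keep, drop = FALSE],
                   merged_mats$pre, merged_mats$post)
  new_design <- rbind(
    d[d$group != group, , drop = FALSE],
    data.frame(sample_id = c(colnames(merged_mats$pre),
                             colnames(merged_mats$post)),
               patient_id = rep(paste0(group, "m", seq_len(target)), 2L),
               group = group,
               timepoint = rep(c("pre", "post"), each = target),
               stringsAsFactors = FALSE))
  out <- expression_study(new_mat, new_design)
  attr(out, "merge_map") <- map
  out
}

#' Center each gene within every group-by-timepoint condition
#'
#' Subtracts each gene's per-condition mean. Gene-gene correlations within
#' any condition slice are unchanged; mean structure (e.g. planted
#' pre-to-post shifts) is removed, which matters when conditions are mixed,
#' as in the label-flip permutations of [diffk_pvalues()].
#'
#' @param study An `ExpressionStudy`.
#' @return The centered `ExpressionStudy`.
#' @export
center_within_condition <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  d <- study$design
  for (grp in unique(d$group)) for (tp in c("pre", "post")) {
    ids <- d$sample_id[d$group == grp & d$timepoint == tp]
    study$matrix[, ids] <- study$matrix[, ids, drop = FALSE] -
      rowMeans(study$matrix[, ids, drop = FALSE])
  }
  study
}

# Greedy closest-pair matching of sample columns under 1 - Pearson distance.
greedy_pairs <- function(m) {
  dist <- 1 - stats::cor(m)
  diag(dist) <- Inf
  ids <- colnames(m)
  pairs <- list()
  while (length(ids) > 0L) {
    sub <- dist[ids, ids, drop = FALSE]
    ix <- arrayInd(which.min(sub), dim(sub))
    pair <- sort(c(ids[ix[1L]], ids[ix[2L]]))
    pairs[[length(pairs) + 1L]] <- pair
    ids <- setdiff(ids, pair)
  }
  pairs
}

#' Build a per-condition co-expression network
#'
#' Pairwise Pearson correlation of the listed genes across one condition's
#' profiles. Connectivity is `K_i = sum_{j != i} |r_ij|` (unsigned, the
#' convention of connectivity-based co-expression analysis; set
#' `signed = TRUE` to sum raw correlations instead) and the normalized
#' connectivity is `k_i = K_i / max_j K_j`, so the most connected gene(s)
#' have k exactly 1. Genes with zero variance in the condition are dropped
#' with a warning before correlation.
#'
#' With only three profiles per condition (the design this pipeline is built
#' around) individual correlations are extremely noisy; normalized
#' connectivities are interpretable only jointly with the permutation
#' p-values of [diffk_pvalues()].
#'
#' @param study An `ExpressionStudy` (typically after
#'   [merge_similar_samples()] for the larger group).
#' @param group,timepoint Condition selector.
#' @param genes Gene ids to include (typically [combine_gene_set()] output).
#' @param signed Use signed connectivity (sum of raw r) instead of `|r|`.
#' @return Object of class `NetworkState`: list with `condition`, `genes`,
#'   `cor` (correlation matrix), `K`, `k`, `n_profiles`.
#' @export
build_network <- function(study, group, timepoint, genes, signed = FALSE) {
  m <- condition_slice(study, group, timepoint, genes)
  if (ncol(m) < 3L)
    stop("need >= 3 profiles to build a network (got ", ncol(m), ")")
  v <- apply(m, 1L, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0),
            " gene(s) with zero variance in ", group, "-", timepoint)
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("fewer than 2 variable genes in the condition")
  r <- stats::cor(t(m))
  K <- if (signed) colSums(r) - 1 else colSums(abs(r)) - 1
  k <- K / max(K)
  structure(list(condition = paste0(group, "-", timepoint),
                 genes = rownames(m), cor = r, K = K, k = k,
                 n_profiles = ncol(m)),
            class = "NetworkState")
}

#' @export
print.NetworkState <- function(x, ...) {
  cat("NetworkState", x$condition, ":", length(x$genes), "genes over",
      x$n_profiles, "profiles\n")
  invisible(x)
}

#' Differential connectivity between two network states
#'
#' `DiffK_i = k_i(post) - k_i(pre)`, bounded in `[-1, 1]`. Genes absent from
#' either state (e.g. dropped for zero variance) are excluded with a message.
#'
#' @param pre,post `NetworkState`s for the same group.
#' @return Data frame with `gene`, `k_pre`, `k_post`, `diffk`.
#' @export
diffk <- function(pre, post) {
  common <- intersect(pre$genes, post$genes)
  if (length(common) == 0L) stop("no genes shared between the two states")
  dropped <- length(union(pre$genes, post$genes)) - length(common)
  if (dropped > 0L)
    message("excluding ", dropped, " gene(s) present in only one state")
  data.frame(gene = common,
             k_pre = unname(pre$k[common]),
             k_post = unname(post$k[common]),
             diffk = unname(post$k[common] - pre$k[common]),
             stringsAsFactors = FALSE)
}

#' Permutation p-values for differential connectivity
#'
#' The null keeps each patient's pair of arrays together and swaps its
#' pre/post labels independently with probability 1/2, then recomputes both
#' networks (re-merging the responder group per permutation when
#' `merge_to` is set) and DiffK. The two-sided empirical p uses the add-one
#' estimator `p = (1 + #{|DiffK*| >= |DiffK_obs|}) / (n_perm + 1)`, so
#' p is always in (0, 1].
#'
#' With g patients the flip null has only `2^g` distinct label patterns, and
#' the identity and all-flip patterns reproduce `|DiffK|` exactly, so the
#' attainable p floor is about `2^(1-g)` — with three patients no gene can
#' reach p < 0.05 under this null. Flips are therefore applied to the
#' *unmerged* study (six responder patients give a floor of ~0.03).
#'
#' Every gene is centered within each timepoint before permuting (which
#' leaves the observed gene-gene correlations unchanged): without this,
#' genes with a real pre-to-post mean shift acquire an artificial shared
#' bimodal pattern in label-mixed slices, creating spurious co-expression
#' in the permuted networks and an anticonservative p.
#'
#' @param study The unmerged `ExpressionStudy`.
#' @param group Group to analyse.
#' @param genes Network gene set.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed for the flip stream.
#' @param merge_to If non-`NULL`, merge this group's samples down to
#'   `merge_to` profiles per timepoint (observed and permuted alike).
#' @param signed Passed to [build_network()].
#' @return Data frame with `gene`, `k_pre`, `k_post`, `diffk`, `p`.
#' @export
diffk_pvalues <- function(study, group, genes, n_perm = 499L, seed = 1L,
                          merge_to = NULL, signed = FALSE) {
  if (n_perm < 100L) stop("n_perm must be >= 100 for a stable p-value")
  netpair <- function(st) {
    pre <- build_network(st, group, "pre", genes, signed = signed)
    post <- build_network(st, group, "post", genes, signed = signed)
    diffk(pre, post)
  }
  prepare <- function(st) {
    if (is.null(merge_to)) st
    else suppressMessages(merge_similar_samples(st, group, merge_to))
  }
  study <- center_within_condition(study)
  obs <- suppressWarnings(netpair(prepare(study)))

  d <- study$design
  patients <- unique(d$patient_id[d$group == group])
  pre_ids <- vapply(patients, function(p)
    d$sample_id[d$patient_id == p & d$timepoint == "pre"], character(1L))
  post_ids <- vapply(patients, function(p)
    d$sample_id[d$patient_id == p & d$timepoint == "post"], character(1L))

  set.seed(seed)
  cnt <- rep(1L, nrow(obs))
  for (b in seq_len(n_perm)) {
    flip <- stats::runif(length(patients)) < 0.5
    st <- study
    if (any(flip)) {
      a <- pre_ids[flip]; z <- post_ids[flip]
      tmp <- st$matrix[, a, drop = FALSE]
      st$matrix[, a] <- st$matrix[, z, drop = FALSE]
      st$matrix[, z] <- tmp
    }
    perm <- suppressWarnings(suppressMessages(netpair(prepare(st))))
    dk <- perm$diffk[match(obs$gene, perm$gene)]
    cnt <- cnt + as.integer(!is.na(dk) & abs(dk) >= abs(obs$diffk))
  }
  obs$p <- cnt / (n_perm + 1)
  obs
}

#' Sector classification of the (DiffK, p) plane
#'
#' The plane is cut by `DiffK = +/- diffk_thr` and `p = p_thr` into six
#' regions, numbered so the two significant flanks carry the hub genes:
#' \describe{
#'   \item{1}{`DiffK > diffk_thr`, `p < p_thr` (significant connectivity gain)}
#'   \item{2}{`DiffK > diffk_thr`, `p >= p_thr`}
#'   \item{3}{`DiffK < -diffk_thr`, `p < p_thr` (significant loss)}
#'   \item{4}{`DiffK < -diffk_thr`, `p >= p_thr`}
#'   \item{5}{`|DiffK| <= diffk_thr`, `p >= p_thr`}
#'   \item{6}{`|DiffK| <= diffk_thr`, `p < p_thr`}
#' }
#' A gene is a hub iff it lies in sector 1 or 3, i.e.
#' `|DiffK| > diffk_thr` and `p < p_thr`.
#'
#' @param records Data frame with `diffk` and `p` (from [diffk_pvalues()]).
#' @param diffk_thr,p_thr Thresholds (defaults 0.2 and 0.05).
#' @return `records` with `sector` (integer 1..6) and `hub` (logical) added.
#' @export
classify_sectors <- function(records, diffk_thr = 0.2, p_thr = 0.05) {
  dk <- records$diffk
  p <- records$p
  sector <- ifelse(dk > diffk_thr & p < p_thr, 1L,
            ifelse(dk > diffk_thr, 2L,
            ifelse(dk < -diffk_thr & p < p_thr, 3L,
            ifelse(dk < -diffk_thr, 4L,
            ifelse(p >= p_thr, 5L, 6L)))))
  records$sector <- sector
  records$hub <- sector %in% c(1L, 3L)
  records
}

#' Export node and edge tables for graph viewers
#'
#' Nodes carry the normalized connectivity, the hub flag and (optionally)
#' the differential-expression direction used for up/down colouring; edges
#' are gene pairs with `|r| >= edge_threshold`, keeping the correlation sign
#' so positive and negative co-expression can be drawn differently.
#'
#' @param state A `NetworkState`.
#' @param records Optional sector-classified DiffK records (adds `hub`).
#' @param directions Optional data frame with `gene` and `direction`.
#' @param edge_threshold Absolute-correlation display threshold in (0, 1].
#' @return List with data frames `nodes` (`gene`, `k`, `hub`, `direction`)
#'   and `edges` (`from`, `to`, `r`, `sign`).
#' @export
export_network <- function(state, records = NULL, directions = NULL,
                           edge_threshold = 0.8) {
  stopifnot(inherits(state, "NetworkState"))
  if (edge_threshold <= 0 || edge_threshold > 1)
    stop("edge_threshold must be in (0, 1]")
  nodes <- data.frame(gene = state$genes, k = unname(state$k),
                      stringsAsFactors = FALSE)
  nodes$hub <- if (!is.null(records))
    records$hub[match(nodes$gene, records$gene)] else NA
  nodes$direction <- if (!is.null(directions))
    directions$direction[match(nodes$gene, directions$gene)] else NA_character_
  r <- state$cor
  ix <- which(upper.tri(r) & abs(r) >= edge_threshold, arr.ind = TRUE)
  edges <- data.frame(from = rownames(r)[ix[, 1L]],
                      to = colnames(r)[ix[, 2L]],
                      r = r[ix],
                      stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  list(nodes = nodes, edges = edges)
}
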