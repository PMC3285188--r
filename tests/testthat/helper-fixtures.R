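# Small in-code fixtures shared across test files.

# A minimal valid paired study: `n_genes` genes, patients per group given by
# `n_patients`, values N(8, 1) unless a matrix is supplied.
toy_study <- function(n_genes = 5L, n_patients = c(IF = 2L, ID = 2L),
                      seed = 42L, matrix = NULL) {
  design <- do.call(rbind, lapply(names(n_patients), function(grp) {
    pats <- paste0(grp, seq_len(n_patients[[grp]]))
    data.frame(sample_id = c(paste0(pats, "_pre"), paste0(pats, "_post")),
               patient_id = rep(pats, 2L), group = grp,
               timepoint = rep(c("pre", "post"), each = length(pats)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(matrix)) {
    set.seed(seed)
    matrix <- matrix(rnorm(n_genes * nrow(design), 8), n_genes, nrow(design),
                     dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                     design$sample_id))
  }
  expression_study(matrix, design)
}

# One-sided Fisher p by explicit choose() arithmetic: upper tail of the
# hypergeometric (k or more DE genes in the set).
fisher_oracle <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# O(n^2) loop connectivity oracle: per-gene sum of |Pearson r| to all others.
loop_connectivity <- function(mat) {
  n <- nrow(mat)
  K <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) K[i] <- K[i] + abs(cor(mat[i, ], mat[j, ]))
    }
  }
  names(K) <- rownames(mat)
  K
}
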