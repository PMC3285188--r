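#' Pipeline thresholds and their defaults
#'
#' `p_thr`/`fdr_thr` gate differential expression and enrichment (both
#' 0.05), `diffk_thr` is the differential-connectivity hub threshold (0.2),
#' `edge_thr` the absolute-correlation display threshold for exported edges
#' (0.8), and `n_perm` the number of label-flip permutations (499).
#'
#' @param path Optional YAML file overriding any subset of the defaults.
#' @return Named list of thresholds.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- list(p_thr = 0.05, fdr_thr = 0.05, diffk_thr = 0.2,
              edge_thr = 0.8, n_perm = 499L)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  stopifnot(cfg$p_thr > 0, cfg$p_thr <= 1, cfg$fdr_thr > 0, cfg$fdr_thr <= 1,
            cfg$diffk_thr > 0, cfg$edge_thr > 0, cfg$edge_thr <= 1,
            cfg$n_perm >= 100L)
  cfg
}

#' Write a results table with a parameter header
#'
#' Prepends `# key: value` comment lines (parameters, seed, package
#' version) so every output records how it was produced, then writes the
#' table as TSV. [read_results_tsv()] skips the header.
#'
#' @param df Data frame.
#' @param path Output file.
#' @param params Named list recorded in the header.
#' @export
write_results_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  params <- c(list(generated_by = paste0("ahstnet ",
                                         utils::packageVersion("ahstnet"))),
              params)
  for (nm in names(params))
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(params[[nm]]), collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "-")
  invisible(df)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = "-",
                    stringsAsFactors = FALSE)
}
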