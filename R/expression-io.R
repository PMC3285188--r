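#' Assemble a paired expression study
#'
#' Bundles a log2 expression matrix (genes x samples) with its sample design
#' and validates the paired pre/post structure: every patient must contribute
#' exactly one `pre` and one `post` sample, ids must be unique, and the
#' matrix must be complete (no missing values).
#'
#' @param matrix Numeric matrix of log2 expression values, genes in rows
#'   (unique rownames) and samples in columns (unique colnames).
#' @param design Data frame with one row per sample and columns
#'   `sample_id`, `patient_id`, `group`, `timepoint` (`"pre"`/`"post"`).
#'   Rows are aligned to the matrix columns by `sample_id`, never by position.
#' @return An object of class `ExpressionStudy`: a list with elements
#'   `matrix` and `design` (design reordered to match the matrix columns).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' d <- data.frame(sample_id = paste0("s", 1:4),
#'                 patient_id = rep(c("P1", "P2"), each = 2),
#'                 group = "IF", timepoint = rep(c("pre", "post"), 2))
#' study <- expression_study(m, d)
#' @export
expression_study <- function(matrix, design) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("`matrix` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate sample ids in expression matrix")
  if (anyNA(matrix))
    stop("expression matrix contains missing values; apply a missing policy first")

  req <- c("sample_id", "patient_id", "group", "timepoint")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample ids in design")
  extra <- setdiff(design$sample_id, colnames(matrix))
  if (length(extra))
    stop("design lists sample(s) absent from matrix: ",
         paste(extra, collapse = ", "))
  extra <- setdiff(colnames(matrix), design$sample_id)
  if (length(extra))
    stop("matrix has sample(s) absent from design: ",
         paste(extra, collapse = ", "))
  if (!all(design$timepoint %in% c("pre", "post")))
    stop("timepoint must be 'pre' or 'post'")

  # paired design: each patient exactly one pre and one post sample
  tab <- table(design$patient_id, design$timepoint)
  bad <- rownames(tab)[tab[, "pre"] != 1 | tab[, "post"] != 1]
  if (length(bad))
    stop("unpaired patient(s): ", paste(bad, collapse = ", "))
  grp_per_pat <- tapply(design$group, design$patient_id,
                        function(g) length(unique(g)))
  if (any(grp_per_pat != 1))
    stop("patient assigned to more than one group")

  design <- design[match(colnames(matrix), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(matrix = matrix, design = design), class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  d <- x$design
  cat("ExpressionStudy:", nrow(x$matrix), "genes x", ncol(x$matrix), "samples\n")
  cat("  patients:", length(unique(d$patient_id)),
      "(", paste(sprintf("%s=%d", names(table(d$group[d$timepoint == "pre"])),
                         table(d$group[d$timepoint == "pre"])), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Read an expression study from disk
#'
#' Reads a tab-delimited expression matrix (header row of sample ids, first
#' column of gene ids) or a GCT `#1.2` file, together with a tab-delimited
#' design table, and returns a validated [expression_study()].
#'
#' Genes containing missing values are dropped with a message (paired
#' differences and correlations require complete vectors). Gene order is
#' preserved as on disk; samples are aligned to the design by id. Duplicate
#' gene ids are collapsed to the first occurrence with a warning
#' (`duplicate_genes = "first"`) or rejected (`"error"`).
#'
#' @param path Expression matrix file (TSV, or GCT when the first line is
#'   `#1.2`).
#' @param design_path Design TSV with columns `sample_id`, `patient_id`,
#'   `group`, `timepoint`.
#' @param log2_transform If `TRUE`, values are log2-transformed
#'   (`log2(x + 1)`) on load; use when the matrix is on the linear scale.
#' @param duplicate_genes Policy for duplicated gene ids.
#' @return An `ExpressionStudy`.
#' @export
read_expression <- function(path, design_path, log2_transform = FALSE,
                            duplicate_genes = c("first", "error")) {
  duplicate_genes <- match.arg(duplicate_genes)
  first <- readLines(path, n = 1L)
  if (identical(first, "#1.2")) {
    mat <- read_gct_matrix(path)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    mat <- as_numeric_matrix(df, path)
  }
  if (log2_transform) mat <- log2(mat + 1)

  if (anyDuplicated(rownames(mat))) {
    if (duplicate_genes == "error") stop("duplicate gene ids in ", path)
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    warning("collapsing ", length(dup),
            " duplicated gene id(s) to first occurrence")
    mat <- mat[!duplicated(rownames(mat)), , drop = FALSE]
  }
  n_na <- sum(apply(mat, 1L, anyNA))
  if (n_na > 0L) {
    message("dropping ", n_na, " gene(s) with missing values")
    mat <- mat[!apply(mat, 1L, anyNA), , drop = FALSE]
  }
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  expression_study(mat, design)
}

# Coerce a read.delim frame (first column gene ids) to a numeric matrix,
# naming the offending cell on failure.
as_numeric_matrix <- function(df, path) {
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]) & body[[j]] != "NA")
    if (length(bad))
      stop("non-numeric value in ", path, " at gene '", ids[bad[1L]],
           "', sample '", names(body)[j], "'")
    body[[j]] <- v
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  mat
}

read_gct_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !identical(lines[1L], "#1.2"))
    stop("not a GCT 1.2 file: ", path)
  dims <- as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]])
  df <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L])
    stop("GCT dimension line disagrees with table in ", path)
  df[[2L]] <- NULL  # Description column
  as_numeric_matrix(df, path)
}

#' Write an expression study to disk
#'
#' Writes the matrix as TSV (gene ids in the first column) or GCT `#1.2`,
#' and the design as TSV. [read_expression()] on the result round-trips the
#' study exactly.
#'
#' @param study An `ExpressionStudy`.
#' @param path,design_path Output files for the matrix and the design.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(study, path, design_path,
                             format = c("tsv", "gct")) {
  format <- match.arg(format)
  stopifnot(inherits(study, "ExpressionStudy"))
  m <- study$matrix
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    df <- data.frame(Name = rownames(m), Description = "na", m,
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(study$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(study)
}

#' Extract the expression slice for one condition
#'
#' @param study An `ExpressionStudy`.
#' @param group Patient group label (e.g. `"IF"` or `"ID"`).
#' @param timepoint `"pre"` or `"post"`.
#' @param genes Optional gene ids to keep (in the given order).
#' @return Numeric matrix, genes x profiles, columns ordered by patient id.
#' @export
condition_slice <- function(study, group, timepoint, genes = NULL) {
  stopifnot(inherits(study, "ExpressionStudy"))
  d <- study$design
  keep <- d$group == group & d$timepoint == timepoint
  if (!any(keep)) stop("no samples for group ", group, " timepoint ", timepoint)
  ids <- d$sample_id[keep][order(d$patient_id[keep])]
  m <- study$matrix[, ids, drop = FALSE]
  if (!is.null(genes)) {
    bad <- setdiff(genes, rownames(m))
    if (length(bad)) stop("unknown gene id(s): ", paste(bad, collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  m
}
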