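#' Build a gene-set collection
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Optional background gene list. When supplied, every set is
#'   intersected with it; sets emptied by the intersection are dropped with a
#'   warning.
#' @return Object of class `GeneSetCollection`: list with `sets` and
#'   `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names")
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  sets <- lapply(sets, as.character)
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    sets <- lapply(sets, intersect, y = universe)
    empty <- lengths(sets) == 0L
    if (any(empty)) {
      warning("dropping ", sum(empty),
              " set(s) empty after intersection with the universe")
      sets <- sets[!empty]
    }
  }
  structure(list(sets = sets, universe = universe),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x$sets), "sets",
      if (!is.null(x$universe)) paste0("(universe of ", length(x$universe),
                                       " genes)"), "\n")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-delimited.
#' Duplicate members within a set are de-duplicated with a warning.
#'
#' @param path GMT file.
#' @param universe Optional background gene list (see
#'   [gene_set_collection()]).
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT parse error in ", path, ": line ", short[1L],
         " has fewer than 3 fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  n_dup <- sum(vapply(sets, anyDuplicated, integer(1L)) > 0L)
  if (n_dup > 0L) {
    warning("de-duplicated members in ", n_dup, " gene set(s)")
    sets <- lapply(sets, unique)
  }
  gene_set_collection(sets, universe)
}

#' Write gene sets in GMT format
#'
#' @param collection A `GeneSetCollection`.
#' @param path Output file.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(collection)
}
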