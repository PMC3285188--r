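#' Read a per-patient clinical table
#'
#' Tab-delimited, one row per patient, with `-` marking values that were not
#' acquired (kept as `NA`, never silently zero). Required columns: `case`,
#' `group` and the numeric variables listed in [clinical_variables()].
#' GADA titers must be strictly positive so that the natural-log transform
#' used for testing is defined.
#'
#' @param path Clinical TSV.
#' @return Data frame of class `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "-",
                          check.names = FALSE)
  req <- c("case", "group", clinical_variables())
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  for (v in clinical_variables()) df[[v]] <- as.numeric(df[[v]])
  if (any(!is.na(df$gada) & df$gada <= 0))
    stop("GADA must be > 0 (natural-log transform undefined)")
  if (!all(df$group %in% c("IF", "ID")))
    stop("group must be 'IF' or 'ID'")
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Numeric variables of the clinical table
#'
#' Age (years), BMI (kg/m^2), infused CD34+ cell dose (10^6/kg), delay from
#' symptom onset to transplantation (months), fasting and postprandial blood
#' glucose (mmol/L), HbA1c (%), GADA titer (U/mL), insulin dose at
#' pre-treatment / 6 / 12 months (IU/kg/day) and C-peptide at the same
#' timepoints (ng/mL).
#'
#' @return Character vector of column names.
#' @export
clinical_variables <- function() {
  c("age", "bmi", "cd34_dose", "duration", "fbg", "pbg", "hba1c", "gada",
    "insulin_pre", "insulin_6mo", "insulin_12mo",
    "cpeptide_pre", "cpeptide_6mo", "cpeptide_12mo")
}

#' Write a clinical table
#'
#' Missing values are written as `-`, matching the convention read back by
#' [read_clinical()].
#'
#' @param table A `ClinicalTable` (or compatible data frame).
#' @param path Output TSV.
#' @export
write_clinical <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "-")
  invisible(table)
}

#' The packaged nine-patient cohort table
#'
#' The published pretreatment and follow-up variables of the nine AHST-treated
#' type 1 diabetes patients: six who became insulin free (IF) and three who
#' remained insulin dependent (ID) at 12 months. Patient 9's 12-month
#' C-peptide was not acquired and is `NA`. Note that the published IF-group
#' GADA mean (864.8) is not the arithmetic mean of the printed column
#' (1196.97) — a likely erratum in the source table; this package reproduces
#' only cell values that follow from the printed per-patient data.
#'
#' @return A `ClinicalTable` with 9 rows.
#' @export
table1_clinical <- function() {
  path <- system.file("extdata", "clinical_table1.tsv", package = "ahstnet",
                      mustWork = TRUE)
  read_clinical(path)
}
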