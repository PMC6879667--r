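# Plain-text input/output. All files are TSV or one-value-per-line text;
# '#'-prefixed lines are comments; numbers use the C locale ('.' decimal).

#' Read P-values from a text file
#'
#' Accepts either one P-value per line or a TSV with a named column.
#' Lines starting with `#` are ignored. Invalid entries are reported
#' with their line numbers.
#'
#' @param path file path.
#' @param column optional column name when the file is a TSV with a
#'   header; by default a single-column file is assumed.
#' @return A [pvalue_set()].
#' @export
read_pvalues <- function(path, column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data lines in ", path)
  if (!is.null(column)) {
    df <- read.delim(textConnection(lines[keep]), header = TRUE,
                     check.names = FALSE)
    if (!column %in% names(df)) stop("column '", column, "' not found")
    vals <- df[[column]]
    lineno <- which(keep)[-1L]
  } else {
    vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
    lineno <- which(keep)
  }
  bad <- which(is.na(vals))
  if (length(bad) > 0)
    stop("non-numeric P-value at line(s) ",
         paste(utils::head(lineno[bad], 5L), collapse = ", "))
  out_of_range <- which(vals < 0 | vals > 1)
  if (length(out_of_range) > 0)
    stop("P-value outside [0, 1] at line(s) ",
         paste(utils::head(lineno[out_of_range], 5L), collapse = ", "))
  pvalue_set(vals)
}

#' Write combined results to TSV
#'
#' @param results a [combined_result()] or a list of them.
#' @param path output path ("" writes to stdout).
#' @return Invisibly, the data frame written.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "combined_result")) results <- list(results)
  if (length(results) == 0L) stop("no results to write")
  df <- do.call(rbind, lapply(results, as.data.frame))
  df <- df[, c("method", "k", "statistic", "p_combined", "notes")]
  write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
              file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a correlation matrix from TSV
#'
#' Expects L rows by L columns of numbers, no header, tab- or
#' whitespace-separated; the matrix must be symmetric with unit
#' diagonal.
#'
#' @param path file path.
#' @return A numeric matrix.
#' @export
read_correlation <- function(path) {
  m <- as.matrix(read.delim(path, header = FALSE, comment.char = "#"))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("correlation matrix must be square")
  if (!isSymmetric(m, tol = 1e-8)) stop("correlation matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-8)) stop("diagonal must be 1")
  m
}

#' Read a haplotype frequency table from TSV
#'
#' Expects columns `haplotype` (strings over `{0,1}`) and `freq`.
#'
#' @param path file path.
#' @return Data frame suitable for [ld_correlation_from_haplotypes()].
#' @export
read_haplotypes <- function(path) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   colClasses = c(haplotype = "character"))
  if (!all(c("haplotype", "freq") %in% names(df)))
    stop("expected columns 'haplotype' and 'freq'")
  df
}

#' Packaged worked example: 11 SNP P-values of the mu-opioid receptor
#'
#' Individual SNP association P-values with pain sensitivity for 11
#' variants of the mu-opioid receptor gene (OPRM1), as packaged in
#' `inst/extdata/mor_table8.tsv`. The smallest (rs563649, P = 0.0007)
#' drives the minimum-P style combiners; the Simes combined P-value for
#' the set is 0.0077.
#'
#' @return Data frame with columns `snp` and `pvalue`.
#' @examples
#' tab <- mor_table8()
#' simes_pvalue(tab$pvalue)
#' @export
mor_table8 <- function() {
  path <- system.file("extdata", "mor_table8.tsv", package = "artcombine",
                      mustWork = TRUE)
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   colClasses = c(snp = "character", pvalue = "double"))
  df
}
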