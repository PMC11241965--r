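#' Construct an abundance table
#'
#' An abundance table is the central container of the package: a numeric
#' matrix of label-free protein intensities with proteins as rows and
#' samples as columns. Non-detections are represented as `NA` — never zero —
#' because non-quantification in label-free LC/MS is censoring at the limit
#' of detection, and `log10(0)` is undefined. The table carries a `scale`
#' marker so that raw-intensity operations (batch correction, fold changes)
#' and log10 operations (t tests, correlations) cannot be mixed up.
#'
#' @param values numeric matrix; rownames are protein ids, colnames sample
#'   ids. `NA` marks a missing (undetected) measurement.
#' @param scale `"raw"` (non-negative intensities) or `"log10"`.
#' @return an object of class `abundance_table` (a matrix with a `scale`
#'   attribute).
#' @examples
#' m <- matrix(c(10, 30, 20, NA), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' tab <- abundance_table(m)
#' @export
abundance_table <- function(values, scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have protein ids as rownames and sample ids as colnames")
  dup_p <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_p))
    stop("duplicated protein id(s): ", paste(unique(dup_p), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "))
  finite_bad <- is.infinite(values)
  if (any(finite_bad))
    stop("non-finite value at [",
         rownames(values)[row(values)[finite_bad][1L]], ", ",
         colnames(values)[col(values)[finite_bad][1L]], "]")
  if (scale == "raw") {
    neg <- !is.na(values) & values < 0
    if (any(neg)) {
      i <- which(neg)[1L]
      stop("negative intensity at [", rownames(values)[row(values)[i]],
           ", ", colnames(values)[col(values)[i]], "]")
    }
  }
  structure(values, scale = scale, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table: ", nrow(x), " proteins x ", ncol(x), " samples (",
      attr(x, "scale"), " scale), ",
      round(100 * mean(is.na(x)), 1), "% missing\n", sep = "")
  invisible(x)
}

#' @export
`[.abundance_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, scale = attr(x, "scale"),
                     class = c("abundance_table", "matrix", "array"))
  out
}

#' Scale marker of an abundance table
#' @param table an `abundance_table`.
#' @return `"raw"` or `"log10"`.
#' @export
abundance_scale <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  attr(table, "scale")
}

#' Read an abundance matrix from delimited text
#'
#' Expects a header row `protein_id,<sample ids...>` and one row per protein
#' (the usual proteomics matrix convention). Tab- and comma-separated files
#' are both accepted; the delimiter is sniffed from the header line. Cells
#' equal to `missing_token` or empty become missing.
#'
#' @param path file path.
#' @param missing_token string marking a non-detection (default `"NA"`).
#' @param scale scale of the stored values, `"raw"` by default.
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path, missing_token = "NA", scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c(missing_token, ""),
                          colClasses = "character",
                          check.names = FALSE, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("abundance file needs a protein id column plus at least one sample column")
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- !is.na(vals) & is.na(storage)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("non-numeric value '", vals[i], "' at row ", ids[row(vals)[i]],
         ", column ", colnames(vals)[col(vals)[i]])
  }
  dimnames(storage) <- list(ids, colnames(vals))
  abundance_table(storage, scale = scale)
}

#' Write an abundance matrix to delimited text
#'
#' Values are serialised with 17 significant digits so that a write-then-read
#' round trip reproduces the matrix bit-exactly.
#'
#' @param table an `abundance_table`.
#' @param path output path.
#' @param sep field separator, tab by default.
#' @param missing_token token written for missing cells.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path, sep = "\t", missing_token = "NA") {
  stopifnot(inherits(table, "abundance_table"))
  chr <- matrix(sprintf("%.17g", table), nrow(table))
  chr[is.na(table)] <- missing_token
  lines <- c(paste(c("protein_id", colnames(table)), collapse = sep),
             paste(rownames(table), apply(chr, 1L, paste, collapse = sep),
                   sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Log10-transform a raw abundance table
#'
#' Downstream group comparisons assume approximate normality of log10
#' intensities, so every statistical stage operates on the transformed
#' table. Missing values stay missing; an explicit zero is an error because
#' non-detections must be encoded as missing upstream.
#'
#' @param table raw-scale `abundance_table`.
#' @return the table on log10 scale.
#' @export
to_log10 <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (abundance_scale(table) != "raw")
    stop("to_log10() expects a raw-scale table")
  zero <- !is.na(table) & table == 0
  if (any(zero)) {
    i <- which(zero)[1L]
    stop("zero intensity at [", rownames(table)[row(table)[i]], ", ",
         colnames(table)[col(table)[i]],
         "]: log10 undefined; encode non-detections as missing, not zero")
  }
  out <- log10(unclass(table))
  abundance_table(out, scale = "log10")
}

#' Back-transform a log10 abundance table to raw scale
#' @param table log10-scale `abundance_table`.
#' @return the table on raw scale (`10^x` pointwise).
#' @export
from_log10 <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (abundance_scale(table) != "log10")
    stop("from_log10() expects a log10-scale table")
  abundance_table(10^unclass(table), scale = "raw")
}

#' Per-protein detection rate within a sample subset
#'
#' Fraction of the given samples in which each protein was detected
#' (non-missing). Detection rates define the analysis universes: proteins
#' complete in a comparison group, and case-specific proteins detected in
#' patients but not controls.
#'
#' @param table an `abundance_table` (either scale).
#' @param sample_subset character vector of sample ids, non-empty and all
#'   present in the table.
#' @return named numeric vector, one rate in `[0, 1]` per protein.
#' @export
detection_rate <- function(table, sample_subset) {
  stopifnot(inherits(table, "abundance_table"))
  if (length(sample_subset) == 0L)
    stop("'sample_subset' must be non-empty")
  missing_ids <- setdiff(sample_subset, colnames(table))
  if (length(missing_ids))
    stop("sample id(s) not in table: ", paste(missing_ids, collapse = ", "))
  sub <- unclass(table)[, sample_subset, drop = FALSE]
  rowMeans(!is.na(sub))
}
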