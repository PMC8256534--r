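#' Validate an OTU count table
#'
#' A count table is a plain base matrix of non-negative integer read
#' counts with samples as rows and taxa as columns, both dimensions
#' named. This follows the `vegan` convention for community matrices, so
#' validated tables can be passed directly to ordination and dissimilarity
#' functions.
#'
#' @param x matrix of counts, samples x taxa, with unique dimnames.
#' @param require_positive_rows require every sample to have at least one
#'   read (the default; filtering steps that keep samples must not create
#'   empty ones).
#' @return `x`, invisibly, after validation.
#' @export
validate_count_table <- function(x, require_positive_rows = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("count table must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("count table must have sample ids as rownames and taxon ids as colnames")
  if (anyDuplicated(rownames(x)))
    stopf("duplicate sample identifiers: %s",
          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stopf("duplicate taxon identifiers: %s",
          paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (nrow(x) < 1L || ncol(x) < 2L)
    stopf("count table needs at least 1 sample and 2 taxa")
  if (anyNA(x) || min(x) < 0 || any(x != round(x)))
    stopf("counts must be non-negative integers")
  if (require_positive_rows && any(rowSums(x) == 0))
    stopf("samples with zero total reads: %s",
          paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  invisible(x)
}

#' Read an OTU count table
#'
#' Reads a tab-delimited count table (first column = identifier, header
#' row = the other dimension's identifiers) or a JSON BIOM file, and
#' returns a validated samples-x-taxa integer matrix.
#'
#' Amplicon pipelines disagree on orientation (taxa-as-rows is common),
#' and a silently transposed table is a classic analysis bug. When
#' `sample_ids` is supplied (e.g. from the metadata file) the orientation
#' is auto-detected by matching identifiers; otherwise the `orientation`
#' argument is taken at face value.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"biom-json"` (requires the `biomformat`
#'   package).
#' @param orientation `"samples"` if rows are samples, `"taxa"` if rows
#'   are taxa, or `"auto"` to detect from `sample_ids`.
#' @param sample_ids optional character vector of known sample
#'   identifiers used for auto-detection.
#' @return samples-x-taxa integer matrix.
#' @export
read_count_table <- function(path, format = c("tsv", "biom-json"),
                             orientation = c("auto", "samples", "taxa"),
                             sample_ids = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)

  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stopf("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))  # biom stores taxa x samples
  } else {
    raw <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "", comment.char = "")
    ids <- as.character(raw[[1L]])
    if (anyDuplicated(ids))
      stopf("duplicate identifiers in first column: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    hdr <- colnames(raw)[-1L]
    if (anyDuplicated(hdr))
      stopf("duplicate identifiers in header: %s",
            paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
    m <- as.matrix(raw[, -1L, drop = FALSE])
    rownames(m) <- ids
  }

  if (orientation == "auto") {
    if (is.null(sample_ids)) {
      orientation <- "samples"
    } else {
      in_rows <- mean(rownames(m) %in% sample_ids)
      in_cols <- mean(colnames(m) %in% sample_ids)
      if (in_rows == 0 && in_cols == 0)
        stopf("none of the supplied sample_ids match either table dimension")
      orientation <- if (in_cols > in_rows) "taxa" else "samples"
    }
  }
  if (orientation == "taxa") m <- t(m)
  storage.mode(m) <- "double"
  validate_count_table(m, require_positive_rows = FALSE)
  if (max(m) < .Machine$integer.max) storage.mode(m) <- "integer"
  m
}

#' Write an OTU count table as TSV
#'
#' Writes samples as rows with a leading `sample_id` column; round-trips
#' losslessly through [read_count_table()].
#'
#' @param x samples-x-taxa count matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  validate_count_table(x, require_positive_rows = FALSE)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
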