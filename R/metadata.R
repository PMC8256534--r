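# Per-sample covariates: the study design frame.

.meta_columns <- c("sample_id", "site", "environment", "land_class",
                   "local_type", "phenotype_alleles", "sex")
.land_to_local <- c(campus = "built", suburban_park = "built",
                    urban_forest = "forest", rural_forest = "forest")

#' Validate a sample metadata frame
#'
#' The design frame carries, per sample: trapping `site`, `environment`
#' (`city`/`rural`), `land_class` (`campus`, `suburban_park`,
#' `urban_forest`, `rural_forest`), `local_type` (`built`/`forest`),
#' `phenotype_alleles` (copies of the melanism-associated MC1R mutant
#' allele: agouti = 0, intermediate = 1, black = 2), and `sex` (`F`/`M`).
#' The land class to local type mapping is checked for consistency
#' (campus and suburban park are built environments; urban and rural
#' forests are forest).
#'
#' @param meta data.frame with the columns listed above.
#' @return `meta`, invisibly.
#' @export
validate_sample_metadata <- function(meta) {
  if (!is.data.frame(meta)) stopf("metadata must be a data.frame")
  missing_cols <- setdiff(.meta_columns, colnames(meta))
  if (length(missing_cols))
    stopf("metadata is missing columns: %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stopf("duplicate sample_id in metadata")
  if (!all(meta$environment %in% c("city", "rural")))
    stopf("environment must be 'city' or 'rural'")
  if (!all(meta$land_class %in% names(.land_to_local)))
    stopf("land_class must be one of: %s",
          paste(names(.land_to_local), collapse = ", "))
  if (!all(meta$local_type %in% c("built", "forest")))
    stopf("local_type must be 'built' or 'forest'")
  bad <- meta$local_type != .land_to_local[meta$land_class]
  if (any(bad))
    stopf("inconsistent land_class/local_type for samples: %s",
          paste(meta$sample_id[bad], collapse = ", "))
  if (!all(meta$phenotype_alleles %in% 0:2))
    stopf("phenotype_alleles must be 0, 1 or 2")
  if (!all(meta$sex %in% c("F", "M")))
    stopf("sex must be 'F' or 'M'")
  invisible(meta)
}

#' Read sample metadata from TSV
#'
#' @param path tab-delimited file with columns `sample_id`, `site`,
#'   `environment`, `land_class`, `local_type`, `phenotype_alleles`,
#'   `sex`.
#' @return validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  meta <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, quote = "",
                     colClasses = "character")
  meta$phenotype_alleles <- as.integer(meta$phenotype_alleles)
  validate_sample_metadata(meta)
  meta
}

#' Write sample metadata as TSV
#'
#' @param meta validated metadata frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  validate_sample_metadata(meta)
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a count table, tree, and metadata to their common support
#'
#' Restricts the table's taxa to the intersection of table taxa and tree
#' tips (pruning the tree to match), and the table's samples to those
#' present in the metadata. Drops are reported via `message()`. The
#' operation is idempotent.
#'
#' @param table samples-x-taxa count matrix.
#' @param tree [ape::phylo] whose tips are taxon ids.
#' @param meta sample metadata frame (optional; `NULL` skips sample
#'   alignment).
#' @return list with elements `table`, `tree`, `meta`, and a `dropped`
#'   list reporting removed taxa and samples.
#' @export
align_inputs <- function(table, tree, meta = NULL) {
  validate_count_table(table, require_positive_rows = FALSE)
  validate_tree(tree)
  shared_taxa <- intersect(colnames(table), tree$tip.label)
  if (length(shared_taxa) == 0)
    stopf("alignment error: count table taxa and tree tips are disjoint")
  dropped_taxa <- setdiff(colnames(table), shared_taxa)
  dropped_tips <- setdiff(tree$tip.label, shared_taxa)
  table <- table[, shared_taxa, drop = FALSE]
  if (length(dropped_tips)) tree <- ape::keep.tip(tree, shared_taxa)

  dropped_samples <- character(0)
  if (!is.null(meta)) {
    validate_sample_metadata(meta)
    shared_samples <- intersect(rownames(table), meta$sample_id)
    if (length(shared_samples) == 0)
      stopf("alignment error: no samples shared between table and metadata")
    dropped_samples <- setdiff(rownames(table), shared_samples)
    table <- table[shared_samples, , drop = FALSE]
    meta <- meta[match(shared_samples, meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (length(dropped_taxa) || length(dropped_tips) || length(dropped_samples))
    message(sprintf(
      "align_inputs: dropped %d table taxa, %d tree tips, %d samples",
      length(dropped_taxa), length(dropped_tips), length(dropped_samples)))
  list(table = table, tree = tree, meta = meta,
       dropped = list(taxa = dropped_taxa, tips = dropped_tips,
                      samples = dropped_samples))
}
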