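#' Construct an omics data block
#'
#' An `omics_block` holds one X-side data block of the multi-block model:
#' a numeric matrix of non-negative measurements with samples in rows and
#' variables (genes or metabolites) in columns, plus a block name.
#'
#' @param values numeric matrix, samples x variables, with complete
#'   dimnames. Values must be finite.
#' @param block_name single string naming the block (e.g. `"transcriptome"`).
#' @return an object of class `omics_block`: a list with elements
#'   `block_name`, `values`, `sample_ids`, `variable_ids`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("s", 1:3), c("g1", "g2")))
#' omics_block(m, "demo")
#' @export
omics_block <- function(values, block_name) {
  stopifnot(is.matrix(values), is.numeric(values),
            is.character(block_name), length(block_name) == 1L)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("omics_block values must carry sample and variable names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate variable ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("non-finite values in block '", block_name, "'")
  structure(list(block_name = block_name,
                 values = values,
                 sample_ids = rownames(values),
                 variable_ids = colnames(values)),
            class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("omics_block '%s': %d samples x %d variables\n",
              x$block_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$values)

# Accept either an omics_block or a bare samples x variables matrix.
block_values <- function(x) {
  if (inherits(x, "omics_block")) x$values
  else if (is.matrix(x)) x
  else stop("expected an omics_block or a matrix")
}

#' Read an omics block from a TSV file
#'
#' The on-disk convention follows the field's matrix exports: rows are
#' variables (genes or metabolites), columns are samples, with variable ids
#' in the first column. The block is transposed into the in-memory
#' samples x variables orientation.
#'
#' @param path path to a tab-separated file.
#' @param block_name name for the resulting block.
#' @return an [omics_block()].
#' @seealso [write_block()] for the inverse.
#' @export
read_block <- function(path, block_name) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate variable ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- colnames(mat)[!apply(mat, 2L, function(col)
      all(!is.na(suppressWarnings(as.numeric(col)))))]
    stop("non-numeric cells in ", path,
         if (length(bad)) paste0(" (columns: ", paste(bad, collapse = ", "), ")"))
  }
  rownames(mat) <- ids
  omics_block(t(mat), block_name)
}

#' Write an omics block to a TSV file
#'
#' @param block an [omics_block()].
#' @param path output path; rows are variables, columns samples, first
#'   column `feature_id`.
#' @return `path`, invisibly.
#' @export
write_block <- function(block, path) {
  mat <- t(block_values(block))
  df <- data.frame(feature_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `treatment`, `day`, `replicate`,
#' `scald`. Validates treatment labels, uniqueness of
#' (treatment, day, replicate) and the ordinal 1-4 scald scale.
#'
#' @param path path to the metadata TSV.
#' @param treatments allowed treatment labels.
#' @return a data.frame of sample metadata, one row per sample.
#' @export
read_metadata <- function(path, treatments = c("control", "DPA", "MCP")) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(meta, treatments)
}

validate_metadata <- function(meta, treatments = c("control", "DPA", "MCP")) {
  need <- c("sample_id", "treatment", "day", "replicate", "scald")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(meta$treatment), treatments)
  if (length(bad))
    stop("unknown treatment labels: ", paste(bad, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  key <- paste(meta$treatment, meta$day, meta$replicate)
  if (anyDuplicated(key))
    stop("duplicate (treatment, day, replicate) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!all(meta$scald %in% 1:4))
    stop("scald scores must be ordinal 1-4")
  meta$treatment <- factor(meta$treatment, levels = treatments)
  meta
}

#' Read a functional-bin annotation table
#'
#' @param path TSV with columns `gene_id` and `bin_path`; bin paths are
#'   hierarchical with `.` separating levels (e.g. `"cell_wall.pectin.PME"`).
#' @return a data.frame with columns `gene_id`, `bin_path`.
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "bin_path") %in% names(ann)))
    stop("annotation table needs columns gene_id, bin_path")
  ann[, c("gene_id", "bin_path")]
}

# Align a block's samples to the order of a metadata table; errors if any
# metadata sample is absent from the block.
align_block <- function(block, meta) {
  vals <- block_values(block)
  miss <- setdiff(meta$sample_id, rownames(vals))
  if (length(miss))
    stop("samples in metadata missing from block '",
         if (inherits(block, "omics_block")) block$block_name else "matrix",
         "': ", paste(miss, collapse = ", "))
  vals <- vals[meta$sample_id, , drop = FALSE]
  if (inherits(block, "omics_block")) omics_block(vals, block$block_name)
  else vals
}
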