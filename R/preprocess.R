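#' Filter low-expression genes
#'
#' Applies the two-rule detection filter to an RPKM expression block. A
#' gene is kept iff
#' \enumerate{
#'   \item the sum of its replicates in at least one (treatment, day) cell
#'     exceeds `threshold` RPKM, and
#'   \item it is detected (replicate sum > 0) in at least two cells.
#' }
#' Genes failing rule 1 are reported as `low_signal`; genes passing rule 1
#' but detected in fewer than two cells as `single_cell_detection`
#' (mirroring the sequential application of the rules).
#'
#' @param expr an [omics_block()] of RPKM values (samples x genes).
#' @param meta sample metadata mapping each sample to a (treatment, day)
#'   cell; every expression sample must be present.
#' @param threshold RPKM threshold for the cell replicate sum (strict `>`).
#' @return a list with `block` (the filtered [omics_block()]) and `report`
#'   (data.frame `gene_id`, `rule_failed` for removed genes).
#' @export
filter_genes <- function(expr, meta, threshold = 5) {
  vals <- block_values(expr)
  miss <- setdiff(rownames(vals), meta$sample_id)
  if (length(miss))
    stop("expression samples missing from metadata: ",
         paste(miss, collapse = ", "))
  meta <- meta[match(rownames(vals), meta$sample_id), ]
  cell <- paste(meta$treatment, meta$day, sep = "|")
  cell_sums <- rowsum(vals, group = cell)       # cells x genes
  pass_a <- apply(cell_sums > threshold, 2L, any)
  detected <- colSums(cell_sums > 0)
  pass_b <- detected >= 2L
  keep <- pass_a & pass_b
  report <- data.frame(
    gene_id = colnames(vals)[!keep],
    rule_failed = ifelse(!pass_a[!keep], "low_signal", "single_cell_detection"),
    stringsAsFactors = FALSE)
  block <- omics_block(vals[, keep, drop = FALSE],
                       if (inherits(expr, "omics_block")) expr$block_name
                       else "expression")
  list(block = block, report = report)
}

#' Autoscale an omics block
#'
#' Mean-centers and unit-variance scales each variable (the chemometric
#' "autoscaling" convention: sd with the n-1 denominator). Zero-variance
#' variables cannot be scaled and are dropped and reported. The centering
#' means and scaling sds are retained as the standard `scaled:center` /
#' `scaled:scale` attributes on the values so the transform is invertible.
#'
#' @param block an [omics_block()] or samples x variables matrix.
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` before scaling
#'   (optional pre-transform for relative-abundance blocks).
#' @return a list with `block` (scaled [omics_block()]) and `dropped`
#'   (character vector of zero-variance variable ids).
#' @examples
#' m <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
#'             dimnames = list(paste0("s", 1:3), c("v1", "v2")))
#' autoscale(omics_block(m, "demo"))$dropped  # "v2"
#' @export
autoscale <- function(block, log2_transform = FALSE) {
  vals <- block_values(block)
  if (nrow(vals) < 2) stop("autoscaling needs at least 2 samples")
  if (log2_transform) vals <- log2(vals + 1)
  sds <- apply(vals, 2L, sd)
  dropped <- colnames(vals)[sds == 0]
  keep <- sds > 0
  scaled <- scale(vals[, keep, drop = FALSE],
                  center = TRUE, scale = sds[keep])
  name <- if (inherits(block, "omics_block")) block$block_name else "block"
  out <- omics_block(unclass(scaled)[, , drop = FALSE], name)
  attr(out$values, "scaled:center") <- attr(scaled, "scaled:center")
  attr(out$values, "scaled:scale") <- attr(scaled, "scaled:scale")
  list(block = out, dropped = dropped)
}

#' Invert autoscaling using the stored centers and sds
#'
#' @param block a scaled [omics_block()] produced by [autoscale()].
#' @return the block on its original scale.
#' @export
unscale <- function(block) {
  vals <- block_values(block)
  ctr <- attr(vals, "scaled:center")
  scl <- attr(vals, "scaled:scale")
  if (is.null(ctr) || is.null(scl))
    stop("block carries no scaling attributes")
  out <- sweep(sweep(vals, 2L, scl, `*`), 2L, ctr, `+`)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  omics_block(out, if (inherits(block, "omics_block")) block$block_name
                   else "block")
}

#' Build the response (Y) design from sample metadata
#'
#' Assembles the dependent variables of the supervised model: one 0/1
#' indicator column per treatment (dummy-coded, rows summing to 1), a
#' continuous storage-day column and the continuous scald-severity column.
#' All columns are autoscaled with the same n-1 convention as the X-blocks
#' so blocks and responses are on comparable scales; the raw columns are
#' retained for reporting and sign assignment.
#'
#' @param meta validated sample metadata (see [read_metadata()]).
#' @param treatments treatment labels defining the indicator columns.
#' @return an object of class `response_design`: list with `Y` (scaled
#'   samples x responses matrix), `raw` (unscaled data.frame) and
#'   `responses` (column names).
#' @export
build_response <- function(meta,
                           treatments = if (is.factor(meta$treatment))
                             levels(meta$treatment)
                           else unique(as.character(meta$treatment))) {
  bad <- setdiff(unique(as.character(meta$treatment)), treatments)
  if (length(bad))
    stop("unknown treatment labels: ", paste(bad, collapse = ", "))
  ind <- vapply(treatments,
                function(tr) as.numeric(meta$treatment == tr),
                numeric(nrow(meta)))
  raw <- cbind(ind, day = meta$day, scald = meta$scald)
  rownames(raw) <- meta$sample_id
  sds <- apply(raw, 2L, sd)
  if (any(sds == 0))
    stop("constant response column(s): ",
         paste(colnames(raw)[sds == 0], collapse = ", "))
  Y <- scale(raw, center = TRUE, scale = sds)
  structure(list(Y = unclass(Y)[, , drop = FALSE],
                 raw = as.data.frame(raw),
                 responses = colnames(raw)),
            class = "response_design")
}

#' @export
print.response_design <- function(x, ...) {
  cat(sprintf("response_design: %d samples x %d responses (%s)\n",
              nrow(x$Y), ncol(x$Y), paste(x$responses, collapse = ", ")))
  invisible(x)
}
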