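#' Median-normalize a reference compendium across cell types
#'
#' Subtracts each gene's across-column median so that values express how
#' strongly a gene is expressed in one cell type relative to the rest of
#' the compendium.  Values are assumed to be on a log scale, hence
#' subtraction rather than division.
#'
#' @param m reference expression matrix (genes x cell-type columns), at
#'   least two columns.
#' @return matrix of the same shape with row medians exactly zero.
#' @export
median_normalize <- function(m) {
  if (ncol(m) < 2)
    stop2("relative expression is undefined for a single-column matrix")
  keep_mode(m - apply(m, 1, median), m)
}

#' Z-transform each column
#'
#' Centers and scales every column to mean zero and unit sample standard
#' deviation (denominator n - 1), so each cell type's relative expression
#' values follow an approximately standard normal distribution.
#'
#' @param m numeric matrix; every column must have nonzero variance.
#' @return matrix of column z-scores.
#' @export
z_transform_columns <- function(m) {
  sds <- apply(m, 2, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(m)[which(sds == 0 | !is.finite(sds))]
    stop2("zero-variance column(s): ", paste(head(bad, 5), collapse = ", "))
  }
  out <- scale(m, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  keep_mode(out, m)
}

#' Replicate maps
#'
#' A replicate map assigns every column of a reference matrix to exactly
#' one cell type.  It may be given as a named list (cell type -> character
#' vector of column labels) or a two-column data frame with columns
#' `column_id` and `cell_type`; `infer_replicate_map()` builds one from
#' column labels by stripping a trailing replicate suffix (default `#1`,
#' `#2`, ...).
#'
#' @param x a named list or a `column_id`/`cell_type` data frame.
#' @return named list mapping cell type to its column labels, in first-
#'   appearance order.
#' @export
as_replicate_map <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("column_id", "cell_type") %in% names(x)))
      stop_invalid("replicate map needs 'column_id' and 'cell_type' columns")
    x <- split(as.character(x$column_id),
               factor(x$cell_type, levels = unique(x$cell_type)))
  }
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop_invalid("replicate map must be a named list or a data frame")
  if (any(lengths(x) == 0))
    stop_invalid("replicate map contains an empty cell-type group")
  cols <- unlist(x, use.names = FALSE)
  if (anyDuplicated(cols))
    stop_invalid("column(s) assigned to more than one cell type: ",
                 paste(head(unique(cols[duplicated(cols)]), 5), collapse = ", "))
  lapply(x, as.character)
}

#' @rdname as_replicate_map
#' @param column_ids character vector of column labels.
#' @param pattern regular expression for the trailing replicate suffix.
#' @export
infer_replicate_map <- function(column_ids, pattern = "#\\d+$") {
  ct <- sub(pattern, "", column_ids)
  split(column_ids, factor(ct, levels = unique(ct)))
}

#' Collapse replicate arrays into one column per cell type
#'
#' Averages the z-scores of replicate columns belonging to the same cell
#' type, then re-z-transforms each collapsed column so every cell type is
#' again on a standard-normal scale.
#'
#' @param m z-transformed reference matrix.
#' @param reps replicate map covering every column of `m` exactly once
#'   (see [as_replicate_map()]).
#' @return matrix with one column per cell type, each with mean 0 and unit
#'   sample sd.
#' @export
collapse_replicates <- function(m, reps) {
  reps <- as_replicate_map(reps)
  cols <- unlist(reps, use.names = FALSE)
  missing <- setdiff(cols, colnames(m))
  if (length(missing))
    stop2("replicate map references absent column(s): ",
          paste(head(missing, 5), collapse = ", "))
  uncovered <- setdiff(colnames(m), cols)
  if (length(uncovered))
    stop2("column(s) not covered by the replicate map: ",
          paste(head(uncovered, 5), collapse = ", "))
  out <- vapply(reps, function(cc) rowMeans(m[, cc, drop = FALSE]),
                numeric(nrow(m)))
  dimnames(out) <- list(rownames(m), names(reps))
  keep_mode(z_transform_columns(out), m)
}

#' Split z-scores into up- and down-regulated subsets
#'
#' The up subset keeps positive z-scores and zeroes the rest; the down
#' subset keeps negative z-scores and zeroes the rest, so that
#' `up + down` reconstructs the input exactly.
#'
#' @param z collapsed z-score matrix.
#' @return list with elements `up` and `down`.
#' @export
split_up_down <- function(z) {
  list(up = pmax(z, 0), down = pmin(z, 0))
}

#' Convert split z-scores into lineage weight vectors
#'
#' Nonzero entries become `-log10` of a one-sided standard-normal tail
#' probability (upper tail for the up subset, lower tail for the down
#' subset), so strongly differential genes carry heavy weight; entries
#' zeroed by [split_up_down()] carry weight 0.  Transformed values above
#' `trim` are capped, and all weights are finally divided by a single
#' maximum so they lie in [0, 1].  Down-subset weights are stored as
#' positive magnitudes; direction is carried by the subset, not the sign.
#'
#' @param up,down matrices from [split_up_down()].
#' @param trim cap on the `-log10(p)` scale before scaling (default 10,
#'   reached near |z| = 6.4).
#' @param scale `"global"` (one maximum across both subsets and all cell
#'   types, the default) or `"per_celltype"` (each cell type's up/down
#'   pair scaled by its own maximum).
#' @return object of class `lineage_weights` with fields `gene_ids`,
#'   `cell_types`, `up`, `down` (weight matrices in [0, 1]), `scale_max`.
#' @export
weights_from_z <- function(up, down, trim = 10,
                           scale = c("global", "per_celltype")) {
  scale <- match.arg(scale)
  if (!identical(dim(up), dim(down)))
    stop2("up and down matrices must have identical shape")
  wu <- matrix(0, nrow(up), ncol(up), dimnames = dimnames(up))
  wd <- wu
  pos <- up > 0
  neg <- down < 0
  wu[pos] <- -log10(pnorm(up[pos], lower.tail = FALSE))
  wd[neg] <- -log10(pnorm(down[neg]))
  wu <- pmin(wu, trim)
  wd <- pmin(wd, trim)
  if (scale == "global") {
    smax <- max(wu, wd)
    if (smax <= 0)
      stop2("no differentially expressed genes: all weights are zero")
    wu <- wu / smax
    wd <- wd / smax
  } else {
    smax <- pmax(apply(wu, 2, max), apply(wd, 2, max))
    if (any(smax <= 0))
      stop2("cell type(s) without any differential gene: ",
            paste(head(colnames(up)[smax <= 0], 5), collapse = ", "))
    wu <- sweep(wu, 2, smax, "/")
    wd <- sweep(wd, 2, smax, "/")
  }
  structure(
    list(gene_ids = rownames(up), cell_types = colnames(up),
         up = wu, down = wd, scale_max = smax, trim = trim, scale = scale),
    class = "lineage_weights"
  )
}

#' @export
print.lineage_weights <- function(x, ...) {
  cat("Lineage weight set: ", length(x$gene_ids), " genes x ",
      length(x$cell_types), " cell types (", x$scale,
      " scaling, trim = ", x$trim, ")\n", sep = "")
  invisible(x)
}

#' Build lineage weights from a raw reference compendium
#'
#' Runs the full five-step preparation: (i) median normalization across
#' cell types, (ii) column z-transformation with replicate collapsing and
#' re-z-transformation, (iii) up/down splitting, (iv) `-log10` tail-
#' probability weighting with outlier trimming, (v) scaling to [0, 1].
#'
#' @param m raw reference matrix (genes x arrays), `reference` channel
#'   mode, log-scale intensities.
#' @param replicate_map optional replicate map; when `NULL`, replicate
#'   groups are inferred from column labels via `replicate_pattern`.
#' @param replicate_pattern suffix regex for [infer_replicate_map()].
#' @inheritParams weights_from_z
#' @return a `lineage_weights` object.
#' @examples
#' sim <- simulate_lineages(sim_config(n_genes = 200, n_celltypes = 4,
#'                                     module_size = 10, seed = 1))
#' w <- build_lineage_weights(sim$expr, sim$replicate_map)
#' w
#' @export
build_lineage_weights <- function(m, replicate_map = NULL, trim = 10,
                                  scale = c("global", "per_celltype"),
                                  replicate_pattern = "#\\d+$") {
  if (is.null(replicate_map))
    replicate_map <- infer_replicate_map(colnames(m), replicate_pattern)
  z <- z_transform_columns(median_normalize(m))
  z <- collapse_replicates(z, replicate_map)
  ud <- split_up_down(z)
  weights_from_z(ud$up, ud$down, trim = trim, scale = scale)
}
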