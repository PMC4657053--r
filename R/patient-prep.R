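#' Collapse probesets to genes
#'
#' Genes measured by several probesets are represented by the probeset
#' with the highest average intensity across all samples; unmapped
#' probesets are dropped.  Ties in the mean are broken by input row order.
#'
#' @param values numeric matrix with probeset identifiers as row names.
#' @param probeset_to_gene mapping from probeset to gene symbol: a named
#'   character vector (names are probesets) or a data frame with columns
#'   `probeset` and `gene`.
#' @return expression matrix with one row per gene, rows ordered by first
#'   appearance of each gene among the mapped probesets.
#' @export
collapse_probesets <- function(values, probeset_to_gene) {
  if (is.data.frame(probeset_to_gene)) {
    if (!all(c("probeset", "gene") %in% names(probeset_to_gene)))
      stop_invalid("probeset map needs 'probeset' and 'gene' columns")
    probeset_to_gene <- setNames(as.character(probeset_to_gene$gene),
                                 as.character(probeset_to_gene$probeset))
  }
  if (length(probeset_to_gene) == 0)
    stop2("empty probeset-to-gene mapping")
  ids <- rownames(values)
  gene <- probeset_to_gene[ids]
  keep <- which(!is.na(gene) & nzchar(gene))
  if (length(keep) == 0)
    stop2("no probeset maps to a gene symbol")
  gene <- as.character(gene[keep])
  means <- rowMeans(values[keep, , drop = FALSE])
  gf <- factor(gene, levels = unique(gene))
  pick <- vapply(split(seq_along(keep), gf),
                 function(i) i[which.max(means[i])], integer(1))
  out <- values[keep[pick], , drop = FALSE]
  rownames(out) <- levels(gf)
  keep_mode(out, values)
}

#' Prepare one-channel patient intensities
#'
#' Absolute intensities are log2-transformed (with a +1 pseudocount to
#' guard zeros) and median-normalized across samples per gene, so that
#' each value reflects a patient's expression relative to the cohort.
#'
#' @param m non-negative one-channel intensity matrix (genes x patients).
#' @return matrix of relative log2 expression with row medians zero and
#'   channel mode `one_channel`.
#' @export
prepare_one_channel <- function(m) {
  if (any(m < 0, na.rm = TRUE))
    stop2("one-channel intensities must be non-negative")
  x <- log2(m + 1)
  out <- x - apply(x, 1, median, na.rm = TRUE)
  attr(out, "channel_mode") <- "one_channel"
  out
}

#' Prepare two-channel patient log-ratios
#'
#' Two-channel values are already relative log-ratios and pass through
#' unchanged.  Genes with missing values are not imputed; they are dropped
#' per patient at ranking time.
#'
#' @param m two-channel log-ratio matrix.
#' @return `m` with channel mode `two_channel`.
#' @export
prepare_two_channel <- function(m) {
  attr(m, "channel_mode") <- "two_channel"
  m
}

#' @rdname prepare_two_channel
#' @param channel_mode `"one_channel"` or `"two_channel"`; defaults to the
#'   matrix's own channel attribute.
#' @export
prepare_patients <- function(m, channel_mode = NULL) {
  channel_mode <- channel_mode %||% channel_mode(m)
  switch(channel_mode,
         one_channel = prepare_one_channel(m),
         two_channel = prepare_two_channel(m),
         stop2("patient data must be 'one_channel' or 'two_channel', got '",
               channel_mode, "'"))
}

#' Harmonize gene symbols between reference weights and patient data
#'
#' Restricts a lineage weight set and a patient matrix to their common
#' genes under case-insensitive symbol matching (murine Title-case vs
#' human UPPER-case), returning both in the same gene order.
#'
#' @param ref a `lineage_weights` object.
#' @param pat patient expression matrix.
#' @return list with elements `weights` and `patients`, row-aligned.
#' @export
harmonize_genes <- function(ref, pat) {
  if (!inherits(ref, "lineage_weights"))
    stop2("'ref' must be a lineage_weights object")
  rk <- toupper(ref$gene_ids)
  pk <- toupper(rownames(pat))
  ri <- which(rk %in% pk)
  if (length(ri) == 0) {
    stop2("no genes shared between reference and patient data; ",
          "unmatched reference symbols include: ",
          paste(head(ref$gene_ids, 5), collapse = ", "),
          "; unmatched patient symbols include: ",
          paste(head(rownames(pat), 5), collapse = ", "))
  }
  pi <- match(rk[ri], pk)
  w <- ref
  w$gene_ids <- ref$gene_ids[ri]
  w$up <- ref$up[ri, , drop = FALSE]
  w$down <- ref$down[ri, , drop = FALSE]
  p <- pat[pi, , drop = FALSE]
  attr(p, "channel_mode") <- attr(pat, "channel_mode")
  list(weights = w, patients = p)
}

#' Rank a patient's genes by decreasing expression
#'
#' Sorts one patient's genes by expression, highest first, with ties kept
#' in input gene order (stable sort).  Genes with missing values for that
#' patient are dropped from the ranking.
#'
#' @param pat patient expression matrix.
#' @param patient_id column label of the patient.
#' @return object of class `patient_ranking` with fields `patient_id`,
#'   `genes`, `values` (non-increasing).
#' @export
rank_patient <- function(pat, patient_id) {
  if (!patient_id %in% colnames(pat))
    stop2("unknown patient id: '", patient_id, "'")
  v <- pat[, patient_id]
  keep <- !is.na(v)
  v <- v[keep]
  g <- rownames(pat)[keep]
  if (length(v) == 0)
    stop2("patient '", patient_id, "' has no non-missing values")
  ord <- order(v, decreasing = TRUE, method = "radix")
  structure(list(patient_id = patient_id, genes = g[ord], values = v[ord]),
            class = "patient_ranking")
}

#' @export
print.patient_ranking <- function(x, ...) {
  cat("Ranking for patient '", x$patient_id, "': ", length(x$genes),
      " genes, top = ", x$genes[1], "\n", sep = "")
  invisible(x)
}
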