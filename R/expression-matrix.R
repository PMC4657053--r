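#' Construct a validated expression matrix
#'
#' The package carries expression data as plain numeric matrices with gene
#' symbols as row names and sample (or cell-type/array) labels as column
#' names, plus a `channel_mode` attribute recording how the values are to
#' be interpreted: `"reference"` for lineage compendium intensities,
#' `"one_channel"` for absolute single-channel intensities, and
#' `"two_channel"` for log-ratio values that are already relative.
#'
#' @param values numeric matrix, genes in rows (unique non-empty row
#'   names), samples in columns (unique column names).
#' @param channel_mode one of `"reference"`, `"one_channel"`,
#'   `"two_channel"`.
#' @param allow_missing if `TRUE`, `NA` entries are tolerated (they are
#'   dropped per patient at ranking time); infinite values are never
#'   allowed.
#' @return the validated matrix with its `channel_mode` attribute set.
#' @examples
#' m <- expression_matrix(
#'   matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2"))),
#'   channel_mode = "two_channel"
#' )
#' channel_mode(m)
#' @export
expression_matrix <- function(values,
                              channel_mode = c("reference", "one_channel",
                                               "two_channel"),
                              allow_missing = FALSE) {
  channel_mode <- match.arg(channel_mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop_invalid("expression values must be a numeric matrix")
  ids <- rownames(values)
  if (is.null(ids) || any(!nzchar(ids)))
    stop_invalid("all gene rows must carry a non-empty identifier")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_invalid("duplicate gene identifiers: ",
                 paste(head(dup, 5), collapse = ", "))
  }
  if (is.null(colnames(values)) || any(!nzchar(colnames(values))))
    stop_invalid("all columns must carry a non-empty label")
  if (anyDuplicated(colnames(values)))
    stop_invalid("duplicate column labels")
  if (any(is.infinite(values)))
    stop_invalid("expression values must be finite")
  if (!allow_missing && anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop_invalid("missing value at gene '", ids[bad[1]], "', column '",
                 colnames(values)[bad[2]], "'")
  }
  attr(values, "channel_mode") <- channel_mode
  values
}

#' @rdname expression_matrix
#' @param m an expression matrix.
#' @export
channel_mode <- function(m) attr(m, "channel_mode") %||% "reference"

#' @rdname expression_matrix
#' @param value replacement channel mode.
#' @export
`channel_mode<-` <- function(m, value) {
  value <- match.arg(value, c("reference", "one_channel", "two_channel"))
  attr(m, "channel_mode") <- value
  m
}

# carry channel_mode (and nothing else) through matrix-producing transforms
keep_mode <- function(out, m) {
  attr(out, "channel_mode") <- attr(m, "channel_mode")
  out
}
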