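# number of leading '#' comment lines at the top of a file (only leading
# lines count: '#' is legal inside column labels such as replicate names)
leading_comments <- function(path, max_scan = 50) {
  first <- readLines(path, n = max_scan)
  n <- 0L
  for (ln in first) {
    if (!startsWith(ln, "#")) break
    n <- n + 1L
  }
  n
}

#' Read an expression matrix from TSV
#'
#' Expects a header row and identifiers in the first column; leading lines
#' starting with `#` are skipped.  Ragged rows, non-numeric cells and
#' duplicate identifiers are rejected with their location.  Decimal
#' parsing is locale-independent (C numeric conversion).
#'
#' @param path TSV file.
#' @param channel_mode channel mode to stamp on the result.
#' @param allow_missing allow `NA` cells (patient matrices only).
#' @return a validated [expression_matrix()].
#' @export
read_expression_tsv <- function(path,
                                channel_mode = c("reference", "one_channel",
                                                 "two_channel"),
                                allow_missing = FALSE) {
  channel_mode <- match.arg(channel_mode)
  if (!file.exists(path))
    stop_invalid("file not found: '", path, "'")
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", comment.char = "",
                   skip = leading_comments(path), fill = FALSE,
                   quote = "")
  if (ncol(df) < 2)
    stop_invalid("'", path, "' needs an identifier column plus at least ",
                 "one data column")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1]
    stop_invalid("duplicate identifier '", d, "' at data row(s) ",
                 paste(which(ids == d), collapse = ", "), " of '", path, "'")
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- is.na(vals) & !(is.na(raw) | raw %in% c("NA", "NaN", ""))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop_invalid("non-numeric value '", raw[w[1], w[2]], "' at data row ",
                 w[1], ", column '", colnames(df)[-1][w[2]], "' of '",
                 path, "'")
  }
  dimnames(vals) <- list(ids, colnames(df)[-1])
  expression_matrix(vals, channel_mode = channel_mode,
                    allow_missing = allow_missing)
}

#' Write an expression matrix to TSV
#'
#' Genes as rows, a `gene_id` identifier column first.  Formatting uses
#' `%.<digits>g` and is deterministic, so identical matrices produce
#' byte-identical files.
#'
#' @param m expression matrix (or any numeric matrix with dimnames).
#' @param path output file.
#' @param digits significant digits (default 7).
#' @param id_name header label for the identifier column.
#' @param comments character vector written as leading `# ` lines.
#' @return invisibly, `path`.
#' @export
write_expression_tsv <- function(m, path, digits = 7, id_name = "gene_id",
                                 comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  writeLines(paste(c(id_name, colnames(m)), collapse = "\t"), con)
  fmt <- paste0("%.", digits, "g")
  body <- apply(m, 1, function(row) {
    paste(ifelse(is.na(row), "NA", sprintf(fmt, row)), collapse = "\t")
  })
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample_id`, `time`, `event`; any further columns are
#' kept as optional covariates (missing covariate cells allowed).
#'
#' @param path TSV file.
#' @return a validated [as_clinical_table()] data frame.
#' @export
read_clinical_tsv <- function(path) {
  if (!file.exists(path))
    stop_invalid("file not found: '", path, "'")
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "", skip = leading_comments(path),
                   stringsAsFactors = FALSE, quote = "")
  as_clinical_table(df)
}

#' Read a replicate map from TSV
#'
#' Two-column TSV with header `column_id`, `cell_type`.
#'
#' @param path TSV file.
#' @return named list, see [as_replicate_map()].
#' @export
read_replicate_map <- function(path) {
  if (!file.exists(path))
    stop_invalid("file not found: '", path, "'")
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "", skip = leading_comments(path),
                   stringsAsFactors = FALSE, quote = "")
  as_replicate_map(df)
}

#' Serialize / deserialize a lineage weight set
#'
#' A weight set is stored as a directory holding `up_weights.tsv`,
#' `down_weights.tsv` and a `weights_meta.json` sidecar recording the
#' scaling maximum, trim threshold and scaling scope.
#'
#' @param w a `lineage_weights` object.
#' @param dir directory (created if absent).
#' @param digits significant digits for the TSVs.
#' @return `write_lineage_weights()` invisibly returns `dir`;
#'   `read_lineage_weights()` returns the `lineage_weights` object.
#' @export
write_lineage_weights <- function(w, dir, digits = 10) {
  stopifnot(inherits(w, "lineage_weights"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop2("cannot create directory '", dir, "'")
  write_expression_tsv(w$up, file.path(dir, "up_weights.tsv"),
                       digits = digits)
  write_expression_tsv(w$down, file.path(dir, "down_weights.tsv"),
                       digits = digits)
  jsonlite::write_json(
    list(scale_max = w$scale_max, trim = w$trim, scale = w$scale,
         n_genes = length(w$gene_ids), cell_types = w$cell_types),
    file.path(dir, "weights_meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_lineage_weights
#' @export
read_lineage_weights <- function(dir) {
  up_path <- file.path(dir, "up_weights.tsv")
  if (!file.exists(up_path))
    stop_invalid("'", dir, "' does not contain a serialized weight set")
  up <- unclass(read_expression_tsv(up_path))
  down <- unclass(read_expression_tsv(file.path(dir, "down_weights.tsv")))
  attr(up, "channel_mode") <- attr(down, "channel_mode") <- NULL
  meta <- jsonlite::read_json(file.path(dir, "weights_meta.json"),
                              simplifyVector = TRUE)
  structure(
    list(gene_ids = rownames(up), cell_types = colnames(up),
         up = up, down = down, scale_max = meta$scale_max,
         trim = meta$trim, scale = meta$scale),
    class = "lineage_weights"
  )
}
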