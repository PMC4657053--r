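#' Pipeline run configuration
#'
#' Validates paths and parameters for [run_pipeline()] up front, so a
#' missing input is reported before any computation starts.  Exactly one
#' of `lineages` (a raw reference TSV, prepared on the fly) or
#' `weights_dir` (a serialized weight set) must be given.
#'
#' @param patients path to the patient expression TSV (genes or probesets
#'   x patients).
#' @param out_dir output directory (created by [run_pipeline()]).
#' @param channel_mode `"one_channel"` or `"two_channel"`.
#' @param lineages path to a raw reference compendium TSV.
#' @param weights_dir path to a serialized weight set (see
#'   [write_lineage_weights()]).
#' @param replicate_map optional path to a replicate-map TSV; otherwise
#'   replicate groups are inferred from column labels.
#' @param clinical optional path to a clinical TSV; enables the survival-
#'   association stage.
#' @param covariates covariate columns for an additional adjusted Cox fit
#'   of survival-associated cell types.
#' @param n_perm permutations per score (default 1000).
#' @param seed global RNG seed, recorded in every artifact.
#' @param cores workers for scoring.
#' @param digits significant digits in output TSVs.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(patients, out_dir,
                       channel_mode = c("two_channel", "one_channel"),
                       lineages = NULL, weights_dir = NULL,
                       replicate_map = NULL, clinical = NULL,
                       covariates = character(), n_perm = 1000,
                       seed = 17L, cores = 1L, digits = 7) {
  channel_mode <- match.arg(channel_mode)
  if (is.null(lineages) == is.null(weights_dir))
    stop_invalid("give exactly one of 'lineages' or 'weights_dir'")
  for (p in c(patients, lineages, replicate_map, clinical))
    if (!file.exists(p))
      stop_invalid("input path does not exist: '", p, "'")
  if (!is.null(weights_dir) && !dir.exists(weights_dir))
    stop_invalid("weights directory does not exist: '", weights_dir, "'")
  if (length(covariates) && is.null(clinical))
    stop_invalid("covariates requested but no clinical table given")
  if (n_perm < 1)
    stop_invalid("n_perm must be at least 1")
  structure(
    list(patients = patients, out_dir = out_dir,
         channel_mode = channel_mode, lineages = lineages,
         weights_dir = weights_dir, replicate_map = replicate_map,
         clinical = clinical, covariates = covariates,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         cores = as.integer(cores), digits = digits),
    class = "run_config"
  )
}

# md5 of the canonical JSON rendering of the configuration; the output
# directory is excluded so reruns into different locations stay
# byte-identical
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  x <- unclass(cfg)
  x$out_dir <- NULL
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full scoring and association pipeline
#'
#' Chains the whole analysis: weight preparation (or loading), patient
#' preparation, gene harmonization, LSS scoring, and — when a clinical
#' table is configured — the univariate Cox screen with BH adjustment,
#' an optional covariate-adjusted fit for cell types passing `adj_p <
#' 0.05`, and a Kaplan-Meier export for the top-ranked cell type.  All
#' outputs carry the run-manifest hash as a leading comment line, and a
#' `manifest.json` records the package version, seed and configuration:
#' identical manifests imply identical outputs.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the artifact paths and the in-memory
#'   `scores` and `associations` objects.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  clin <- if (!is.null(cfg$clinical)) read_clinical_tsv(cfg$clinical)
  if (!dir.exists(cfg$out_dir) &&
      !dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE))
    stop2("cannot create output directory '", cfg$out_dir, "'")
  hash <- config_hash(cfg)
  stamp <- paste0("manifest: ", hash)

  weights <- if (!is.null(cfg$weights_dir)) {
    read_lineage_weights(cfg$weights_dir)
  } else {
    ref <- read_expression_tsv(cfg$lineages, channel_mode = "reference")
    rmap <- if (!is.null(cfg$replicate_map))
      read_replicate_map(cfg$replicate_map)
    build_lineage_weights(ref, replicate_map = rmap)
  }
  pat <- read_expression_tsv(cfg$patients, channel_mode = cfg$channel_mode,
                             allow_missing = TRUE)
  pat <- prepare_patients(pat)
  scores <- score_all(weights, pat, n_perm = cfg$n_perm, seed = cfg$seed,
                      cores = cfg$cores)
  wide <- lss_wide(scores)

  paths <- c(manifest = file.path(cfg$out_dir, "manifest.json"),
             lss_long = file.path(cfg$out_dir, "lss_long.tsv"),
             lss_matrix = file.path(cfg$out_dir, "lss_matrix.tsv"))
  write_tsv_df(scores, paths["lss_long"], digits = cfg$digits,
               comments = stamp)
  write_expression_tsv(wide, paths["lss_matrix"], digits = cfg$digits,
                       id_name = "patient_id", comments = stamp)

  assoc <- NULL
  if (!is.null(clin)) {
    assoc <- cox_univariate_all(wide, clin)
    assoc <- assoc[order(assoc$adj_p), ]
    if (length(cfg$covariates)) {
      hits <- assoc$cell_type[!is.na(assoc$adj_p) & assoc$adj_p < 0.05]
      assoc$mv_coef <- assoc$mv_hr <- assoc$mv_wald_p <- NA_real_
      for (ct in hits) {
        mv <- cox_multivariate(setNames(wide[, ct], rownames(wide)), clin,
                               covariates = cfg$covariates)
        i <- match(ct, assoc$cell_type)
        assoc$mv_coef[i] <- mv$coef
        assoc$mv_hr[i] <- mv$hr
        assoc$mv_wald_p[i] <- mv$wald_p
      }
    }
    paths["associations"] <- file.path(cfg$out_dir, "associations.tsv")
    write_tsv_df(assoc, paths["associations"], digits = cfg$digits,
                 comments = stamp)
    top <- assoc$cell_type[which.min(assoc$adj_p)]
    km <- tryCatch({
      di <- dichotomize_lss(setNames(wide[, top], rownames(wide)))
      km_logrank(di$labels, clin)
    }, error = function(e) {
      warning("Kaplan-Meier export skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(km)) {
      paths["km_curves"] <- file.path(cfg$out_dir, "km_curves.tsv")
      write_tsv_df(km$curves, paths["km_curves"], digits = cfg$digits,
                   comments = c(stamp,
                                paste0("cell_type: ", top),
                                paste0("logrank_p: ",
                                       format(km$logrank_p, digits = 6))))
    }
  }

  jsonlite::write_json(
    list(package = "lineagescore",
         version = as.character(utils::packageVersion("lineagescore")),
         config = unclass(cfg), config_hash = hash,
         n_patients = nrow(wide), n_celltypes = ncol(wide),
         artifacts = as.list(basename(paths))),
    paths["manifest"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(paths = paths, scores = scores, associations = assoc,
                 manifest_hash = hash))
}

# deterministic TSV writer for result data frames
write_tsv_df <- function(df, path, digits = 7, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  df <- as.data.frame(df)
  fmt <- paste0("%.", digits, "g")
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), "NA", sprintf(fmt, df[[j]]))
  }
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}
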