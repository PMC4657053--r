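#' Foreground and background running sums
#'
#' Given a patient's ranked expression magnitudes and a cell type's weight
#' vector aligned to that ranking, the foreground function accumulates
#' expression weighted by the lineage weights and the background function
#' accumulates expression weighted by the complementary weights:
#' \deqn{f(i) = \sum_{j \le i} |g_j| w_j / \sum_j |g_j| w_j, \qquad
#'       b(i) = \sum_{j \le i} |g_j| (1 - w_j) / \sum_j |g_j| (1 - w_j).}
#' Both are non-decreasing and reach 1 at the last gene.  Expression
#' enters through its magnitude; for two-channel (log-ratio) data the sign
#' information is carried entirely by rank position.
#'
#' @param ranking a `patient_ranking` from [rank_patient()], or a numeric
#'   vector already sorted in decreasing order.
#' @param w weight vector in [0, 1], aligned to the ranking (element j
#'   weights the j-th ranked gene).
#' @return object of class `running_sums` with fields `f` and `b`.
#' @examples
#' rs <- running_sums(c(4, 3, 2, 1), c(1, 1, 0, 0))
#' rs$f  # 4/7, 1, 1, 1
#' pre_lss(rs)
#' @export
running_sums <- function(ranking, w) {
  v <- if (inherits(ranking, "patient_ranking")) ranking$values else ranking
  if (length(w) != length(v))
    stop2("weight vector length must match the ranking length")
  if (any(w < 0 | w > 1))
    stop2("weights must lie in [0, 1]")
  a <- abs(v)
  totF <- sum(a * w)
  totB <- sum(a * (1 - w))
  if (totF <= 0 || totB <= 0)
    stop2("degenerate weights: foreground or background mass is zero")
  structure(list(f = cumsum(a * w) / totF, b = cumsum(a * (1 - w)) / totB),
            class = "running_sums")
}

#' Pre-normalization LSS: signed maximum deviation
#'
#' Computes `d(i) = f(i) - b(i)`, takes the largest positive deviation
#' (concordance with the weighted direction) and the largest negative
#' deviation, and returns whichever has the larger magnitude (the positive
#' branch wins exact ties).  Always lies in [-1, 1].
#'
#' @param rs a `running_sums` object.
#' @return the signed pre-LSS.
#' @export
pre_lss <- function(rs) {
  d <- rs$f - rs$b
  plus <- max(0, max(d))
  minus <- min(0, min(d))
  if (plus >= -minus) plus else minus
}

#' Permutation null for the pre-LSS
#'
#' Shuffles the alignment between the weight vector and the ranked gene
#' list `n_perm` times, recomputes the pre-LSS for each shuffle, and
#' returns the mean of its absolute value — the normalizing constant that
#' turns a pre-LSS into an LSS.
#'
#' @inheritParams running_sums
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed; fixed seed gives an identical value on repeat.
#' @return mean absolute permuted pre-LSS (non-negative).
#' @export
permutation_null <- function(ranking, w, n_perm = 1000, seed = 1L) {
  if (n_perm < 1)
    stop2("n_perm must be at least 1")
  v <- if (inherits(ranking, "patient_ranking")) ranking$values else ranking
  if (length(w) != length(v))
    stop2("weight vector length must match the ranking length")
  set.seed(seed)
  out <- null_mean_abs_cpp(abs(v), matrix(w, ncol = 1), n_perm)[1]
  if (is.na(out))
    stop2("degenerate weights: permutation null is undefined")
  out
}

#' Normalize pre-LSS values and combine per channel mode
#'
#' Divides the up- and down-subset pre-LSS by their permutation-null mean
#' magnitudes and combines them: for two-channel data
#' `LSS = LSS_up - LSS_dn`; for one-channel data `LSS = LSS_up` (the down
#' subset is dominated by cross-hybridization noise on absolute-intensity
#' platforms).  A pre-LSS of exactly 0 with a zero null mean — as produced
#' by a constant weight vector, where foreground and background coincide —
#' normalizes to 0; a zero null mean with nonzero pre-LSS is an error.
#'
#' @param pLSS_up,pLSS_dn pre-normalization deviations for the up/down
#'   weight subsets.
#' @param null_up,null_dn mean absolute permuted deviations.
#' @param channel_mode `"one_channel"` or `"two_channel"`.
#' @return list with `LSS_up`, `LSS_dn`, `LSS`.
#' @export
normalize_and_combine <- function(pLSS_up, pLSS_dn, null_up, null_dn,
                                  channel_mode = c("two_channel",
                                                   "one_channel")) {
  channel_mode <- match.arg(channel_mode)
  norm1 <- function(p, m, lab) {
    if (m > 0) return(p / m)
    if (p == 0) return(0)
    stop2("non-positive null mean for the ", lab, " subset")
  }
  up <- norm1(pLSS_up, null_up, "up")
  dn <- norm1(pLSS_dn, null_dn, "down")
  list(LSS_up = up, LSS_dn = dn,
       LSS = if (channel_mode == "two_channel") up - dn else up)
}

#' Score every patient against every cell type
#'
#' The core scoring loop: for each patient, genes are ranked by decreasing
#' expression; for each cell type, the pre-LSS is computed against the up
#' and down weight subsets and normalized by its own permutation null; the
#' normalized scores are combined according to the channel mode.  Each
#' patient draws permutations from an RNG stream derived from the global
#' seed and the patient id, so results are independent of patient column
#' order and of execution order under parallel evaluation.
#'
#' @param weights a `lineage_weights` object.
#' @param patients prepared patient expression matrix (see
#'   [prepare_patients()]).
#' @param channel_mode `"one_channel"` or `"two_channel"`; defaults to the
#'   patient matrix's channel attribute.
#' @param n_perm permutations per (patient, cell type, subset); default
#'   1000.
#' @param seed global RNG seed, recorded in every output row.
#' @param cores workers for [parallel::mclapply()]; 1 (the default) runs
#'   serially.
#' @param harmonize harmonize gene symbols first (default `TRUE`); set
#'   `FALSE` only if inputs are already row-aligned.
#' @return data frame of class `lss_result`, one row per (patient, cell
#'   type): `patient_id`, `cell_type`, `pLSS_up`, `pLSS_dn`,
#'   `null_mean_abs_up`, `null_mean_abs_dn`, `LSS_up`, `LSS_dn`, `LSS`,
#'   `n_perm`, `seed`.
#' @examples
#' cfg <- sim_config(n_genes = 300, n_celltypes = 4, module_size = 15,
#'                   n_patients = 6, seed = 7)
#' sim <- simulate_lineages(cfg)
#' w <- build_lineage_weights(sim$expr, sim$replicate_map)
#' coh <- simulate_cohort(cfg, sim)
#' res <- score_all(w, coh$expr, n_perm = 50, seed = 7)
#' head(res)
#' @export
score_all <- function(weights, patients, channel_mode = NULL,
                      n_perm = 1000, seed = 1L, cores = 1L,
                      harmonize = TRUE) {
  if (!inherits(weights, "lineage_weights"))
    stop2("'weights' must be a lineage_weights object")
  channel_mode <- channel_mode %||% attr(patients, "channel_mode")
  if (is.null(channel_mode) ||
      !channel_mode %in% c("one_channel", "two_channel"))
    stop2("channel_mode must be 'one_channel' or 'two_channel'")
  if (n_perm < 1) stop2("n_perm must be at least 1")
  if (harmonize) {
    h <- harmonize_genes(weights, patients)
    weights <- h$weights
    patients <- h$patients
  } else if (nrow(patients) != length(weights$gene_ids)) {
    stop2("with harmonize = FALSE, patient rows must align with weights")
  }
  gkey <- toupper(weights$gene_ids)
  pids <- colnames(patients)
  score_one <- function(pid) {
    r <- rank_patient(patients, pid)
    a <- abs(r$values)
    n <- length(a)
    ri <- match(toupper(r$genes), gkey)
    Wu <- weights$up[ri, , drop = FALSE]
    Wd <- weights$down[ri, , drop = FALSE]
    pup <- prelss_cols_cpp(a, Wu)
    pdn <- prelss_cols_cpp(a, Wd)
    bad <- is.na(pup) | is.na(pdn)
    if (any(bad))
      stop2("degenerate weights for patient '", pid, "', cell type(s): ",
            paste(head(weights$cell_types[bad], 5), collapse = ", "))
    set.seed(seed_for(seed, pid))
    nup <- null_mean_abs_cpp(a, Wu, n_perm)
    ndn <- null_mean_abs_cpp(a, Wd, n_perm)
    lss_up <- ifelse(nup > 0, pup / nup, ifelse(pup == 0, 0, NA_real_))
    lss_dn <- ifelse(ndn > 0, pdn / ndn, ifelse(pdn == 0, 0, NA_real_))
    bad <- is.na(lss_up) | is.na(lss_dn)
    if (any(bad))
      stop2("non-positive null mean for patient '", pid,
            "', cell type(s): ",
            paste(head(weights$cell_types[bad], 5), collapse = ", "))
    data.frame(
      patient_id = pid, cell_type = weights$cell_types,
      pLSS_up = pup, pLSS_dn = pdn,
      null_mean_abs_up = nup, null_mean_abs_dn = ndn,
      LSS_up = lss_up, LSS_dn = lss_dn,
      LSS = if (channel_mode == "two_channel") lss_up - lss_dn else lss_up,
      n_perm = n_perm, seed = seed,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  rows <- if (cores > 1L) {
    parallel::mclapply(pids, score_one, mc.cores = cores)
  } else {
    lapply(pids, score_one)
  }
  out <- do.call(rbind, rows)
  attr(out, "channel_mode") <- channel_mode
  class(out) <- c("lss_result", "data.frame")
  out
}

#' Reshape long LSS results to a patients x cell types matrix
#'
#' @param x an `lss_result` data frame from [score_all()].
#' @param value which column to spread (default `"LSS"`).
#' @return numeric matrix, patients in rows, cell types in columns.
#' @export
lss_wide <- function(x, value = "LSS") {
  pids <- unique(x$patient_id)
  cts <- unique(x$cell_type)
  out <- matrix(NA_real_, length(pids), length(cts),
                dimnames = list(pids, cts))
  out[cbind(match(x$patient_id, pids), match(x$cell_type, cts))] <- x[[value]]
  out
}
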