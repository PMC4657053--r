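#' Simulation configuration
#'
#' Defines the synthetic study: a reference compendium of cell types with
#' planted up/down gene modules, and a patient cohort whose expression is
#' a mixture of one planted cell type's profile and background, with
#' survival hazard driven by the per-patient mixing coefficient alpha.
#'
#' Defaults emulate a desk-scale version of a lineage-compendium study:
#' 2000 genes, 20 cell types with 3 replicate arrays each, signature
#' modules of 50 up- and 50 down-regulated genes shifted by 3 noise SDs,
#' a 200-patient two-channel cohort with alpha ~ Beta(2, 2), log-hazard
#' 1.5 per unit alpha on an exponential baseline, and 30% censoring.
#'
#' @param n_genes,n_celltypes,n_replicates compendium dimensions.
#' @param module_size number of up-regulated and of down-regulated genes
#'   per cell type (`2 * module_size <= n_genes`).
#' @param effect_z mean differential shift of module genes, in units of
#'   `noise_sd`.
#' @param noise_sd SD of the log-scale expression noise.
#' @param n_patients cohort size.
#' @param channel_mode `"two_channel"` (log-ratio-like, median-centered
#'   per gene) or `"one_channel"` (absolute intensities).
#' @param alpha_shape1,alpha_shape2 Beta parameters of the per-patient
#'   mixing coefficient alpha in [0, 1].
#' @param beta log-hazard per unit alpha.
#' @param baseline_hazard exponential baseline hazard rate.
#' @param censor_rate target fraction of censored patients, via
#'   independent uniform censoring calibrated by root-finding.
#' @param confounded if `TRUE`, age shifts both alpha and the hazard,
#'   creating a measured confounder for adjustment tests.
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_celltypes = 20, n_replicates = 3,
                       module_size = 50, effect_z = 3, noise_sd = 1,
                       n_patients = 200,
                       channel_mode = c("two_channel", "one_channel"),
                       alpha_shape1 = 2, alpha_shape2 = 2,
                       beta = 1.5, baseline_hazard = 0.1,
                       censor_rate = 0.3, confounded = FALSE, seed = 1L) {
  channel_mode <- match.arg(channel_mode)
  cfg <- list(n_genes = as.integer(n_genes),
              n_celltypes = as.integer(n_celltypes),
              n_replicates = as.integer(n_replicates),
              module_size = as.integer(module_size),
              effect_z = effect_z, noise_sd = noise_sd,
              n_patients = as.integer(n_patients),
              channel_mode = channel_mode,
              alpha_shape1 = alpha_shape1, alpha_shape2 = alpha_shape2,
              beta = beta, baseline_hazard = baseline_hazard,
              censor_rate = censor_rate, confounded = isTRUE(confounded),
              seed = as.integer(seed))
  counts <- c("n_genes", "n_celltypes", "n_replicates", "module_size",
              "n_patients")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1)
      stop2("'", f, "' must be a positive integer")
  if (2L * cfg$module_size > cfg$n_genes)
    stop2("up and down modules cannot fit: need 2 * module_size <= n_genes")
  if (cfg$effect_z <= 0 || cfg$noise_sd <= 0)
    stop2("effect_z and noise_sd must be positive")
  if (cfg$alpha_shape1 <= 0 || cfg$alpha_shape2 <= 0)
    stop2("alpha distribution parameters must be positive")
  if (cfg$baseline_hazard <= 0)
    stop2("baseline_hazard must be positive")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop2("censor_rate must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Simulate a reference lineage compendium
#'
#' Each cell type receives disjoint up- and down-regulated gene modules
#' whose mean is shifted by `+/- effect_z * noise_sd` against a N(0,
#' noise_sd) background; replicate arrays share the cell-type mean with
#' independent noise.  When the gene pool allows, modules are disjoint
#' across cell types as well.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (genes x replicate arrays, `reference` mode,
#'   replicate columns labelled `CT01#1`, ...), `replicate_map`, and
#'   `truth` (module membership per cell type).
#' @export
simulate_lineages <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed_for(cfg$seed, "lineages"))
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  cts <- sprintf("CT%02d", seq_len(cfg$n_celltypes))
  ms <- cfg$module_size
  pool <- sample(genes)
  disjoint <- 2L * ms * cfg$n_celltypes <= cfg$n_genes
  modules_up <- modules_dn <- vector("list", cfg$n_celltypes)
  names(modules_up) <- names(modules_dn) <- cts
  for (k in seq_len(cfg$n_celltypes)) {
    if (disjoint) {
      block <- pool[((k - 1) * 2 * ms + 1):(k * 2 * ms)]
    } else {
      block <- sample(genes, 2 * ms)
    }
    modules_up[[k]] <- sort(block[1:ms])
    modules_dn[[k]] <- sort(block[(ms + 1):(2 * ms)])
  }
  shift <- cfg$effect_z * cfg$noise_sd
  mu <- matrix(0, cfg$n_genes, cfg$n_celltypes,
               dimnames = list(genes, cts))
  for (k in seq_len(cfg$n_celltypes)) {
    mu[modules_up[[k]], k] <- shift
    mu[modules_dn[[k]], k] <- -shift
  }
  cols <- as.vector(t(outer(cts, seq_len(cfg$n_replicates),
                            function(a, b) paste0(a, "#", b))))
  expr <- matrix(rnorm(cfg$n_genes * length(cols), sd = cfg$noise_sd),
                 cfg$n_genes, length(cols),
                 dimnames = list(genes, cols))
  for (j in seq_along(cols)) {
    k <- match(sub("#\\d+$", "", cols[j]), cts)
    expr[, j] <- expr[, j] + mu[, k]
  }
  expr <- expression_matrix(expr, channel_mode = "reference")
  rep_map <- data.frame(column_id = cols,
                        cell_type = sub("#\\d+$", "", cols),
                        stringsAsFactors = FALSE)
  truth <- list(cell_types = cts, modules_up = modules_up,
                modules_dn = modules_dn, mean_profiles = mu,
                seed = cfg$seed)
  list(expr = expr, replicate_map = rep_map, truth = truth)
}

# uniform-censoring horizon such that the expected censored fraction over
# the drawn event times equals the target rate
censor_horizon <- function(t_event, rate) {
  f <- function(tau) mean(pmin(t_event, tau)) / tau - rate
  upper <- 2 * mean(t_event) / rate
  uniroot(f, lower = 1e-9, upper = max(upper, max(t_event)),
          tol = 1e-9)$root
}

#' Simulate a patient cohort tied to a planted cell type
#'
#' Patient i's expression is `alpha_i * mu_planted + noise` where
#' `mu_planted` is the planted cell type's mean differential profile and
#' the background is flat on the log scale; survival time is exponential
#' with hazard `baseline_hazard * exp(beta * alpha_i)` under independent
#' uniform censoring calibrated to the target rate.  Two-channel cohorts
#' are median-centered per gene across patients; one-channel cohorts are
#' exponentiated to positive absolute intensities.  Pseudo-clinical
#' covariates (age, FAB-like subtype, FLT3-like status) are attached; with
#' `confounded = TRUE`, age shifts both alpha and the hazard.
#'
#' @param cfg a [sim_config()].
#' @param lineages output of [simulate_lineages()].
#' @param planted_celltype cell type whose profile drives the cohort;
#'   default: drawn at random under the config seed.
#' @return list with `expr` (genes x patients), `clinical`
#'   (clinical table with `sample_id`, `time`, `event`, `age`, `fab`,
#'   `flt3`) and `truth` (`planted_celltype`, `alpha`, `beta`,
#'   `t_event`, `censor_horizon`).
#' @export
simulate_cohort <- function(cfg, lineages, planted_celltype = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- lineages$truth
  set.seed(seed_for(cfg$seed, "cohort"))
  cts <- truth$cell_types
  planted <- planted_celltype %||% sample(cts, 1)
  if (!planted %in% cts)
    stop2("unknown planted cell type: '", planted, "'")
  n <- cfg$n_patients
  pids <- sprintf("P%04d", seq_len(n))
  age <- rnorm(n, 55, 10)
  z_age <- (age - 55) / 10
  alpha_raw <- rbeta(n, cfg$alpha_shape1, cfg$alpha_shape2)
  alpha <- if (cfg$confounded) {
    plogis(qlogis(pmin(pmax(alpha_raw, 1e-6), 1 - 1e-6)) + 0.8 * z_age)
  } else {
    alpha_raw
  }
  mu <- truth$mean_profiles[, planted]
  expr <- matrix(rnorm(cfg$n_genes * n, sd = cfg$noise_sd),
                 cfg$n_genes, n,
                 dimnames = list(rownames(truth$mean_profiles), pids))
  expr <- expr + outer(mu, alpha)
  if (cfg$channel_mode == "two_channel") {
    expr <- expr - apply(expr, 1, median)
    expr <- expression_matrix(expr, channel_mode = "two_channel")
  } else {
    expr <- expression_matrix(2^(expr + 8), channel_mode = "one_channel")
  }
  log_hr <- cfg$beta * alpha + if (cfg$confounded) 0.5 * z_age else 0
  t_event <- rexp(n, rate = cfg$baseline_hazard * exp(log_hr))
  if (cfg$censor_rate > 0) {
    tau <- censor_horizon(t_event, cfg$censor_rate)
    c_time <- runif(n, 0, tau)
  } else {
    tau <- Inf
    c_time <- rep(Inf, n)
  }
  clinical <- as_clinical_table(data.frame(
    sample_id = pids,
    time = pmin(t_event, c_time),
    event = as.integer(t_event <= c_time),
    age = round(age, 1),
    fab = sample(paste0("M", 0:5), n, replace = TRUE),
    flt3 = ifelse(rbinom(n, 1, 0.3) == 1, "mutated", "wildtype"),
    stringsAsFactors = FALSE
  ))
  truth_out <- list(planted_celltype = planted, alpha = alpha,
                    beta = cfg$beta, t_event = t_event,
                    censor_horizon = tau, seed = cfg$seed)
  list(expr = expr, clinical = clinical, truth = truth_out)
}

#' Write a self-contained fixture bundle
#'
#' Simulates a compendium and cohort and writes them as five plain-text
#' files — `lineages.tsv`, `replicate_map.tsv`, `patients.tsv`,
#' `clinical.tsv`, `truth.json` — re-readable by the package's own
#' readers and usable directly by the command-line pipeline.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if absent).
#' @param digits significant digits for the expression TSVs.
#' @return invisibly, a named character vector of the file paths.
#' @export
write_fixture_bundle <- function(cfg, dir, digits = 6) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop2("cannot create output directory '", dir, "'")
  sim <- simulate_lineages(cfg)
  coh <- simulate_cohort(cfg, sim)
  paths <- c(
    lineages = file.path(dir, "lineages.tsv"),
    replicate_map = file.path(dir, "replicate_map.tsv"),
    patients = file.path(dir, "patients.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_tsv(sim$expr, paths["lineages"], digits = digits)
  utils::write.table(sim$replicate_map, paths["replicate_map"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_tsv(coh$expr, paths["patients"], digits = digits)
  utils::write.table(as.data.frame(coh$clinical), paths["clinical"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(cfg),
         planted_celltype = coh$truth$planted_celltype,
         alpha = coh$truth$alpha,
         censor_horizon = coh$truth$censor_horizon,
         modules_up = sim$truth$modules_up,
         modules_dn = sim$truth$modules_dn),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
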