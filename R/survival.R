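#' Validate a clinical table
#'
#' A clinical table carries one row per sample with at least `sample_id`,
#' `time` (positive, in whatever unit the study uses) and `event`
#' (1 = death observed, 0 = censored).  Any further columns are kept as
#' optional covariates; missing covariate cells are allowed, missing
#' time/event are not.
#'
#' @param x data frame to validate.
#' @return the validated data frame (class `clinical_table`).
#' @export
as_clinical_table <- function(x) {
  if (!is.data.frame(x))
    stop_invalid("clinical data must be a data frame")
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_invalid("clinical table lacks required column(s): ",
                 paste(miss, collapse = ", "))
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id))
    stop_invalid("duplicate sample_id(s): ",
                 paste(head(unique(x$sample_id[duplicated(x$sample_id)]), 5),
                       collapse = ", "))
  bad <- which(!is.finite(x$time) | x$time <= 0)
  if (length(bad))
    stop_invalid("non-positive or missing survival time at row(s): ",
                 paste(head(bad, 5), collapse = ", "))
  bad <- which(!x$event %in% c(0, 1))
  if (length(bad))
    stop_invalid("event must be 0 or 1; offending row(s): ",
                 paste(head(bad, 5), collapse = ", "))
  x$event <- as.integer(x$event)
  if (!inherits(x, "clinical_table")) class(x) <- c("clinical_table", class(x))
  x
}

# align an LSS matrix (patients x cell types) with a clinical table on the
# shared samples
align_lss_clinical <- function(lss, clin) {
  clin <- as_clinical_table(clin)
  if (inherits(lss, "lss_result")) lss <- lss_wide(lss)
  common <- intersect(rownames(lss), clin$sample_id)
  if (length(common) < 2)
    stop2("fewer than two samples shared between LSS matrix and clinical ",
          "table")
  list(lss = lss[common, , drop = FALSE],
       clin = clin[match(common, clin$sample_id), , drop = FALSE])
}

# one univariate Cox fit; returns a one-row data frame with a convergence
# flag instead of crashing on degenerate covariates
cox_fit_one <- function(time, event, x, conf_level = 0.95) {
  df <- data.frame(time = time, event = event, lss = x)
  warn <- NULL
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ lss, data = df,
                      ties = "efron"),
      warning = function(w) {
        warn <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  co <- if (is.null(fit)) NA_real_ else unname(coef(fit)[1])
  se <- if (is.null(fit)) NA_real_ else sqrt(fit$var[1, 1])
  converged <- !is.null(fit) && is.null(warn) && is.finite(co) &&
    is.finite(se) && se > 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    coef = co, se = se, hr = exp(co),
    ci_low = exp(co - z * se), ci_high = exp(co + z * se),
    wald_p = if (converged) pchisq((co / se)^2, 1, lower.tail = FALSE)
             else NA_real_,
    converged = converged
  )
}

#' Univariate Cox screen of every cell type's LSS
#'
#' Fits one Cox proportional-hazards model per cell type with the LSS as
#' the sole continuous covariate (Efron tie handling), reports the Wald
#' test per coefficient, and adjusts p-values across all converged fits
#' with the Benjamini-Hochberg procedure.  Non-converged or degenerate
#' fits are flagged, not dropped silently, and are excluded from the
#' adjustment.
#'
#' @param lss LSS matrix (patients x cell types) or an `lss_result` data
#'   frame.
#' @param clin clinical table (see [as_clinical_table()]); samples are
#'   intersected with the LSS matrix by `sample_id`.
#' @param conf_level confidence level for the hazard-ratio interval.
#' @return data frame of class `assoc_result`, one row per cell type:
#'   `cell_type`, `n`, `n_event`, `coef`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `wald_p`, `converged`, `adj_p`.
#' @export
cox_univariate_all <- function(lss, clin, conf_level = 0.95) {
  al <- align_lss_clinical(lss, clin)
  if (sum(al$clin$event) < 2)
    stop2("fewer than two observed events; Cox screen is not estimable")
  rows <- lapply(colnames(al$lss), function(ct) {
    cbind(cell_type = ct,
          cox_fit_one(al$clin$time, al$clin$event, al$lss[, ct],
                      conf_level),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$n <- nrow(al$clin)
  out$n_event <- sum(al$clin$event)
  out$adj_p <- NA_real_
  out$adj_p[out$converged] <- bh_adjust(out$wald_p[out$converged])
  out <- out[, c("cell_type", "n", "n_event", "coef", "se", "hr",
                 "ci_low", "ci_high", "wald_p", "converged", "adj_p")]
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, monotone-enforced and capped
#' at 1 (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values, elementwise no smaller than the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0)
    stop2("empty p-value vector")
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop2("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Covariate-adjusted Cox model for one cell type's LSS
#'
#' Fits a multivariate Cox proportional-hazards model with the LSS plus
#' clinical covariates (dummy-encoded against stated reference levels)
#' and reports the LSS coefficient adjusted for them.  With an empty
#' covariate list this reduces to the univariate fit.
#'
#' @param lss_col named numeric vector of one cell type's LSS per sample
#'   (names are sample ids), or an unnamed vector aligned with `clin`.
#' @param clin clinical table.
#' @param covariates character vector of covariate column names in `clin`.
#' @param reference_levels named character vector of reference levels for
#'   categorical covariates; defaults: `fab = "M1"`, `flt3 = "wildtype"`,
#'   `cyto_risk = "favorable"`, `prior_malignancy = "0"`.
#' @param conf_level confidence level for the hazard-ratio interval.
#' @return one-row `assoc_result` data frame for the LSS term, with the
#'   full coefficient table attached as attribute `"full_table"`.
#' @export
cox_multivariate <- function(lss_col, clin, covariates = character(),
                             reference_levels = c(fab = "M1",
                                                  flt3 = "wildtype",
                                                  cyto_risk = "favorable",
                                                  prior_malignancy = "0"),
                             conf_level = 0.95) {
  clin <- as_clinical_table(clin)
  miss <- setdiff(covariates, names(clin))
  if (length(miss))
    stop2("covariate column(s) not in clinical table: ",
          paste(miss, collapse = ", "))
  if (!is.null(names(lss_col))) {
    common <- intersect(names(lss_col), clin$sample_id)
    if (length(common) < 2)
      stop2("fewer than two samples shared with the clinical table")
    df <- clin[match(common, clin$sample_id), , drop = FALSE]
    df$lss <- unname(lss_col[common])
  } else {
    if (length(lss_col) != nrow(clin))
      stop2("unnamed LSS vector must match the clinical table length")
    df <- clin
    df$lss <- lss_col
  }
  df <- as.data.frame(df)[, c("time", "event", "lss", covariates)]
  df <- df[complete.cases(df), , drop = FALSE]
  for (cv in covariates) {
    if (is.character(df[[cv]]) || is.factor(df[[cv]]) ||
        cv %in% names(reference_levels)) {
      f <- factor(df[[cv]])
      ref <- reference_levels[cv]
      if (!is.na(ref) && ref %in% levels(f)) f <- stats::relevel(f, ref)
      df[[cv]] <- droplevels(f)
    }
  }
  form <- stats::reformulate(c("lss", covariates),
                             response = "survival::Surv(time, event)")
  fit <- survival::coxph(form, data = df, ties = "efron")
  npar <- length(coef(fit))
  if (nrow(df) < 10 * npar)
    warning("only ", nrow(df), " complete cases for ", npar,
            " parameters (fewer than 10 per parameter)", call. = FALSE)
  if (any(is.na(coef(fit))))
    stop2("singular design; aliased column(s): ",
          paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  co <- unname(coef(fit)["lss"])
  se <- sqrt(diag(fit$var))[match("lss", names(coef(fit)))]
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    cell_type = NA_character_, n = nrow(df), n_event = sum(df$event),
    coef = co, se = se, hr = exp(co),
    ci_low = exp(co - z * se), ci_high = exp(co + z * se),
    wald_p = pchisq((co / se)^2, 1, lower.tail = FALSE),
    converged = TRUE, adj_p = NA_real_
  )
  class(out) <- c("assoc_result", "data.frame")
  sm <- summary(fit)$coefficients
  attr(out, "full_table") <- sm
  attr(out, "covariates") <- covariates
  out
}

# interior local maxima of a density curve with their topographic
# prominence (height above the key saddle toward higher ground)
density_peaks <- function(x, y) {
  pk <- which(diff(sign(diff(y))) < 0) + 1
  prom <- vapply(pk, function(i) {
    h <- y[i]
    lh <- pk[pk < i & y[pk] > h]
    rh <- pk[pk > i & y[pk] > h]
    saddles <- c(
      if (length(lh)) min(y[max(lh):i]),
      if (length(rh)) min(y[i:min(rh)])
    )
    if (length(saddles) == 0) h else h - max(saddles)
  }, numeric(1))
  data.frame(index = pk, x = x[pk], height = y[pk], prominence = prom)
}

#' Dichotomize LSS values into high/low groups
#'
#' Estimates the score density with a Gaussian kernel (Silverman
#' bandwidth).  If exactly two modes pass a relative-prominence filter the
#' threshold is placed at the density minimum between them (a bimodal
#' distribution is split at its valley); otherwise the threshold sits at
#' the density mode.  Samples strictly above the threshold are labelled
#' `high`.
#'
#' @param scores numeric vector of LSS values (named by sample id if
#'   available).
#' @param min_n minimum sample size (default 20).
#' @param prominence minimum mode prominence as a fraction of the density
#'   maximum (default 0.10).
#' @param bw bandwidth selector passed to [stats::density()].
#' @return object of class `lss_dichotomy`: `threshold`, `labels` (factor
#'   `low`/`high`, named like `scores`), `n_modes`, `modes`, `density`.
#' @export
dichotomize_lss <- function(scores, min_n = 20, prominence = 0.10,
                            bw = "nrd0") {
  scores <- scores[!is.na(scores)]
  if (length(scores) < min_n)
    stop2("need at least ", min_n, " samples to dichotomize")
  if (sd(scores) == 0)
    stop2("constant scores cannot be dichotomized")
  d <- density(scores, bw = bw)
  pk <- density_peaks(d$x, d$y)
  keep <- pk[pk$prominence >= prominence * max(d$y), , drop = FALSE]
  if (nrow(keep) == 2) {
    i1 <- keep$index[1]; i2 <- keep$index[2]
    valley <- i1 + which.min(d$y[i1:i2]) - 1
    threshold <- d$x[valley]
    n_modes <- 2L
  } else {
    threshold <- d$x[which.max(d$y)]
    n_modes <- nrow(keep)
  }
  labels <- factor(ifelse(scores > threshold, "high", "low"),
                   levels = c("low", "high"))
  names(labels) <- names(scores)
  if (any(table(labels) == 0))
    stop2("dichotomization produced an empty group (threshold = ",
          signif(threshold, 4), ")")
  structure(list(threshold = threshold, labels = labels,
                 n_modes = n_modes, modes = keep$x, density = d),
            class = "lss_dichotomy")
}

#' @export
print.lss_dichotomy <- function(x, ...) {
  cat("LSS dichotomy: threshold ", signif(x$threshold, 4), " (",
      x$n_modes, " mode(s); ", sum(x$labels == "high"), " high / ",
      sum(x$labels == "low"), " low)\n", sep = "")
  invisible(x)
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Computes product-limit survival estimates per group (censoring marks
#' retained in the exported curve table) and the two-sided log-rank
#' chi-square p-value for the difference between groups.
#'
#' @param labels group labels, named by sample id (e.g. the `labels`
#'   component of [dichotomize_lss()]) or aligned with `clin` rows.
#' @param clin clinical table.
#' @return object of class `km_result`: `fit` (a [survival::survfit()]
#'   object), `curves` (data frame of `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`), `chisq`, `df`, `logrank_p`.
#' @export
km_logrank <- function(labels, clin) {
  clin <- as_clinical_table(clin)
  if (!is.null(names(labels))) {
    common <- intersect(names(labels), clin$sample_id)
    if (length(common) < 2)
      stop2("fewer than two samples shared with the clinical table")
    df <- clin[match(common, clin$sample_id), , drop = FALSE]
    df$group <- factor(labels[common])
  } else {
    if (length(labels) != nrow(clin))
      stop2("unnamed labels must match the clinical table length")
    df <- clin
    df$group <- factor(labels)
  }
  df <- as.data.frame(df)
  df$group <- droplevels(df$group)
  if (nlevels(df$group) < 2)
    stop2("log-rank comparison needs at least two groups")
  ev <- tapply(df$event, df$group, sum)
  if (any(ev == 0))
    stop2("group(s) without any observed event: ",
          paste(names(ev)[ev == 0], collapse = ", "))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sdf <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(sdf$n) - 1
  p <- pchisq(sdf$chisq, dfree, lower.tail = FALSE)
  s <- summary(fit, censored = TRUE)
  curves <- data.frame(
    group = sub("^group=", "", as.character(s$strata)),
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, surv = s$surv,
    stringsAsFactors = FALSE
  )
  structure(list(fit = fit, curves = curves, chisq = unname(sdf$chisq),
                 df = dfree, logrank_p = unname(p)),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("Log-rank test: chisq = ", signif(x$chisq, 4), " on ", x$df,
      " df, p = ", signif(x$logrank_p, 4), "\n", sep = "")
  invisible(x)
}

#' Nonparametric group comparisons of LSS values
#'
#' Kruskal-Wallis across more than two groups plus pairwise Wilcoxon
#' rank-sum tests (two-sided by default); with exactly two groups only the
#' Wilcoxon comparison is run.  Group sizes are reported alongside every
#' test.
#'
#' @param scores numeric vector of LSS values.
#' @param groups factor (or coercible) of group membership, aligned with
#'   `scores`.
#' @param alternative passed to [stats::wilcox.test()].
#' @return data frame with columns `test`, `comparison`, `n1`, `n2`,
#'   `statistic`, `p_value`; group sizes attached as attribute `"sizes"`.
#' @export
group_tests <- function(scores, groups, alternative = "two.sided") {
  keep <- !is.na(scores) & !is.na(groups)
  scores <- scores[keep]
  groups <- droplevels(factor(groups[keep]))
  sizes <- table(groups)
  if (nlevels(groups) < 2)
    stop2("need at least two groups")
  if (any(sizes < 2))
    stop2("every group needs at least two members; too small: ",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  rows <- list()
  if (nlevels(groups) > 2) {
    kw <- kruskal.test(scores, groups)
    rows[[1]] <- data.frame(
      test = "kruskal-wallis", comparison = "all groups",
      n1 = length(scores), n2 = NA_integer_,
      statistic = unname(kw$statistic), p_value = kw$p.value,
      stringsAsFactors = FALSE
    )
  }
  lv <- levels(groups)
  for (i in seq_along(lv)) for (j in seq_len(i - 1)) {
    a <- lv[j]; b <- lv[i]
    wt <- wilcox.test(scores[groups == a], scores[groups == b],
                      alternative = alternative, exact = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      test = "wilcoxon", comparison = paste(a, "vs", b),
      n1 = unname(sizes[a]), n2 = unname(sizes[b]),
      statistic = unname(wt$statistic), p_value = wt$p.value,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "sizes") <- sizes
  out
}
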