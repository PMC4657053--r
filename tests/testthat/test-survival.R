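sim_surv <- function(n, lss, beta = 0, base = 0.1, censor_q = NULL) {
  t_event <- rexp(n, rate = base * exp(beta * lss))
  if (is.null(censor_q)) {
    data.frame(sample_id = paste0("s", seq_len(n)), time = t_event,
               event = 1L, stringsAsFactors = FALSE)
  } else {
    cmax <- quantile(t_event, censor_q)
    ct <- runif(n, 0, cmax)
    data.frame(sample_id = paste0("s", seq_len(n)),
               time = pmin(t_event, ct),
               event = as.integer(t_event <= ct), stringsAsFactors = FALSE)
  }
}

test_that("univariate Cox screen is calibrated under the null", {
  set.seed(21)
  hits <- 0L
  total <- 0L
  for (rep in 1:250) {
    lss <- matrix(rnorm(200 * 4), 200, 4,
                  dimnames = list(paste0("s", 1:200), paste0("CT", 1:4)))
    clin <- sim_surv(200, 0)
    a <- cox_univariate_all(lss, clin)
    hits <- hits + sum(a$wald_p < 0.05)
    total <- total + nrow(a)
  }
  frac <- hits / total
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("univariate Cox recovers a planted log-hazard coefficient", {
  set.seed(22)
  coefs <- vapply(1:100, function(i) {
    lss <- matrix(rnorm(500), 500, 1,
                  dimnames = list(paste0("s", 1:500), "CT1"))
    clin <- sim_surv(500, lss[, 1], beta = 0.5)
    cox_univariate_all(lss, clin)$coef
  }, numeric(1))
  expect_lt(abs(mean(coefs) - 0.5), 0.1)
})

test_that("degenerate covariates are flagged, not fatal, and skipped in
           adjustment", {
  set.seed(23)
  lss <- cbind(CT1 = rnorm(100), CT2 = rep(2, 100))
  rownames(lss) <- paste0("s", 1:100)
  clin <- sim_surv(100, 0)
  a <- cox_univariate_all(lss, clin)
  expect_false(a$converged[a$cell_type == "CT2"])
  expect_true(is.na(a$adj_p[a$cell_type == "CT2"]))
  expect_true(a$converged[a$cell_type == "CT1"])
  clin0 <- clin
  clin0$event <- 0L
  expect_error(cox_univariate_all(lss, clin0), "events")
})

test_that("Cox estimates approach the truth as the cohort grows", {
  set.seed(24)
  bias <- vapply(c(100, 500, 2000), function(n) {
    est <- vapply(1:20, function(i) {
      lss <- matrix(rnorm(n), n, 1,
                    dimnames = list(paste0("s", 1:n), "CT1"))
      clin <- sim_surv(n, lss[, 1], beta = 0.7)
      cox_univariate_all(lss, clin)$coef
    }, numeric(1))
    abs(mean(est) - 0.7)
  }, numeric(1))
  expect_lt(bias[3], 0.05)
  expect_lt(bias[3], bias[1] + 0.02)
})

test_that("BH adjustment matches the closed-form step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  set.seed(25)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "empty")
})

test_that("multivariate Cox with no covariates reduces to the univariate fit", {
  set.seed(26)
  lss <- rnorm(150)
  names(lss) <- paste0("s", 1:150)
  clin <- sim_surv(150, lss, beta = 0.5)
  uni <- cox_univariate_all(matrix(lss, dimnames = list(names(lss), "CT1")),
                            clin)
  mv <- cox_multivariate(lss, clin, covariates = character())
  expect_equal(mv$coef, uni$coef, tolerance = 1e-10)
  expect_equal(mv$wald_p, uni$wald_p, tolerance = 1e-10)
  expect_error(cox_multivariate(lss, clin, covariates = "karyotype"),
               "not in clinical table")
})

test_that("adjusting for a measured confounder moves the estimate toward the
           direct effect", {
  set.seed(27)
  direct <- 0.3
  res <- vapply(1:100, function(i) {
    n <- 300
    age <- rnorm(n)
    lss <- 0.8 * age + rnorm(n)
    names(lss) <- paste0("s", 1:n)
    clin <- data.frame(sample_id = names(lss),
                       time = rexp(n, 0.1 * exp(direct * lss + 0.5 * age)),
                       event = 1L, age = age, stringsAsFactors = FALSE)
    c(unadj = cox_multivariate(lss, clin)$coef,
      adj = cox_multivariate(lss, clin, covariates = "age")$coef)
  }, numeric(2))
  expect_lt(abs(mean(res["adj", ]) - direct),
            abs(mean(res["unadj", ]) - direct))
})

test_that("singular multivariate designs report the aliased column", {
  set.seed(28)
  n <- 100
  lss <- rnorm(n)
  names(lss) <- paste0("s", 1:n)
  clin <- data.frame(sample_id = names(lss), time = rexp(n, 0.1),
                     event = 1L, x1 = rnorm(n), stringsAsFactors = FALSE)
  clin$x2 <- clin$x1                       # exact alias
  expect_error(
    suppressWarnings(cox_multivariate(lss, clin, covariates = c("x1", "x2"))),
    "aliased|singular")
})

test_that("bimodal scores split at the valley, unimodal at the mode", {
  set.seed(29)
  bim <- c(rnorm(200, -2, 0.5), rnorm(200, 2, 0.5))
  d1 <- dichotomize_lss(bim)
  expect_equal(d1$n_modes, 2L)
  expect_gt(d1$threshold, -1)
  expect_lt(d1$threshold, 1)
  expect_true(all(table(d1$labels) > 0))
  uni <- rnorm(400)
  d2 <- dichotomize_lss(uni)
  dens <- density(uni)
  expect_lt(abs(d2$threshold - dens$x[which.max(dens$y)]), 0.3)
  expect_error(dichotomize_lss(rep(1, 50)), "constant")
  expect_error(dichotomize_lss(rnorm(5)), "at least 20")
})

test_that("log-rank test returns p = 1 on identical groups and steps only at
           event times", {
  set.seed(30)
  base <- sim_surv(50, 0, censor_q = 0.9)
  clin <- rbind(base,
                transform(base, sample_id = paste0(sample_id, "b")))
  labels <- setNames(rep(c("low", "high"), each = 50), clin$sample_id)
  km <- km_logrank(labels, clin)
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$logrank_p, 1)
  for (g in unique(km$curves$group)) {
    cv <- km$curves[km$curves$group == g, ]
    drops <- which(diff(cv$surv) < 0) + 1
    expect_true(all(cv$n_event[drops] > 0))
  }
  expect_error(km_logrank(setNames(rep("low", 100), clin$sample_id), clin),
               "two groups")
})

test_that("log-rank detects a strong planted hazard ratio", {
  set.seed(31)
  sig <- vapply(1:100, function(i) {
    t1 <- rexp(200, 0.1)
    t2 <- rexp(200, 0.3)          # hazard ratio 3
    clin <- data.frame(sample_id = paste0("s", 1:400),
                       time = c(t1, t2), event = 1L,
                       stringsAsFactors = FALSE)
    labels <- setNames(rep(c("low", "high"), each = 200), clin$sample_id)
    km_logrank(labels, clin)$logrank_p < 0.01
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})

test_that("dichotomized log-rank and continuous Cox agree in direction", {
  set.seed(32)
  n <- 300
  lss <- c(rnorm(n / 2, -1.5), rnorm(n / 2, 1.5))
  names(lss) <- paste0("s", 1:n)
  clin <- sim_surv(n, lss, beta = 0.6)
  a <- cox_univariate_all(matrix(lss, dimnames = list(names(lss), "CT1")),
                          clin)
  di <- dichotomize_lss(lss)
  km <- km_logrank(di$labels, clin)
  expect_gt(a$coef, 0)
  expect_lt(km$logrank_p, 0.01)
  med <- tapply(clin$time, di$labels[clin$sample_id], median)
  expect_lt(med["high"], med["low"])   # higher score, shorter survival
})

test_that("group comparisons are calibrated and sensitive", {
  set.seed(33)
  kw_p <- vapply(1:400, function(i) {
    g <- factor(rep(c("a", "b", "c"), each = 50))
    group_tests(rnorm(150), g)$p_value[1]
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(kw_p, "punif"))$p.value, 0.01)
  shifted <- group_tests(c(rnorm(50), rnorm(50, 2)),
                         factor(rep(c("wildtype", "mutated"), each = 50)))
  expect_lt(shifted$p_value[shifted$test == "wilcoxon"], 0.001)
  expect_equal(as.integer(attr(shifted, "sizes")), c(50L, 50L))
  g3 <- group_tests(rnorm(150), factor(rep(c("M0", "M1", "M2"), each = 50)))
  expect_identical(g3$test[1], "kruskal-wallis")
  expect_equal(nrow(g3), 1 + 3)         # overall + three pairwise
  expect_error(group_tests(rnorm(50), factor(rep("a", 50))), "two groups")
})
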