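# Independent oracles, written by direct summation / closed form, never by
# calling the implementation under test.

# pre-LSS by brute force: evaluate d(i) at every index by direct summation
prelss_brute <- function(a, w) {
  n <- length(a)
  totF <- sum(a * w)
  totB <- sum(a * (1 - w))
  if (totF <= 0 || totB <= 0) return(NA_real_)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- sum(a[seq_len(i)] * w[seq_len(i)]) / totF -
      sum(a[seq_len(i)] * (1 - w[seq_len(i)])) / totB
  }
  plus <- max(0, max(d))
  minus <- min(0, min(d))
  if (plus >= -minus) plus else minus
}

# Benjamini-Hochberg by the closed-form step-up procedure
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(q)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# hand-rolled five-step lineage preparation on a tiny matrix, written as
# literal arithmetic (no shared code with the package)
prep_by_hand <- function(m, groups, trim = 10) {
  med <- apply(m, 1, median)
  m1 <- m - med
  zcol <- function(x) (x - mean(x)) / sd(x)
  m2 <- apply(m1, 2, zcol)
  m3 <- sapply(groups, function(cc) rowMeans(m2[, cc, drop = FALSE]))
  m3 <- apply(m3, 2, zcol)
  up <- ifelse(m3 > 0, m3, 0)
  dn <- ifelse(m3 < 0, m3, 0)
  wu <- ifelse(up > 0, pmin(-log10(1 - pnorm(up)), trim), 0)
  wd <- ifelse(dn < 0, pmin(-log10(pnorm(dn)), trim), 0)
  mx <- max(wu, wd)
  list(up = wu / mx, down = wd / mx, scale_max = mx)
}

# small deterministic simulated study shared by several tests
small_study <- function(seed = 11, n_patients = 12, beta = 1.5,
                        n_genes = 400, n_celltypes = 5, module_size = 20,
                        ...) {
  cfg <- sim_config(n_genes = n_genes, n_celltypes = n_celltypes,
                    module_size = module_size, n_patients = n_patients,
                    beta = beta, seed = seed, ...)
  sim <- simulate_lineages(cfg)
  w <- build_lineage_weights(sim$expr, sim$replicate_map)
  coh <- simulate_cohort(cfg, sim)
  list(cfg = cfg, sim = sim, weights = w, cohort = coh)
}
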