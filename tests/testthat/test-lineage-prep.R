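ref3 <- function() {
  expression_matrix(
    matrix(c(1, 2, 6,
             5, 5, 5,
             2, 1, 0), 3, 3, byrow = TRUE,
           dimnames = list(c("Ga", "Gb", "Gc"), c("c1", "c2", "c3"))),
    channel_mode = "reference")
}

test_that("median normalization subtracts row medians and is idempotent", {
  m <- ref3()
  out <- median_normalize(m)
  expect_equal(unname(out["Ga", ]), c(-1, 0, 4))
  expect_equal(unname(out["Gb", ]), c(0, 0, 0))
  expect_equal(unname(apply(out, 1, median)), rep(0, 3))
  expect_equal(median_normalize(out), out)
  expect_error(median_normalize(m[, 1, drop = FALSE]), "single-column")
})

test_that("column z-transformation gives mean 0, sample sd 1", {
  m <- matrix(c(-1, 0, 4), 3, 1, dimnames = list(letters[1:3], "c1"))
  z <- z_transform_columns(cbind(m, c2 = rnorm(3)))
  expect_equal(unname(z[, "c1"]), c(-0.7559, -0.3780, 1.1339),
               tolerance = 1e-4)
  big <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  zb <- z_transform_columns(big)
  expect_equal(unname(colMeans(zb)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(zb, 2, sd)), rep(1, 10), tolerance = 1e-12)
  const <- big
  const[, 3] <- 5
  expect_error(z_transform_columns(const), "c3")
})

test_that("replicate collapsing averages z-scores and renormalizes", {
  set.seed(1)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10),
                              c("A#1", "A#2", "B#1", "B#2")))
  z <- z_transform_columns(m)
  coll <- collapse_replicates(z, list(A = c("A#1", "A#2"),
                                      B = c("B#1", "B#2")))
  expect_identical(colnames(coll), c("A", "B"))
  expect_equal(unname(colMeans(coll)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(coll, 2, sd)), c(1, 1), tolerance = 1e-12)
  # identical replicates collapse to the re-z-transformed column itself
  dup <- z[, c(1, 1, 3)]
  colnames(dup) <- c("A#1", "A#2", "B#1")
  coll2 <- collapse_replicates(dup, infer_replicate_map(colnames(dup)))
  expect_equal(unname(coll2[, "A"]),
               unname(z_transform_columns(z[, 1, drop = FALSE])[, 1]))
  # the collapsed value is the arithmetic mean before renormalization:
  # renormalization is affine, so order statistics must agree
  expect_equal(order(coll[, "A"]), order(rowMeans(z[, 1:2])))
  expect_error(collapse_replicates(z, list(A = c("A#1", "nope"))),
               "absent")
  expect_error(collapse_replicates(z, list(A = c("A#1", "A#2"))),
               "not covered")
})

test_that("up/down splitting zeroes the opposite sign and reconstructs z", {
  z <- matrix(c(1.2, -0.5, 0, 2), 4, 1,
              dimnames = list(paste0("g", 1:4), "A"))
  ud <- split_up_down(z)
  expect_equal(unname(ud$up[, 1]), c(1.2, 0, 0, 2))
  expect_equal(unname(ud$down[, 1]), c(0, -0.5, 0, 0))
  expect_equal(ud$up + ud$down, z)
  neg <- -abs(z)
  expect_true(all(split_up_down(neg)$up == 0))
})

test_that("weights are -log10 tail probabilities, trimmed and scaled", {
  up <- matrix(c(1.6449, 7, 0, 0.5), 4, 1,
               dimnames = list(paste0("g", 1:4), "A"))
  dn <- matrix(c(0, 0, -2, 0), 4, 1,
               dimnames = dimnames(up))
  w <- weights_from_z(up, dn)
  # pre-scale values recoverable through the recorded scaling maximum
  expect_equal(w$up["g1", 1] * w$scale_max, 1.3010, tolerance = 1e-4)
  expect_equal(w$up["g2", 1] * w$scale_max, 10)        # trimmed
  expect_equal(w$scale_max, 10)                        # global max is the trim
  expect_equal(w$up["g3", 1], 0)                       # zeroed entry
  expect_equal(w$down["g3", 1] * w$scale_max,
               -log10(pnorm(-2)), tolerance = 1e-10)
  expect_true(all(w$up >= 0 & w$up <= 1 & w$down >= 0 & w$down <= 1))
  expect_equal(max(w$up, w$down), 1)
  expect_error(weights_from_z(up * 0, dn * 0), "all weights are zero")
})

test_that("weight construction is monotone in z and sparsity-complementary", {
  set.seed(2)
  z <- matrix(rnorm(300), 100, 3,
              dimnames = list(paste0("g", 1:100), c("A", "B", "C")))
  ud <- split_up_down(z)
  w <- weights_from_z(ud$up, ud$down)
  for (k in 1:3) {
    pos <- ud$up[, k] > 0
    expect_equal(order(w$up[pos, k]), order(ud$up[pos, k]))
  }
  expect_true(all(w$up * w$down == 0))
})

test_that("five-step preparation matches an independent hand computation", {
  set.seed(3)
  m <- matrix(rnorm(24, mean = 8), 3, 8,
              dimnames = list(c("Ga", "Gb", "Gc"),
                              paste0(rep(c("A", "B"), each = 4), "#",
                                     rep(1:4, 2))))
  groups <- list(A = paste0("A#", 1:4), B = paste0("B#", 1:4))
  got <- build_lineage_weights(expression_matrix(m, "reference"))
  want <- prep_by_hand(m, groups)
  expect_equal(got$up, want$up, tolerance = 1e-12)
  expect_equal(got$down, want$down, tolerance = 1e-12)
  expect_equal(got$scale_max, want$scale_max, tolerance = 1e-12)
})

test_that("per-celltype scaling normalizes each cell type to max 1", {
  set.seed(4)
  z <- matrix(rnorm(60), 20, 3,
              dimnames = list(paste0("g", 1:20), c("A", "B", "C")))
  ud <- split_up_down(z)
  w <- weights_from_z(ud$up, ud$down, scale = "per_celltype")
  per_ct_max <- pmax(apply(w$up, 2, max), apply(w$down, 2, max))
  expect_equal(unname(per_ct_max), rep(1, 3))
})
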