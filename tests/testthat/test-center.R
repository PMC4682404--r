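test_that("reference is the item-wise mean of the designated samples", {
  vals <- rbind(g1 = c(1, 3), g2 = c(2, 2))
  colnames(vals) <- c("c1", "c2")
  m <- ExpressionMatrix(vals)
  d <- ExperimentDesign(c("c1", "c2"), c("ctrl", "ctrl"),
                        "control_group", "ctrl")
  expect_equal(referenceValues(computeReference(m, d)),
               c(g1 = 2, g2 = 2))

  # grand mean of identical samples is that sample
  v <- c(g1 = 1.5, g2 = -2, g3 = 0)
  m2 <- ExpressionMatrix(cbind(s1 = v, s2 = v, s3 = v))
  d2 <- ExperimentDesign(paste0("s", 1:3), rep("A", 3), "grand_mean")
  expect_equal(referenceValues(computeReference(m2, d2)), v)
})

test_that("grand-mean reference matches explicit per-item summation", {
  # 10 groups x 4 repeats, some missing cells
  set.seed(42)
  vals <- matrix(rnorm(30 * 40), 30, 40,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:40)))
  vals[sample(length(vals), 60)] <- NA
  m <- ExpressionMatrix(vals)
  d <- ExperimentDesign(paste0("s", 1:40), rep(paste0("t", 1:10), each = 4),
                        "grand_mean")
  r <- referenceValues(computeReference(m, d))
  for (i in seq_len(nrow(vals))) {
    tot <- 0; n <- 0
    for (j in seq_len(ncol(vals)))
      if (!is.na(vals[i, j])) { tot <- tot + vals[i, j]; n <- n + 1 }
    expect_equal(unname(r[i]), tot / n)
  }
})

test_that("all-missing items get reference zero and are excluded", {
  vals <- rbind(g1 = c(1, 2, 5), g2 = c(NA, NA, 7))
  colnames(vals) <- c("c1", "c2", "t1")
  m <- ExpressionMatrix(vals)
  d <- ExperimentDesign(colnames(vals), c("ctrl", "ctrl", "trt"),
                        "control_group", "ctrl")
  ref <- computeReference(m, d)
  expect_equal(unname(referenceValues(ref)["g2"]), 0)
  expect_equal(excludedItems(ref), "g2")
  cen <- centerMatrix(m, ref)
  expect_true(all(centeredValues(cen)[, "g2"] == 0))
  expect_equal(nFunctional(cen), 1L)
})

test_that("an empty designated sample set is an error naming the rule", {
  vals <- rbind(g1 = c(1, 2))
  colnames(vals) <- c("t1", "t2")
  m <- ExpressionMatrix(vals)
  # the control group exists in the design but none of its samples are in
  # the matrix
  d <- ExperimentDesign(c("t1", "t2", "c1"), c("trt", "trt", "ctrl"),
                        "control_group", "ctrl")
  expect_error(computeReference(m, d), "control_group\\(ctrl\\)")
})

test_that("centering subtracts the reference and transposes", {
  # samples (2,3) and (4,5) over items g1, g2; r = (1,1)
  vals <- rbind(g1 = c(2, 4), g2 = c(3, 5))
  colnames(vals) <- c("s1", "s2")
  ref <- new("ReferenceVector", values = c(g1 = 1, g2 = 1),
             rule = "grand_mean", allMissingItems = character())
  X <- centeredValues(centerMatrix(ExpressionMatrix(vals), ref))
  expect_equal(X, rbind(s1 = c(1, 2), s2 = c(3, 4)),
               ignore_attr = "dimnames")
  expect_equal(rownames(X), c("s1", "s2"))   # samples now in rows
  expect_equal(colnames(X), c("g1", "g2"))
})

test_that("a sample equal to the reference lands on the origin", {
  vals <- rbind(g1 = c(1, 9), g2 = c(-2, 4))
  colnames(vals) <- c("s1", "s2")
  ref <- new("ReferenceVector", values = c(g1 = 1, g2 = -2),
             rule = "control_group", allMissingItems = character())
  X <- centeredValues(centerMatrix(ExpressionMatrix(vals), ref))
  expect_true(all(X["s1", ] == 0))
})

test_that("missing cells are replaced with exactly zero", {
  vals <- rbind(g1 = c(2, NA), g2 = c(3, 5))
  colnames(vals) <- c("s1", "s2")
  ref <- new("ReferenceVector", values = c(g1 = 123.4, g2 = 1),
             rule = "grand_mean", allMissingItems = character())
  X <- centeredValues(centerMatrix(ExpressionMatrix(vals), ref))
  expect_identical(X["s2", "g1"], 0)
})

test_that("a reference that does not cover all items is rejected", {
  vals <- rbind(g1 = c(1, 2), g2 = c(3, 4))
  colnames(vals) <- c("s1", "s2")
  ref <- new("ReferenceVector", values = c(g1 = 0),
             rule = "grand_mean", allMissingItems = character())
  expect_error(centerMatrix(ExpressionMatrix(vals), ref), "g2")
})

test_that("zeroOutItems zero-replaces columns and tracks m_f", {
  X <- randX(4, 12, seed = 1)
  cen <- makeCentered(X)
  expect_equal(zeroOutItems(cen, character()), cen)
  half <- colnames(X)[1:6]
  z <- zeroOutItems(cen, half)
  expect_equal(nFunctional(z), 6L)
  expect_true(all(centeredValues(z)[, half] == 0))
  expect_equal(dim(centeredValues(z)), dim(X))
  expect_setequal(excludedItems(z), half)
  expect_error(zeroOutItems(cen, "nope"), "unknown item")
  expect_error(zeroOutItems(cen, colnames(X)), "no functional items")
})

test_that("zeroing items removes exactly their inner-product terms", {
  X <- randX(6, 30, seed = 7)
  model <- fitOn(X)
  S <- colnames(X)[c(3, 11, 25)]
  y0 <- componentScores(projectSamples(makeCentered(X), model))
  y1 <- componentScores(projectSamples(zeroOutItems(makeCentered(X), S),
                                       model))
  V <- axisLoadings(model)
  for (k in seq_len(nrow(X)))
    for (j in seq_len(ncol(V))) {
      dropTerms <- 0
      for (item in S) dropTerms <- dropTerms + X[k, item] * V[item, j]
      expect_equal(y0[k, j] - y1[k, j], dropTerms, tolerance = 1e-12)
    }
})
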