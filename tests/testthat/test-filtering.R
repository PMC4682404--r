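twoGroupDesign <- function(nPerGroup = 4) {
  samples <- paste0(rep(c("A", "B"), each = nPerGroup), "_", seq_len(nPerGroup))
  ExperimentDesign(samples, rep(c("A", "B"), each = nPerGroup), "grand_mean")
}

mkProbeData <- function(genes, design) {
  ProbeLevelData(genes, sampleIds(design))
}

test_that("a constant gene has an undefined F and is not positive", {
  d <- twoGroupDesign()
  m <- matrix(5, 3, 8)
  res <- anovaGroupTest(mkProbeData(list(flat = m), d), d)
  tab <- filterTable(res)
  expect_true(is.na(tab$p_value))
  expect_false(tab$positive)
  expect_false(tab$testable)
})

test_that("the group F test matches an explicit sum-of-squares oracle and lm", {
  d <- twoGroupDesign()
  set.seed(101)
  shift <- rep(c(0, 5), each = 4)
  m <- matrix(rnorm(3 * 8, sd = 1), 3, 8) + rnorm(3) +  # probe sensitivity
    rep(shift, each = 3)
  res <- anovaGroupTest(mkProbeData(list(g = m), d), d)
  tab <- filterTable(res)
  expect_true(tab$positive)
  oracle <- ssAnovaOracle(m, groupOf(d)[sampleIds(d)])
  expect_equal(tab$p_value, oracle$p, tolerance = 1e-10)
  # and against stats::anova(lm()) as a second independent route
  y <- as.vector(m)
  probe <- factor(rep(1:3, times = 8))
  group <- factor(rep(groupOf(d)[sampleIds(d)], each = 3))
  fit <- anova(lm(y ~ probe + group))
  expect_equal(tab$p_value, fit["group", "Pr(>F)"], tolerance = 1e-10)
})

test_that("null genes keep the nominal false-positive rate and no NA leaks", {
  cfg <- simulationConfig(nGroups = 2L, repsPerGroup = 4L, nItems = 2000L,
                          nInformative = 0L, noiseSd = 1, seed = 55,
                          referenceRule = "grand_mean")
  sim <- simulateProbeLevel(cfg, probesPerGene = 3L)
  res <- anovaGroupTest(sim$data, sim$design)
  tab <- filterTable(res)
  expect_true(all(tab$testable))
  rate <- mean(tab$positive)
  se <- sqrt(0.01 * 0.99 / nrow(tab))
  expect_lt(abs(rate - 0.01), 3 * se)
  # p values uniform enough for a coarse check
  expect_gt(stats::ks.test(tab$p_value, "punif")$p.value, 1e-4)
})

test_that("lowering alpha never adds positives, and power rises with effect", {
  cfg <- simulationConfig(nGroups = 2L, repsPerGroup = 4L, nItems = 300L,
                          nInformative = 0L, noiseSd = 1, seed = 77,
                          referenceRule = "grand_mean")
  sim <- simulateProbeLevel(cfg, probesPerGene = 3L,
                            effectGenes = seq_len(300), effectSize = 1)
  resHi <- anovaGroupTest(sim$data, sim$design, alpha = 0.05)
  resLo <- anovaGroupTest(sim$data, sim$design, alpha = 0.005)
  posHi <- filterTable(resHi)$positive
  posLo <- filterTable(resLo)$positive
  expect_true(all(posHi[posLo]))  # lo-alpha positives nest in hi-alpha ones
  # power monotone over an effect grid, averaged over seeds
  rates <- sapply(c(0, 1, 2, 3), function(eff) {
    mean(sapply(1:5, function(s) {
      cfg2 <- simulationConfig(nGroups = 2L, repsPerGroup = 4L,
                               nItems = 150L, nInformative = 0L,
                               noiseSd = 1, seed = 1000L + s,
                               referenceRule = "grand_mean")
      sim2 <- simulateProbeLevel(cfg2, probesPerGene = 3L,
                                 effectGenes = seq_len(150),
                                 effectSize = eff)
      mean(filterTable(anovaGroupTest(sim2$data, sim2$design))$positive)
    }))
  })
  expect_true(all(diff(rates) >= 0))
})

test_that("selectItems partitions the testable genes", {
  d <- twoGroupDesign()
  set.seed(9)
  genes <- c(
    lapply(1:5, function(i) matrix(rnorm(24), 3, 8) +
             rep(rep(c(0, 8), each = 4), each = 3)),  # strong effects
    lapply(1:5, function(i) matrix(rnorm(24), 3, 8)),  # null
    list(matrix(2, 3, 8)))  # constant, untestable
  names(genes) <- paste0("g", 1:11)
  res <- anovaGroupTest(mkProbeData(genes, d), d)
  sel <- selectItems(res)
  tab <- filterTable(res)
  expect_equal(length(sel$positive) + length(sel$negative),
               sum(tab$testable))
  expect_length(intersect(sel$positive, sel$negative), 0)
  expect_false("g11" %in% c(sel$positive, sel$negative))
  # alpha = 0: nothing can be positive
  res0 <- anovaGroupTest(mkProbeData(genes, d), d, alpha = 0)
  expect_length(selectItems(res0)$positive, 0)
  # all genes positive -> empty negative set
  strong <- genes[1:5]
  selS <- selectItems(anovaGroupTest(mkProbeData(strong, d), d))
  expect_length(selS$negative, 0)
})

test_that("single-probe and NA genes are untestable, never an exception", {
  d <- twoGroupDesign()
  g1 <- matrix(rnorm(8), 1, 8)            # one probe
  g2 <- matrix(rnorm(24), 3, 8); g2[1] <- NA
  res <- anovaGroupTest(mkProbeData(list(p1 = g1, na1 = g2), d), d)
  tab <- filterTable(res)
  expect_false(any(tab$testable))
  expect_false(any(tab$positive))
})

test_that("the gene-level one-way fallback matches anova(lm)", {
  d <- twoGroupDesign(5)
  set.seed(12)
  vals <- matrix(rnorm(4 * 10), 4, 10,
                 dimnames = list(paste0("g", 1:4), sampleIds(d)))
  vals[1, ] <- vals[1, ] + rep(c(0, 3), each = 5)
  vals[4, 2] <- NA  # exercises the incomplete-row path
  res <- geneLevelGroupTest(ExpressionMatrix(vals), d)
  tab <- filterTable(res)
  for (i in 1:4) {
    ok <- !is.na(vals[i, ])
    fit <- anova(lm(vals[i, ok] ~ factor(groupOf(d)[sampleIds(d)][ok])))
    expect_equal(tab$p_value[i], fit[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  expect_true(tab$positive[1])
  expect_false(any(tab$positive[2:3]))
})
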