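test_that("identical config and seed give bit-identical output", {
  cfg <- simulationConfig(nItems = 100, nInformative = 40,
                          outlierFraction = 0.1,
                          heterogeneousItemFraction = 0.2, seed = 5)
  a <- simulateExperiment(cfg)
  b <- simulateExperiment(cfg)
  expect_identical(exprValues(a$matrix), exprValues(b$matrix))
  expect_identical(a$truth, b$truth)
})

test_that("the default design mirrors a 7-group, 5-repeat toxicology layout", {
  cfg <- simulationConfig(nItems = 20, nInformative = 10)
  sim <- simulateExperiment(cfg)
  expect_length(sampleIds(sim$matrix), 35L)
  expect_equal(referenceRule(sim$design), "control_group")
  expect_equal(sim$design@referenceGroup, "C")
  expect_equal(sort(unique(groupOf(sim$design))),
               sort(c("C", paste0("G", 1:6))))
  expect_setequal(toxicGroups(cfg), c("G1", "G3", "G5"))
  # toxic groups share the strong first latent axis
  L <- cfg@latentPositions
  expect_true(all(L[c("G1", "G3", "G5"), 1] == 3))
  expect_true(all(L[c("C", "G2", "G4", "G6"), 1] == 0))
})

test_that("the noiseless limit reproduces latent geometry exactly", {
  cfg <- simulationConfig(nItems = 80, nInformative = 80, noiseSd = 0,
                          seed = 6)
  sim <- simulateExperiment(cfg)
  vals <- exprValues(sim$matrix)
  # within-group samples are identical
  g <- groupOf(sim$design)
  for (grp in unique(g)) {
    cols <- vals[, names(g)[g == grp], drop = FALSE]
    expect_lt(max(abs(cols - cols[, 1])), 1e-12)
  }
  # training scores recover the latent group geometry exactly: distances
  # equal the item-space distances of the loading-mapped latent positions
  # (up to the known sqrt(m_f) scaling), and track raw latent distances
  fit <- depcaFit(sim$matrix, sim$design)
  reps <- componentScores(fit$trainingScores)
  dScore <- as.matrix(dist(reps)) * sqrt(nFunctional(fit$model))
  mapped <- sim$truth$latentPositions %*% t(sim$truth$loadings)
  dMapped <- as.matrix(dist(mapped))[rownames(reps), rownames(reps)]
  expect_lt(max(abs(dScore - dMapped)), 1e-8)
  dLatent <- as.matrix(dist(sim$truth$latentPositions))[rownames(reps),
                                                        rownames(reps)]
  expect_gt(cor(dScore[upper.tri(dScore)], dLatent[upper.tri(dLatent)],
                method = "spearman"), 0.9)
})

test_that("empirical moments match the configured parameters", {
  # one group, many repeats: item-wise means approach the noiseless values
  # and item-wise sds approach the configured noise sd
  cfg <- simulationConfig(nGroups = 1L, repsPerGroup = 400L, nItems = 25L,
                          nInformative = 10L, noiseSd = 1.5, seed = 8,
                          referenceRule = "grand_mean")
  cfg0 <- simulationConfig(nGroups = 1L, repsPerGroup = 1L, nItems = 25L,
                           nInformative = 10L, noiseSd = 0, seed = 8,
                           referenceRule = "grand_mean")
  vals <- exprValues(simulateExperiment(cfg)$matrix)
  mu <- exprValues(simulateExperiment(cfg0)$matrix)[, 1]
  n <- ncol(vals)
  seMean <- 1.5 / sqrt(n)
  seSd <- 1.5 / sqrt(2 * (n - 1))
  expect_true(all(abs(rowMeans(vals) - mu) < 4 * seMean))
  expect_true(all(abs(apply(vals, 1, sd) - 1.5) < 4 * seSd))
})

test_that("outlier samples and heterogeneous groups inflate variance", {
  base <- simulationConfig(nItems = 200, nInformative = 100, seed = 9)
  het <- simulationConfig(nItems = 200, nInformative = 100, seed = 9,
                          heterogeneousGroup = 4L)  # G3
  vw <- function(sim, grp) {
    g <- groupOf(sim$design)
    cols <- exprValues(sim$matrix)[, names(g)[g == grp]]
    mean(apply(cols, 1, var))
  }
  simBase <- simulateExperiment(base)
  simHet <- simulateExperiment(het)
  expect_gt(vw(simHet, "G3"), 2 * vw(simBase, "G3"))
  out <- simulateExperiment(simulationConfig(nItems = 200,
                                             nInformative = 0,
                                             outlierFraction = 0.3,
                                             outlierMagnitude = 6,
                                             seed = 10))
  expect_gt(length(out$truth$outlierSamples), 0)
  sdAll <- apply(exprValues(out$matrix), 2, sd)
  expect_gt(min(sdAll[out$truth$outlierSamples]),
            max(sdAll[setdiff(colnames(exprValues(out$matrix)),
                              out$truth$outlierSamples)]))
})

test_that("probe-level simulation is additive and null when told to be", {
  cfg <- simulationConfig(nGroups = 2L, repsPerGroup = 6L, nItems = 4L,
                          noiseSd = 0, seed = 11,
                          referenceRule = "grand_mean")
  sim <- simulateProbeLevel(cfg, probesPerGene = 3L, effectGenes = "gene00001",
                            effectSize = 2)
  g <- groupOf(sim$design)
  m <- sim$data@genes[["gene00001"]]
  # probe-sensitivity offsets cancel in per-probe group-mean differences
  for (p in 1:3) {
    dA <- mean(m[p, g[colnames(m)] == "C"])
    dB <- mean(m[p, g[colnames(m)] == "G1"])
    expect_equal(dB - dA, 2, tolerance = 1e-12)
  }
  # null genes have zero group difference
  m0 <- sim$data@genes[["gene00002"]]
  expect_equal(mean(m0[, g[colnames(m0)] == "C"]),
               mean(m0[, g[colnames(m0)] == "G1"]), tolerance = 1e-12)
})

test_that("one strong effect gene outranks every null gene's F", {
  cfg <- simulationConfig(nGroups = 2L, repsPerGroup = 4L, nItems = 200L,
                          noiseSd = 1, seed = 13,
                          referenceRule = "grand_mean")
  sim <- simulateProbeLevel(cfg, probesPerGene = 3L,
                            effectGenes = "gene00007", effectSize = 6)
  tab <- filterTable(anovaGroupTest(sim$data, sim$design))
  pEff <- tab$p_value[tab$gene_id == "gene00007"]
  expect_lt(pEff, min(tab$p_value[tab$gene_id != "gene00007"]))
  # cross-check that gene against the brute-force oracle
  oracle <- ssAnovaOracle(sim$data@genes[["gene00007"]],
                          groupOf(sim$design)[sampleIds(sim$data)])
  expect_equal(pEff, oracle$p, tolerance = 1e-10)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(nItems = 10, nInformative = 20),
               "exceeds")
  expect_error(simulationConfig(outlierFraction = 1.5), "fractions")
  expect_error(simulationConfig(repsPerGroup = 0), ">= 1")
  expect_error(simulateProbeLevel(simulationConfig(nItems = 5),
                                  probesPerGene = 1), ">= 2")
})
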