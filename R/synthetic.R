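#' Build a simulation configuration
#'
#' Defaults emulate a toxicology-style design: seven groups — a mock
#' control "C" plus three toxic compounds (G1, G3, G5) sharing a strong
#' first latent axis and three nontoxic compounds (G2, G4, G6) near the
#' control — with five repeats each, 2000 items of which 500 load on two
#' latent axes, latent effect three times the individual-noise sd, and the
#' control group as reference. Every regime of interest (outlier samples,
#' high within-group-variance items, a heterogeneous group, biased group
#' sizes via `repsPerGroup`) is a parameter.
#'
#' @param nGroups number of groups.
#' @param repsPerGroup repeats per group (scalar recycled, or one per
#'   group — unequal values create biased group sizes).
#' @param nItems,nInformative total items and items loading on the latent
#'   axes (default: a quarter of the items, i.e. 500 of the default 2000).
#' @param nLatent number of latent axes.
#' @param latentPositions optional nGroups x nLatent matrix; default is the
#'   deterministic toxic/nontoxic layout scaled by `effectSize`.
#' @param effectSize latent effect scale (default 3).
#' @param noiseSd sd of per-cell Gaussian noise (default 1).
#' @param outlierFraction,outlierMagnitude probability that a sample is an
#'   outlier, and the size of the offset spikes it receives.
#' @param heterogeneousItemFraction fraction of informative items whose
#'   latent contribution jitters per sample (higher within-group variance).
#' @param heterogeneousGroup index of a group whose samples carry extra
#'   per-item individual noise with sd `heterogeneousSd` — small
#'   individual differences spread over many items, raising the group's
#'   within-group variance (`NA` = none).
#' @param heterogeneousSd sd of the latent jitter of heterogeneous items
#'   and of the extra individual noise of a heterogeneous group (default
#'   `effectSize`).
#' @param referenceGroup index of the reference group (default 1, the
#'   control).
#' @param referenceRule `"control_group"` or `"grand_mean"`.
#' @param groupLabels labels; default `C, G1, ..., G6` style.
#' @param seed integer RNG seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(nGroups = 7L, repsPerGroup = 5L, nItems = 2000L,
                             nInformative = ceiling(nItems / 4), nLatent = 2L,
                             latentPositions = NULL, effectSize = 3,
                             noiseSd = 1, outlierFraction = 0,
                             outlierMagnitude = 5,
                             heterogeneousItemFraction = 0,
                             heterogeneousGroup = NA_integer_,
                             heterogeneousSd = effectSize,
                             referenceGroup = 1L,
                             referenceRule = c("control_group", "grand_mean"),
                             groupLabels = NULL, seed = 1L) {
  referenceRule <- match.arg(referenceRule)
  nGroups <- as.integer(nGroups)
  reps <- as.integer(rep_len(repsPerGroup, nGroups))
  if (is.null(groupLabels))
    groupLabels <- c("C", paste0("G", seq_len(max(nGroups - 1L, 0L))))[
      seq_len(nGroups)]
  if (is.null(latentPositions))
    latentPositions <- .defaultLatentLayout(nGroups, as.integer(nLatent),
                                            effectSize)
  latentPositions <- as.matrix(latentPositions)
  rownames(latentPositions) <- groupLabels
  new("SimulationConfig", nGroups = nGroups, repsPerGroup = reps,
      nItems = as.integer(nItems), nInformative = as.integer(nInformative),
      nLatent = as.integer(nLatent), latentPositions = latentPositions,
      effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
      outlierFraction = as.numeric(outlierFraction),
      outlierMagnitude = as.numeric(outlierMagnitude),
      heterogeneousItemFraction = as.numeric(heterogeneousItemFraction),
      heterogeneousGroup = as.integer(heterogeneousGroup),
      heterogeneousSd = as.numeric(heterogeneousSd),
      referenceGroup = as.integer(referenceGroup),
      referenceRule = referenceRule,
      groupLabels = as.character(groupLabels), seed = as.integer(seed))
}

# Control at the origin; odd-numbered treatment groups ("toxic") share a
# strong axis-1 displacement and spread on axis 2; even-numbered groups
# ("nontoxic") stay near the control with small axis-2 offsets.
.defaultLatentLayout <- function(nGroups, nLatent, effectSize) {
  L <- matrix(0, nGroups, nLatent)
  if (nGroups > 1L && nLatent >= 1L) {
    treat <- seq(2L, nGroups)
    odd <- (treat %% 2L) == 0L  # groups 2,4,6 in index = G1,G3,G5 by label
    k <- seq_along(treat)
    L[treat[odd], 1L] <- effectSize
    if (nLatent >= 2L) {
      spread <- function(n) if (n > 1) seq(-1, 1, length.out = n) else 0
      L[treat[odd], 2L] <- effectSize / 2 * spread(sum(odd))
      L[treat[!odd], 2L] <- effectSize / 3 * spread(sum(!odd))
    }
  }
  L
}

#' Group labels of the "toxic" cluster in the default layout
#'
#' Convenience for classification scenarios: the treatment groups placed on
#' the strong first latent axis by the default layout of
#' [simulationConfig()].
#'
#' @param config a [SimulationConfig-class].
#' @return Character vector of group labels (possibly empty for custom
#'   layouts).
#' @export
toxicGroups <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  config@groupLabels[config@latentPositions[, 1] ==
                       max(config@latentPositions[, 1]) &
                     config@latentPositions[, 1] > 0]
}

#' Simulate a designed expression experiment
#'
#' Each item carries a baseline level; informative items additionally load
#' on the latent axes, so a sample of group g has expected value
#' `baseline + loadings %*% latent[g, ]`, plus Gaussian individual noise
#' per cell. Heterogeneous items, a heterogeneous group, and outlier
#' samples perturb this as configured. Output is bit-reproducible from the
#' seed.
#'
#' @param config a [SimulationConfig-class].
#' @return A list: `matrix` ([ExpressionMatrix-class]), `design`
#'   ([ExperimentDesign-class]), `truth` (latent positions, loadings,
#'   informative/heterogeneous item ids, outlier sample ids).
#' @examples
#' sim <- simulateExperiment(simulationConfig(nItems = 50, nInformative = 20,
#'                                            seed = 7))
#' sim$design
#' @export
simulateExperiment <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  nI <- config@nItems
  items <- sprintf("item%04d", seq_len(nI))
  groups <- rep(config@groupLabels, times = config@repsPerGroup)
  sampleIds <- unlist(lapply(seq_len(config@nGroups), function(g)
    paste0(config@groupLabels[g], "_r", seq_len(config@repsPerGroup[g]))))
  n <- length(sampleIds)
  baseline <- stats::rnorm(nI, mean = 8, sd = 1)
  informative <- if (config@nInformative > 0L)
    sort(sample.int(nI, config@nInformative)) else integer()
  loadings <- matrix(0, nI, config@nLatent)
  if (length(informative))
    loadings[informative, ] <- stats::rnorm(
      length(informative) * config@nLatent)
  nHet <- round(config@heterogeneousItemFraction * length(informative))
  hetItems <- if (nHet > 0) sort(sample(informative, nHet)) else integer()
  hetGroup <- if (!is.na(config@heterogeneousGroup))
    config@groupLabels[config@heterogeneousGroup] else NA_character_
  vals <- matrix(NA_real_, nI, n, dimnames = list(items, sampleIds))
  gIndex <- match(groups, config@groupLabels)
  for (s in seq_len(n)) {
    latent <- config@latentPositions[gIndex[s], ]
    mu <- baseline + drop(loadings %*% latent)
    if (length(hetItems)) {
      jitter <- stats::rnorm(config@nLatent, sd = config@heterogeneousSd)
      mu[hetItems] <- mu[hetItems] +
        drop(loadings[hetItems, , drop = FALSE] %*% jitter)
    }
    # a heterogeneous group's samples carry larger individual differences
    # spread over many items, not outliers in single items
    if (!is.na(hetGroup) && groups[s] == hetGroup)
      mu <- mu + stats::rnorm(nI, sd = config@heterogeneousSd)
    vals[, s] <- mu + stats::rnorm(nI, sd = config@noiseSd)
  }
  outliers <- character()
  if (config@outlierFraction > 0) {
    isOut <- stats::runif(n) < config@outlierFraction
    for (s in which(isOut)) {
      spiked <- sample.int(nI, max(1L, round(0.1 * nI)))
      vals[spiked, s] <- vals[spiked, s] +
        sample(c(-1, 1), length(spiked), replace = TRUE) *
          config@outlierMagnitude
    }
    outliers <- sampleIds[isOut]
  }
  design <- ExperimentDesign(sampleIds, groups,
    referenceRule = config@referenceRule,
    referenceGroup = config@groupLabels[config@referenceGroup],
    trainingGroups = config@groupLabels)
  list(matrix = ExpressionMatrix(vals),
       design = design,
       truth = list(latentPositions = config@latentPositions,
                    loadings = `rownames<-`(loadings, items),
                    informativeItems = items[informative],
                    heterogeneousItems = items[hetItems],
                    outlierSamples = outliers))
}

#' Simulate probe-level data for the ANOVA filter
#'
#' Per probe value = gene baseline + probe sensitivity + group effect (for
#' effect genes only) + Gaussian noise. Group effects are a centered
#' pattern whose extreme groups differ by `effectSize`. With
#' `effectSize = 0` (or no effect genes) this yields null data for type-I
#' calibration.
#'
#' @param config a [SimulationConfig-class]; supplies the group structure
#'   (`nGroups`, `repsPerGroup`), the noise sd, the gene count (`nItems`)
#'   and the seed.
#' @param probesPerGene probes per gene (>= 2).
#' @param effectGenes gene ids (or indices) carrying a group effect.
#' @param effectSize difference between the extreme groups' effects.
#' @return A list: `data` ([ProbeLevelData-class]), `design`
#'   ([ExperimentDesign-class]), `truth` (effect gene ids, group offsets).
#' @export
simulateProbeLevel <- function(config, probesPerGene = 3L,
                               effectGenes = character(), effectSize = 1) {
  stopifnot(is(config, "SimulationConfig"))
  probesPerGene <- as.integer(probesPerGene)
  if (probesPerGene < 2L) stop("probesPerGene must be >= 2")
  set.seed(config@seed)
  nGenes <- config@nItems
  geneIds <- sprintf("gene%05d", seq_len(nGenes))
  if (is.numeric(effectGenes)) effectGenes <- geneIds[effectGenes]
  bad <- setdiff(effectGenes, geneIds)
  if (length(bad)) stop("unknown effect genes: ", paste(bad, collapse = ", "))
  groups <- rep(config@groupLabels, times = config@repsPerGroup)
  sampleIds <- unlist(lapply(seq_len(config@nGroups), function(g)
    paste0(config@groupLabels[g], "_r", seq_len(config@repsPerGroup[g]))))
  G <- config@nGroups
  offsets <- if (G > 1) effectSize * ((seq_len(G) - 1) / (G - 1) - 0.5)
             else 0
  names(offsets) <- config@groupLabels
  genes <- vector("list", nGenes)
  names(genes) <- geneIds
  for (i in seq_len(nGenes)) {
    base <- stats::rnorm(1, 8, 1)
    sens <- stats::rnorm(probesPerGene)
    eff <- if (geneIds[i] %in% effectGenes) offsets[groups] else 0
    m <- base + outer(sens, rep(0, length(sampleIds)), "+") +
      rep(eff, each = probesPerGene) +
      stats::rnorm(probesPerGene * length(sampleIds), sd = config@noiseSd)
    dim(m) <- c(probesPerGene, length(sampleIds))
    dimnames(m) <- list(paste0(geneIds[i], "_p", seq_len(probesPerGene)),
                        sampleIds)
    genes[[i]] <- m
  }
  design <- ExperimentDesign(sampleIds, groups,
    referenceRule = config@referenceRule,
    referenceGroup = config@groupLabels[config@referenceGroup],
    trainingGroups = config@groupLabels)
  list(data = ProbeLevelData(genes, sampleIds), design = design,
       truth = list(effectGenes = effectGenes, groupOffsets = offsets))
}
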