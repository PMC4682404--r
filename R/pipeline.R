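#' End-to-end designed-experiment PCA
#'
#' Convenience wrapper chaining the full pipeline: reference, centering,
#' optional item exclusion (e.g. test-negative genes), training-matrix
#' construction, axis identification, projection of all samples, item
#' components, and scaling of both score sets.
#'
#' @param x an [ExpressionMatrix-class].
#' @param design an [ExperimentDesign-class].
#' @param excludeItems item ids to zero-replace before the analysis.
#' @inheritParams buildTraining
#' @inheritParams fitAxes
#' @return A list with elements `reference`, `centered`, `training`,
#'   `model`, `sampleScores` and `itemScores` (both scaled),
#'   `sampleScoresUnscaled`, `itemScoresUnscaled`, and
#'   `trainingScores` (scaled scores of the training rows).
#' @examples
#' sim <- simulateExperiment(simulationConfig(nItems = 60, nInformative = 30,
#'                                            seed = 11))
#' fit <- depcaFit(sim$matrix, sim$design)
#' fit$model
#' @export
depcaFit <- function(x, design, excludeItems = character(),
                     representative = c("mean", "trimmed_mean", "median"),
                     trimFraction = 0.2, expandGroups = character(),
                     tolRank = 1e-12) {
  representative <- match.arg(representative)
  ref <- computeReference(x, design)
  centered <- centerMatrix(x, ref)
  if (length(excludeItems)) centered <- zeroOutItems(centered, excludeItems)
  training <- buildTraining(centered, design,
                            representative = representative,
                            trimFraction = trimFraction,
                            expandGroups = expandGroups)
  model <- fitAxes(training, ref, nFunctional(centered), tolRank = tolRank)
  ys <- projectSamples(centered, model)
  yi <- itemComponents(model, training)
  list(reference = ref, centered = centered, training = training,
       model = model,
       sampleScoresUnscaled = ys, itemScoresUnscaled = yi,
       sampleScores = scaleSampleComponents(ys, nFunctional(model)),
       itemScores = scaleItemComponents(yi, nTraining(model)),
       trainingScores = trainingScores(model, scaled = TRUE))
}

#' Apply a (possibly shared) axis model to a new experiment
#'
#' Computes the reference within the new experiment using the model's
#' reference rule, centers the data, and projects onto the model's axes —
#' matching items by id, so the model may come from another laboratory or
#' item ordering. Trivial differences between experiments cancel through
#' the per-experiment reference.
#'
#' @param x an [ExpressionMatrix-class] of the new experiment.
#' @param model an [AxisModel-class] (e.g. from [loadAxisModel()]).
#' @param design optional [ExperimentDesign-class] of the new experiment;
#'   if omitted the model's own reference vector is subtracted instead of
#'   recomputing a reference in the new data.
#' @param scaled return scaled scores (default TRUE)?
#' @return A [ComponentTable-class] of sample scores.
#' @export
applyAxisModel <- function(x, model, design = NULL, scaled = TRUE) {
  stopifnot(is(x, "ExpressionMatrix"), is(model, "AxisModel"))
  ref <- if (is.null(design)) referenceVector(model)
         else computeReference(x, design)
  keep <- intersect(itemIds(x), itemIds(ref))
  if (!length(keep)) stop("no items shared with the reference")
  xSub <- ExpressionMatrix(exprValues(x)[keep, , drop = FALSE])
  centered <- centerMatrix(xSub, ref)
  ys <- projectSamples(centered, model)
  if (scaled) scaleSampleComponents(ys, nFunctional(model)) else ys
}
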