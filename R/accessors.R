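#' @rdname accessors
#' @export
setMethod("itemIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("sampleIds", "ExperimentDesign", function(x) names(x@groupOf))

#' @rdname accessors
#' @export
setMethod("groupOf", "ExperimentDesign", function(x) x@groupOf)

#' @rdname accessors
#' @export
setMethod("referenceRule", "ExperimentDesign", function(x) x@referenceRule)

#' @rdname accessors
#' @export
setMethod("trainingGroups", "ExperimentDesign", function(x) x@trainingGroups)

#' @rdname accessors
#' @export
setMethod("referenceValues", "ReferenceVector", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("itemIds", "ReferenceVector", function(x) names(x@values))

#' @rdname accessors
#' @export
setMethod("excludedItems", "ReferenceVector", function(x) x@allMissingItems)

#' @rdname accessors
#' @export
setMethod("centeredValues", "CenteredMatrix", function(x) x@X)

#' @rdname accessors
#' @export
setMethod("itemIds", "CenteredMatrix", function(x) colnames(x@X))

#' @rdname accessors
#' @export
setMethod("sampleIds", "CenteredMatrix", function(x) rownames(x@X))

#' @rdname accessors
#' @export
setMethod("excludedItems", "CenteredMatrix", function(x) x@excludedItems)

#' @rdname accessors
#' @export
setMethod("nFunctional", "CenteredMatrix", function(x) x@mf)

#' @rdname accessors
#' @export
setMethod("trainingValues", "TrainingMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("itemIds", "TrainingMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("nTraining", "TrainingMatrix", function(x) x@nt)

#' @rdname accessors
#' @export
setMethod("trainingLabels", "TrainingMatrix", function(x) x@rowInfo$label)

#' @rdname accessors
#' @export
setMethod("axisLoadings", "AxisModel", function(x) x@V)

#' @rdname accessors
#' @export
setMethod("leftVectors", "AxisModel", function(x) x@U)

#' @rdname accessors
#' @export
setMethod("singularValues", "AxisModel", function(x) x@d)

#' @rdname accessors
#' @export
setMethod("nAxes", "AxisModel", function(x) length(x@d))

#' @rdname accessors
#' @export
setMethod("itemIds", "AxisModel", function(x) rownames(x@V))

#' @rdname accessors
#' @export
setMethod("referenceVector", "AxisModel", function(x) x@reference)

#' @rdname accessors
#' @export
setMethod("nTraining", "AxisModel", function(x) x@nt)

#' @rdname accessors
#' @export
setMethod("nFunctional", "AxisModel", function(x) x@mf)

#' @rdname accessors
#' @export
setMethod("trainingLabels", "AxisModel", function(x) x@trainingLabels)

#' @rdname accessors
#' @export
setMethod("componentScores", "ComponentTable", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("isScaled", "ComponentTable", function(x) x@scaled)

#' @rdname accessors
#' @export
setMethod("rowKind", "ComponentTable", function(x) x@rowKind)

#' @rdname accessors
#' @export
setMethod("nAxes", "ComponentTable", function(x) ncol(x@scores))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ProbeLevelData", function(x) x@sampleIds)

#' @rdname accessors
#' @export
setMethod("itemIds", "ProbeLevelData", function(x) names(x@genes))

#' @rdname accessors
#' @export
setMethod("filterTable", "FilterResult", function(x) x@table)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d items x %d samples (%d missing cells)\n",
              nrow(object@values), ncol(object@values),
              sum(is.na(object@values))))
})

setMethod("show", "ExperimentDesign", function(object) {
  tab <- table(object@groupOf)
  cat(sprintf("ExperimentDesign: %d samples in %d groups; reference = %s\n",
              length(object@groupOf), length(tab),
              if (object@referenceRule == "grand_mean") "grand mean"
              else sprintf("control group '%s'", object@referenceGroup)))
  cat("  groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\n")
})

setMethod("show", "ReferenceVector", function(object) {
  cat(sprintf("ReferenceVector (%s): %d items, %d flagged all-missing\n",
              object@rule, length(object@values),
              length(object@allMissingItems)))
})

setMethod("show", "CenteredMatrix", function(object) {
  cat(sprintf(
    "CenteredMatrix: %d samples x %d items; m_f = %d (%d excluded)\n",
    nrow(object@X), ncol(object@X), object@mf, length(object@excludedItems)))
})

setMethod("show", "TrainingMatrix", function(object) {
  cat(sprintf("TrainingMatrix: n_t = %d rows (%d representatives, %d raw samples) x %d items\n",
              object@nt, sum(object@rowInfo$kind == "representative"),
              sum(object@rowInfo$kind == "sample"), ncol(object@values)))
})

setMethod("show", "AxisModel", function(object) {
  cat(sprintf("AxisModel: %d axes over %d items; n_t = %d, m_f = %d\n",
              length(object@d), nrow(object@V), object@nt, object@mf))
  cat("  singular values:",
      paste(sprintf("%.4g", utils::head(object@d, 5)), collapse = " "),
      if (length(object@d) > 5) "..." else "", "\n")
  cat("  sign convention:", object@signConvention, "\n")
})

setMethod("show", "ComponentTable", function(object) {
  cat(sprintf("ComponentTable (%s, %s): %d rows x %d axes\n",
              object@rowKind, if (object@scaled) "scaled" else "unscaled",
              nrow(object@scores), ncol(object@scores)))
})

setMethod("show", "ProbeLevelData", function(object) {
  np <- vapply(object@genes, nrow, 0L)
  cat(sprintf("ProbeLevelData: %d genes x %d samples; probes/gene %d-%d\n",
              length(object@genes), length(object@sampleIds),
              min(np), max(np)))
})

setMethod("show", "FilterResult", function(object) {
  tab <- object@table
  cat(sprintf(
    "FilterResult (alpha = %g, %s): %d positive / %d negative / %d untestable\n",
    object@alpha, object@adjust, sum(tab$positive),
    sum(tab$testable & !tab$positive), sum(!tab$testable)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d groups (reps %s), %d items (%d informative), %d latent axes, noise sd %g, seed %d\n",
    object@nGroups, paste(object@repsPerGroup, collapse = ","),
    object@nItems, object@nInformative, object@nLatent, object@noiseSd,
    object@seed))
})
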