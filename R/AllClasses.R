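#' @import methods
NULL

#' Expression matrix (items x samples)
#'
#' Thin validated container for a normalized, log-scale expression grid.
#' Rows are items (genes), columns are samples; `NA` marks missing cells.
#' Row and column names carry the item and sample identifiers and must be
#' unique.
#'
#' @slot values numeric matrix, items in rows, samples in columns, with
#'   unique dimnames.
#' @seealso [readExpressionMatrix()], [computeReference()], [centerMatrix()]
#' @export
setClass("ExpressionMatrix", slots = c(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("'values' must carry item ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(v))) return("duplicated item ids")
  if (anyDuplicated(colnames(v))) return("duplicated sample ids")
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix of expression levels (items x samples).
#' @param itemIds,sampleIds optional id vectors; default to the dimnames of
#'   `values`.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- ExpressionMatrix(matrix(1:6, 3, 2), paste0("g", 1:3), c("s1", "s2"))
#' itemIds(m)
#' @export
ExpressionMatrix <- function(values, itemIds = rownames(values),
                             sampleIds = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(itemIds, sampleIds)
  new("ExpressionMatrix", values = values)
}

#' Experimental design: sample-to-group map and reference rule
#'
#' Records which group each sample belongs to, how the reference (the center
#' of rotation of the component space) is chosen — the item-wise mean of a
#' designated control group or the grand mean of all samples — and which
#' groups enter the training data.
#'
#' @slot groupOf named character vector, sample id -> group label.
#' @slot referenceRule `"grand_mean"` or `"control_group"`.
#' @slot referenceGroup group label used when `referenceRule` is
#'   `"control_group"`, else `NA`.
#' @slot trainingGroups ordered group labels contributing training rows.
#' @export
setClass("ExperimentDesign",
  slots = c(groupOf = "character", referenceRule = "character",
            referenceGroup = "character", trainingGroups = "character"))

setValidity("ExperimentDesign", function(object) {
  if (is.null(names(object@groupOf)) || anyDuplicated(names(object@groupOf)))
    return("'groupOf' must be named by unique sample ids")
  if (!object@referenceRule %in% c("grand_mean", "control_group"))
    return("referenceRule must be 'grand_mean' or 'control_group'")
  if (object@referenceRule == "control_group" &&
      !(object@referenceGroup %in% object@groupOf))
    return(sprintf("control group '%s' has no samples", object@referenceGroup))
  if (!all(object@trainingGroups %in% object@groupOf))
    return("trainingGroups contains labels with no samples")
  if (anyDuplicated(object@trainingGroups))
    return("duplicated trainingGroups labels")
  TRUE
})

#' Construct an ExperimentDesign
#'
#' @param samples character vector of sample ids.
#' @param groups group label per sample (recycled names not allowed).
#' @param referenceRule `"grand_mean"` or `"control_group"`.
#' @param referenceGroup control-group label (required for
#'   `"control_group"`).
#' @param trainingGroups group labels whose representatives form the
#'   training data; defaults to all groups in order of first appearance.
#' @return An [ExperimentDesign-class] object.
#' @examples
#' d <- ExperimentDesign(c("a1", "a2", "b1"), c("A", "A", "B"),
#'                       referenceRule = "control_group", referenceGroup = "A")
#' @export
ExperimentDesign <- function(samples, groups,
                             referenceRule = c("grand_mean", "control_group"),
                             referenceGroup = NA_character_,
                             trainingGroups = unique(groups)) {
  referenceRule <- match.arg(referenceRule)
  stopifnot(length(samples) == length(groups))
  g <- as.character(groups)
  names(g) <- as.character(samples)
  new("ExperimentDesign", groupOf = g, referenceRule = referenceRule,
      referenceGroup = as.character(referenceGroup),
      trainingGroups = as.character(trainingGroups))
}

#' Reference vector: the center of rotation
#'
#' Per-item baseline subtracted from every sample; the origin of the
#' component space. Items whose designated reference samples were all
#' missing are recorded in `allMissingItems` and excluded downstream.
#'
#' @slot values named numeric vector, item id -> reference level.
#' @slot rule provenance: `"grand_mean"` or `"control_group"`.
#' @slot allMissingItems item ids flagged for exclusion.
#' @export
setClass("ReferenceVector",
  slots = c(values = "numeric", rule = "character",
            allMissingItems = "character"))

setValidity("ReferenceVector", function(object) {
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    return("'values' must be named by unique item ids")
  if (!all(object@allMissingItems %in% names(object@values)))
    return("allMissingItems not a subset of item ids")
  TRUE
})

#' Centered matrix X (samples x items)
#'
#' Reference-subtracted data with missing and excluded cells replaced by
#' exactly zero (the fail-safe direction: such cells pull scores toward the
#' origin, never away). `mf` is the number of functional items — items not
#' excluded — and is the divisor base for sample-score scaling.
#'
#' @slot X numeric matrix, samples in rows, items in columns.
#' @slot excludedItems item ids whose columns are zero-replaced.
#' @slot mf integer count of functional items.
#' @export
setClass("CenteredMatrix",
  slots = c(X = "matrix", excludedItems = "character", mf = "integer"))

setValidity("CenteredMatrix", function(object) {
  if (anyNA(object@X)) return("centered matrix must not contain NA")
  if (!all(object@excludedItems %in% colnames(object@X)))
    return("excludedItems not among item ids")
  if (length(object@excludedItems) &&
      any(object@X[, object@excludedItems] != 0))
    return("excluded item columns must be exactly zero")
  mf <- ncol(object@X) - length(object@excludedItems)
  if (object@mf != mf)
    return(sprintf("mf (%d) != items - excluded (%d)", object@mf, mf))
  if (object@mf < 1L) return("at least one functional item required")
  TRUE
})

#' Training matrix T of group representatives
#'
#' One row per group representative (mean, trimmed mean or median of the
#' group's centered samples) — or, for groups expanded to emulate group
#' bias, one row per raw sample. Columns are the items of the centered
#' matrix it was built from, in identical order. `nt` (the row count) is
#' the divisor base for item-score scaling.
#'
#' @slot values numeric matrix of centered representatives (rows) by items.
#' @slot rowInfo data.frame with columns `label`, `group`, `kind`
#'   (`"representative"` or `"sample"`).
#' @slot nt integer number of rows.
#' @export
setClass("TrainingMatrix",
  slots = c(values = "matrix", rowInfo = "data.frame", nt = "integer"))

setValidity("TrainingMatrix", function(object) {
  if (nrow(object@values) < 1L) return("training matrix needs >= 1 row")
  if (object@nt != nrow(object@values)) return("nt must equal the row count")
  if (nrow(object@rowInfo) != object@nt)
    return("rowInfo must describe every training row")
  if (!all(c("label", "group", "kind") %in% colnames(object@rowInfo)))
    return("rowInfo needs columns label, group, kind")
  if (is.null(colnames(object@values))) return("item ids (colnames) required")
  TRUE
})

#' Construct a TrainingMatrix directly
#'
#' Usually produced by [buildTraining()]; the constructor is exported so
#' custom training sets (e.g. replicated rows in scaling experiments) can
#' be assembled.
#'
#' @param values centered representative-by-item matrix with item colnames.
#' @param labels row labels; default rownames of `values`.
#' @param groups group label per row; defaults to `labels`.
#' @param kind `"representative"` or `"sample"` per row.
#' @return A [TrainingMatrix-class] object.
#' @export
TrainingMatrix <- function(values, labels = rownames(values), groups = labels,
                           kind = rep("representative", nrow(values))) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("row", seq_len(nrow(values)))
  rownames(values) <- labels
  new("TrainingMatrix", values = values,
      rowInfo = data.frame(label = labels, group = groups, kind = kind,
                           stringsAsFactors = FALSE),
      nt = nrow(values))
}

#' Axis model: the shareable factorization
#'
#' The result of the singular value decomposition of the training matrix,
#' T = U D V*, together with everything needed to apply the axes to new
#' data: the reference vector, the number of training rows `nt`, the number
#' of functional items `mf`, and the deterministic sign convention. `V` can
#' be serialized ([saveAxisModel()]) and shared between experiments or
#' laboratories.
#'
#' @slot V item-by-axis loadings, columns orthonormal.
#' @slot U training-row-by-axis left singular vectors, columns orthonormal.
#' @slot d singular values, non-negative, non-increasing.
#' @slot reference the [ReferenceVector-class] defining the origin.
#' @slot nt,mf integer counts (training rows; functional items).
#' @slot signConvention `"largest_loading_positive"` or `"none"`.
#' @slot trainingLabels row labels of `U`.
#' @export
setClass("AxisModel",
  slots = c(V = "matrix", U = "matrix", d = "numeric",
            reference = "ReferenceVector", nt = "integer", mf = "integer",
            signConvention = "character", trainingLabels = "character"))

setValidity("AxisModel", function(object) {
  k <- length(object@d)
  if (ncol(object@V) != k || ncol(object@U) != k)
    return("V, U and d must agree on the number of axes")
  if (k == 0L) return("no axes retained")
  if (any(object@d < 0) || is.unsorted(rev(object@d)))
    return("singular values must be non-negative and non-increasing")
  if (is.null(rownames(object@V))) return("V must carry item ids")
  # 1e-8 admits models re-read from text at %.12g; freshly fitted models are
  # orthonormal to 1e-10 and tests assert that directly.
  if (max(abs(crossprod(object@V) - diag(k))) > 1e-8)
    return("columns of V must be orthonormal")
  if (max(abs(crossprod(object@U) - diag(k))) > 1e-8)
    return("columns of U must be orthonormal")
  if (object@nt < 1L || object@mf < 1L) return("nt and mf must be >= 1")
  if (length(object@trainingLabels) != nrow(object@U))
    return("trainingLabels must label the rows of U")
  TRUE
})

#' Component table: scores of samples or items on the axes
#'
#' Unscaled scores are `Y_s = X V` (samples) or `Y_i = T* U` (items);
#' scaled scores divide by `sqrt(mf)` or `sqrt(nt)` respectively, giving a
#' size unit independent of the number of items or training rows. Column
#' names are `PC1...` (unscaled) or `sPC1...` (scaled).
#'
#' @slot scores row-entity-by-axis numeric matrix.
#' @slot rowKind `"samples"` or `"items"`.
#' @slot scaled logical flag.
#' @slot scaleDivisor the divisor applied (`NA` when unscaled).
#' @export
setClass("ComponentTable",
  slots = c(scores = "matrix", rowKind = "character", scaled = "logical",
            scaleDivisor = "numeric"))

setValidity("ComponentTable", function(object) {
  if (!object@rowKind %in% c("samples", "items"))
    return("rowKind must be 'samples' or 'items'")
  if (is.null(rownames(object@scores))) return("scores must carry row ids")
  if (object@scaled && !is.finite(object@scaleDivisor))
    return("scaled table must record its divisor")
  TRUE
})

.componentTable <- function(scores, rowKind, scaled = FALSE,
                            scaleDivisor = NA_real_) {
  colnames(scores) <- paste0(if (scaled) "sPC" else "PC",
                             seq_len(ncol(scores)))
  new("ComponentTable", scores = scores, rowKind = rowKind,
      scaled = scaled, scaleDivisor = scaleDivisor)
}

#' Probe-level data for the ANOVA filter
#'
#' Normalized probe values, one probe-by-sample matrix per gene, with a
#' shared sample panel. Genes need at least two probes (and the design at
#' least two groups) to be testable.
#'
#' @slot genes named list of numeric probe-by-sample matrices.
#' @slot sampleIds shared sample ids (column order of every matrix).
#' @export
setClass("ProbeLevelData",
  slots = c(genes = "list", sampleIds = "character"))

setValidity("ProbeLevelData", function(object) {
  if (is.null(names(object@genes)) || anyDuplicated(names(object@genes)))
    return("genes must be a named list with unique gene ids")
  ok <- vapply(object@genes, function(m)
    is.matrix(m) && ncol(m) == length(object@sampleIds), logical(1))
  if (!all(ok)) return("every gene matrix must cover the shared sample panel")
  TRUE
})

#' Construct ProbeLevelData
#'
#' @param genes named list of probe-by-sample matrices.
#' @param sampleIds shared sample ids; default: colnames of the first gene.
#' @return A [ProbeLevelData-class] object.
#' @export
ProbeLevelData <- function(genes, sampleIds = colnames(genes[[1]])) {
  genes <- lapply(genes, function(m) {
    m <- as.matrix(m); colnames(m) <- sampleIds; m
  })
  new("ProbeLevelData", genes = genes, sampleIds = as.character(sampleIds))
}

#' Result of the per-gene group-effect test
#'
#' One row per gene with the group-effect p value, the positive flag at the
#' chosen threshold, and testability. Positive means p < alpha; untestable
#' genes are never positive.
#'
#' @slot table data.frame with columns `gene_id`, `p_value`, `positive`,
#'   `testable`.
#' @slot alpha the significance threshold used.
#' @slot adjust `"none"` or `"BH"`.
#' @export
setClass("FilterResult",
  slots = c(table = "data.frame", alpha = "numeric", adjust = "character"))

setValidity("FilterResult", function(object) {
  need <- c("gene_id", "p_value", "positive", "testable")
  if (!all(need %in% colnames(object@table)))
    return("table needs columns gene_id, p_value, positive, testable")
  tab <- object@table
  if (any(tab$positive & !tab$testable))
    return("untestable genes can never be positive")
  if (object@alpha <= 0 && any(tab$positive))
    return("alpha <= 0 admits no positives")
  TRUE
})

#' Simulation configuration for designed expression experiments
#'
#' Parameterizes group-structured synthetic data: groups with repeated
#' measurements placed at latent positions on a small number of latent
#' axes, informative items loading on those axes, Gaussian individual
#' noise, optional outlier samples (offset spikes), optional
#' within-group-heterogeneous items, and an optional heterogeneous group
#' whose samples jitter around their latent position. Fully reproducible
#' from `seed`.
#'
#' @slot nGroups,nItems,nInformative,nLatent integer counts.
#' @slot repsPerGroup integer vector of repeats, one per group.
#' @slot latentPositions nGroups x nLatent matrix of latent group positions.
#' @slot effectSize scale of the default latent layout.
#' @slot noiseSd sd of per-cell Gaussian individual noise.
#' @slot outlierFraction,outlierMagnitude outlier-sample rate and spike size.
#' @slot heterogeneousItemFraction fraction of informative items with
#'   per-sample latent jitter (high within-group variance regime).
#' @slot heterogeneousGroup group index whose samples carry extra
#'   per-item individual noise (NA = none).
#' @slot heterogeneousSd sd of the latent jitter / extra noise.
#' @slot referenceGroup index of the reference (control) group.
#' @slot referenceRule `"control_group"` or `"grand_mean"`.
#' @slot groupLabels group labels.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  slots = c(nGroups = "integer", repsPerGroup = "integer", nItems = "integer",
            nInformative = "integer", nLatent = "integer",
            latentPositions = "matrix", effectSize = "numeric",
            noiseSd = "numeric", outlierFraction = "numeric",
            outlierMagnitude = "numeric",
            heterogeneousItemFraction = "numeric",
            heterogeneousGroup = "integer", heterogeneousSd = "numeric",
            referenceGroup = "integer", referenceRule = "character",
            groupLabels = "character", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nGroups < 1L || object@nItems < 1L || object@nLatent < 1L)
    return("counts must be positive")
  if (length(object@repsPerGroup) != object@nGroups ||
      any(object@repsPerGroup < 1L))
    return("repsPerGroup needs one entry >= 1 per group")
  if (object@nInformative > object@nItems)
    return("nInformative exceeds nItems")
  if (object@nInformative < 0L) return("nInformative must be >= 0")
  frac <- c(object@outlierFraction, object@heterogeneousItemFraction)
  if (any(frac < 0 | frac > 1)) return("fractions must lie in [0, 1]")
  if (!all(dim(object@latentPositions) == c(object@nGroups, object@nLatent)))
    return("latentPositions must be nGroups x nLatent")
  if (object@referenceGroup < 1L || object@referenceGroup > object@nGroups)
    return("referenceGroup out of range")
  if (length(object@groupLabels) != object@nGroups)
    return("one label per group required")
  TRUE
})
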