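#' Identify orthogonal axes in the training data
#'
#' Singular value decomposition of the training matrix, T = U D V*. No
#' additional row or column centering is applied to T: the reference
#' already defines the center of rotation, and re-centering would
#' reintroduce the grand-mean origin the method deliberately replaces.
#' Axes whose singular value falls below `tolRank` times the largest are
#' numerically null and dropped, and at most `min(n_t, m_f)` axes are
#' retained. Signs are made deterministic via [unifySigns()].
#'
#' @param training a [TrainingMatrix-class].
#' @param reference the [ReferenceVector-class] that centered the data.
#' @param mf number of functional items of the centered matrix the training
#'   data came from (see [nFunctional()]).
#' @param tolRank relative singular-value cutoff (default 1e-12).
#' @param signConvention `"largest_loading_positive"` (default) or
#'   `"none"`.
#' @return An [AxisModel-class]: loadings `V`, left vectors `U`, singular
#'   values, reference, `n_t`, `m_f`.
#' @examples
#' tm <- TrainingMatrix(matrix(c(3, 0, 0, 4), 2,
#'                      dimnames = list(c("A", "B"), c("g1", "g2"))))
#' ref <- new("ReferenceVector", values = c(g1 = 0, g2 = 0),
#'            rule = "grand_mean", allMissingItems = character())
#' singularValues(fitAxes(tm, ref, mf = 2))
#' @export
fitAxes <- function(training, reference, mf, tolRank = 1e-12,
                    signConvention = c("largest_loading_positive", "none")) {
  stopifnot(is(training, "TrainingMatrix"), is(reference, "ReferenceVector"))
  signConvention <- match.arg(signConvention)
  Tm <- trainingValues(training)
  if (all(Tm == 0))
    stop("training data identical to reference: nothing to decompose")
  s <- svd(Tm)
  keep <- min(sum(s$d >= tolRank * s$d[1]), nTraining(training), mf)
  idx <- seq_len(keep)
  V <- s$v[, idx, drop = FALSE]
  U <- s$u[, idx, drop = FALSE]
  rownames(V) <- itemIds(training)
  rownames(U) <- trainingLabels(training)
  colnames(V) <- colnames(U) <- paste0("axis", idx)
  model <- new("AxisModel", V = V, U = U, d = s$d[idx],
               reference = reference, nt = nTraining(training),
               mf = as.integer(mf), signConvention = "none",
               trainingLabels = trainingLabels(training))
  if (signConvention == "largest_loading_positive") unifySigns(model)
  else model
}

#' Make axis signs deterministic
#'
#' An SVD determines each axis only up to a joint sign of the matched
#' columns of V and U. For each axis the loading of largest absolute value
#' is made positive (ties broken by the lowest item index) by negating both
#' columns together, which preserves the reconstruction U D V* = T exactly.
#'
#' @param model an [AxisModel-class].
#' @return The model with unified signs; idempotent.
#' @export
unifySigns <- function(model) {
  stopifnot(is(model, "AxisModel"))
  V <- model@V; U <- model@U
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))  # ties resolve to the lowest index
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  initialize(model, V = V, U = U, signConvention = "largest_loading_positive")
}

#' Project samples onto the model's axes
#'
#' Sample components Y_s = X V. Items are matched by id against the model:
#' model items absent from the matrix contribute zero (fail-safe — scores
#' move toward the origin, never away), and matrix items unknown to the
#' model are dropped; both counts are reported via `message()`.
#'
#' @param x a [CenteredMatrix-class] (centered on the model's reference,
#'   or on an equivalent reference found in the new experiment).
#' @param model an [AxisModel-class].
#' @return A [ComponentTable-class] of unscaled sample scores (`PC1...`).
#' @export
projectSamples <- function(x, model) {
  stopifnot(is(x, "CenteredMatrix"), is(model, "AxisModel"))
  modelItems <- itemIds(model)
  common <- intersect(itemIds(x), modelItems)
  if (!length(common))
    stop("no items shared between the matrix and the axis model")
  dropped <- setdiff(itemIds(x), modelItems)
  zeroFilled <- setdiff(modelItems, itemIds(x))
  if (length(dropped))
    message(length(dropped), " matrix item(s) unknown to the model dropped")
  if (length(zeroFilled))
    message(length(zeroFilled), " model item(s) absent from the matrix ",
            "contribute zero")
  X <- centeredValues(x)
  Xr <- matrix(0, nrow(X), length(modelItems),
               dimnames = list(rownames(X), modelItems))
  Xr[, common] <- X[, common]
  .componentTable(Xr %*% axisLoadings(model), "samples")
}

#' Item components on the model's axes
#'
#' Item components Y_i = T* U for the training matrix the model was fitted
#' on; algebraically equal to V D, so items and samples live on identical
#' axes (the basis of the joint, biplot-like presentation).
#'
#' @param model an [AxisModel-class].
#' @param training the [TrainingMatrix-class] the model was fitted on.
#' @return A [ComponentTable-class] of unscaled item scores.
#' @export
itemComponents <- function(model, training) {
  stopifnot(is(model, "AxisModel"), is(training, "TrainingMatrix"))
  Tm <- trainingValues(training)
  if (nrow(Tm) != nrow(leftVectors(model)) ||
      !identical(colnames(Tm), itemIds(model)))
    stop("training matrix does not match the model (rows or item ids differ)")
  .componentTable(t(Tm) %*% leftVectors(model), "items")
}

#' Scores of the training representatives
#'
#' The training rows projected on their own axes, U D — identical to
#' `projectSamples()` applied to the training rows. These are the group
#' representatives' positions used for nearest-representative
#' classification and for the joint table.
#'
#' @param model an [AxisModel-class].
#' @param scaled divide by `sqrt(m_f)` (sample-score scaling)?
#' @return A [ComponentTable-class] (`rowKind` `"samples"`).
#' @export
trainingScores <- function(model, scaled = FALSE) {
  stopifnot(is(model, "AxisModel"))
  sc <- leftVectors(model) %*% diag(singularValues(model),
                                    nrow = nAxes(model))
  rownames(sc) <- trainingLabels(model)
  out <- .componentTable(sc, "samples")
  if (scaled) scaleSampleComponents(out, nFunctional(model)) else out
}
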