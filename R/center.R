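#' Compute the reference vector (center of rotation)
#'
#' The reference is the item-wise mean over a designated sample set: all
#' samples under the grand-mean rule, or the control group's samples under
#' the control-group rule. Missing cells are ignored; an item whose
#' designated cells are all missing gets reference 0 and is flagged for
#' exclusion downstream.
#'
#' @param x an [ExpressionMatrix-class].
#' @param design an [ExperimentDesign-class] covering the samples of `x`.
#' @return A [ReferenceVector-class].
#' @examples
#' m <- ExpressionMatrix(matrix(c(1, 2, 3, 2), 2,
#'                       dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' d <- ExperimentDesign(c("s1", "s2"), c("ctrl", "ctrl"),
#'                       "control_group", "ctrl")
#' referenceValues(computeReference(m, d))
#' @export
computeReference <- function(x, design) {
  stopifnot(is(x, "ExpressionMatrix"), is(design, "ExperimentDesign"))
  g <- groupOf(design)
  missingDesign <- setdiff(sampleIds(x), names(g))
  if (length(missingDesign))
    stop("samples without a group in the design: ",
         paste(missingDesign, collapse = ", "))
  sel <- if (referenceRule(design) == "grand_mean") sampleIds(x)
         else intersect(sampleIds(x),
                        names(g)[g == design@referenceGroup])
  if (!length(sel))
    stop(sprintf("reference rule '%s' designates no samples in the matrix",
                 if (referenceRule(design) == "grand_mean") "grand_mean"
                 else paste0("control_group(", design@referenceGroup, ")")))
  vals <- exprValues(x)[, sel, drop = FALSE]
  nObs <- rowSums(!is.na(vals))
  r <- rowMeans(vals, na.rm = TRUE)
  allMissing <- rownames(vals)[nObs == 0L]
  r[nObs == 0L] <- 0
  new("ReferenceVector", values = r, rule = referenceRule(design),
      allMissingItems = allMissing)
}

#' Center an expression matrix on a reference
#'
#' Subtracts the per-item reference from every sample and transposes to the
#' internal sample-by-item orientation. Missing cells become exactly 0 —
#' zero means "no difference from the reference", so missing data pull
#' scores toward the origin (fail-safe), never away. Items the reference
#' flagged as all-missing are excluded (zeroed) and `m_f` reduced
#' accordingly.
#'
#' @param x an [ExpressionMatrix-class].
#' @param reference a [ReferenceVector-class] covering every item of `x`.
#' @return A [CenteredMatrix-class] (samples x items).
#' @seealso [zeroOutItems()] for removing further items (e.g. test-negative
#'   genes) the same way.
#' @export
centerMatrix <- function(x, reference) {
  stopifnot(is(x, "ExpressionMatrix"), is(reference, "ReferenceVector"))
  miss <- setdiff(itemIds(x), itemIds(reference))
  if (length(miss))
    stop("reference does not cover items: ", paste(miss, collapse = ", "))
  r <- referenceValues(reference)[itemIds(x)]
  X <- t(exprValues(x) - r)
  X[is.na(X)] <- 0
  excl <- intersect(excludedItems(reference), itemIds(x))
  if (length(excl)) X[, excl] <- 0
  mf <- ncol(X) - length(excl)
  if (mf < 1L) stop("no functional items remain after exclusion")
  new("CenteredMatrix", X = X, excludedItems = excl, mf = as.integer(mf))
}

#' Zero-replace item columns (fail-safe removal)
#'
#' Sets the listed items' columns to exactly zero — the same replacement
#' used for missing data — so they contribute nothing to any inner product
#' with the loadings; scores move toward the origin, never away. The items
#' join `excludedItems` and `m_f` drops accordingly; the matrix shape is
#' unchanged.
#'
#' @param x a [CenteredMatrix-class].
#' @param items item ids to remove (typically ANOVA-negative genes).
#' @return The updated [CenteredMatrix-class].
#' @export
zeroOutItems <- function(x, items) {
  stopifnot(is(x, "CenteredMatrix"))
  items <- as.character(items)
  unknown <- setdiff(items, itemIds(x))
  if (length(unknown))
    stop("unknown item ids: ", paste(unknown, collapse = ", "))
  if (!length(items)) return(x)
  X <- centeredValues(x)
  X[, items] <- 0
  excl <- union(excludedItems(x), items)
  mf <- ncol(X) - length(excl)
  if (mf < 1L) stop("zeroing these items would leave no functional items")
  new("CenteredMatrix", X = X, excludedItems = excl, mf = as.integer(mf))
}
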