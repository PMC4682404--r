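#' Build the training matrix of group representatives
#'
#' One row per training group, computed as the mean, trimmed mean or median
#' of that group's centered sample rows. Taking means of repeats reduces
#' measurement noise; trimmed means or medians further reduce the effect of
#' outlier samples. Groups listed in `expandGroups` contribute all their
#' raw sample rows instead of a representative — the device used to emulate
#' group bias (a group over-represented in the data used to find axes).
#'
#' @param x a [CenteredMatrix-class].
#' @param design an [ExperimentDesign-class]; its `trainingGroups` order the
#'   rows.
#' @param representative `"mean"`, `"trimmed_mean"` or `"median"`.
#' @param trimFraction trim fraction per tail for `"trimmed_mean"`
#'   (default 0.2). Groups with fewer than 5 samples fall back to the plain
#'   mean with a warning; a fraction that would trim away a whole group
#'   (`ceiling(2 * f * n) >= n`) is an error.
#' @param expandGroups group labels contributing raw samples instead of a
#'   representative.
#' @return A [TrainingMatrix-class]; `nTraining()` is the total row count.
#' @export
buildTraining <- function(x, design,
                          representative = c("mean", "trimmed_mean", "median"),
                          trimFraction = 0.2, expandGroups = character()) {
  stopifnot(is(x, "CenteredMatrix"), is(design, "ExperimentDesign"))
  representative <- match.arg(representative)
  expandGroups <- as.character(expandGroups)
  bad <- setdiff(expandGroups, trainingGroups(design))
  if (length(bad))
    stop("expandGroups not among training groups: ",
         paste(bad, collapse = ", "))
  g <- groupOf(design)
  X <- centeredValues(x)
  rows <- list(); labels <- character(); groups <- character()
  kinds <- character()
  for (grp in trainingGroups(design)) {
    members <- intersect(rownames(X), names(g)[g == grp])
    if (!length(members))
      stop(sprintf("training group '%s' has no samples in the matrix", grp))
    Xg <- X[members, , drop = FALSE]
    if (grp %in% expandGroups) {
      for (s in members) {
        rows[[length(rows) + 1L]] <- Xg[s, ]
        labels <- c(labels, s); groups <- c(groups, grp)
        kinds <- c(kinds, "sample")
      }
      next
    }
    rep <- switch(representative,
      mean = colMeans(Xg),
      median = apply(Xg, 2, stats::median),
      trimmed_mean = {
        n <- nrow(Xg)
        if (n < 5L) {
          warning(sprintf(
            "group '%s' has %d samples (< 5); trimmed mean degrades to mean",
            grp, n))
          colMeans(Xg)
        } else {
          if (ceiling(2 * trimFraction * n) >= n)
            stop(sprintf(
              "trim fraction %g would trim all %d samples of group '%s'",
              trimFraction, n, grp))
          apply(Xg, 2, mean, trim = trimFraction)
        }
      })
    rows[[length(rows) + 1L]] <- rep
    labels <- c(labels, grp); groups <- c(groups, grp)
    kinds <- c(kinds, "representative")
  }
  values <- do.call(rbind, rows)
  colnames(values) <- itemIds(x)
  TrainingMatrix(values, labels = labels, groups = groups, kind = kinds)
}
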