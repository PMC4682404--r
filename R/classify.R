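#' Classify samples by nearest training representative
#'
#' Euclidean distance in the leading `nAxesUsed` component dimensions
#' between each sample and each training representative; each sample gets
#' the label of its nearest representative (ties broken by training-row
#' order). With a shared axis model this classifies unknown samples on
#' pre-arranged axes.
#'
#' @param samples a [ComponentTable-class] of sample scores.
#' @param training a [ComponentTable-class] of training-representative
#'   scores from the same model (see [trainingScores()]); both tables must
#'   be scaled, or both unscaled, with equal axis counts.
#' @param nAxesUsed number of leading axes for the distance (default: all).
#' @return A data.frame with columns `sample_id`, `nearest`, `distance`,
#'   and one `dist.<label>` column per training representative.
#' @export
classifySamples <- function(samples, training, nAxesUsed = NULL) {
  stopifnot(is(samples, "ComponentTable"), is(training, "ComponentTable"))
  if (isScaled(samples) != isScaled(training))
    stop("sample and training tables must both be scaled or both unscaled")
  if (nAxes(samples) != nAxes(training))
    stop(sprintf("axis counts differ: samples have %d, training has %d",
                 nAxes(samples), nAxes(training)))
  if (is.null(nAxesUsed)) nAxesUsed <- nAxes(samples)
  if (nAxesUsed < 1L || nAxesUsed > nAxes(samples))
    stop("nAxesUsed out of range")
  ax <- seq_len(nAxesUsed)
  S <- componentScores(samples)[, ax, drop = FALSE]
  R <- componentScores(training)[, ax, drop = FALSE]
  d2 <- outer(rowSums(S^2), rowSums(R^2), "+") - 2 * S %*% t(R)
  d <- sqrt(pmax(d2, 0))
  nearest <- max.col(-d, ties.method = "first")
  labels <- rownames(R)
  out <- data.frame(sample_id = rownames(S), nearest = labels[nearest],
                    distance = d[cbind(seq_len(nrow(d)), nearest)],
                    stringsAsFactors = FALSE, row.names = NULL)
  dists <- as.data.frame(d)
  colnames(dists) <- paste0("dist.", labels)
  cbind(out, dists)
}
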