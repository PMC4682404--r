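#' Scale sample components to a size unit independent of item count
#'
#' A sample score grows proportionally to the square root of the number of
#' functional items contributing to it (each loading column is a unit
#' vector over m_f items, so each of the m_f summands of the inner product
#' contributes on the order of m_f^(-1/2)). Dividing by sqrt(m_f) yields
#' the average contribution per item, Z_s = m_f^(-1/2) Y_s, making scores
#' comparable across analyses that used different item sets. The singular
#' values are not cancelled, so the ratios among axes are retained.
#'
#' @param x an unscaled [ComponentTable-class] of sample scores.
#' @param mf number of functional items (>= 1).
#' @return The scaled table (`sPC1...`), with the divisor recorded.
#' @export
scaleSampleComponents <- function(x, mf) {
  .scaleComponents(x, mf, "m_f")
}

#' Scale item components to a size unit independent of training size
#'
#' The item-score analogue: Z_i = n_t^(-1/2) Y_i, where n_t is the number
#' of rows of the training matrix in which U was found. After both
#' scalings, sample and item scores have comparable magnitudes and can be
#' presented together ([jointComponentTable()]).
#'
#' @param x an unscaled [ComponentTable-class] of item scores.
#' @param nt number of training rows (>= 1).
#' @return The scaled table.
#' @export
scaleItemComponents <- function(x, nt) {
  .scaleComponents(x, nt, "n_t")
}

.scaleComponents <- function(x, count, what) {
  stopifnot(is(x, "ComponentTable"))
  if (isScaled(x)) stop("component table is already scaled")
  count <- as.numeric(count)
  if (length(count) != 1L || !is.finite(count) || count < 1)
    stop(what, " must be a single count >= 1")
  divisor <- sqrt(count)
  .componentTable(componentScores(x) / divisor, rowKind(x),
                  scaled = TRUE, scaleDivisor = divisor)
}
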