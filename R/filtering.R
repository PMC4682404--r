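#' Per-gene two-way ANOVA group-effect test on probe-level data
#'
#' For each gene, a fixed-effects additive two-factor model is fitted to
#' the normalized probe values: value ~ probe + group (probe sensitivity
#' plus group effect, no interaction). The F statistic of the group factor
#' yields the gene's p value, and genes with p below `alpha` (default
#' 0.01, uncorrected, per gene) are called positive; negative genes are
#' typically removed from the centered matrix with [zeroOutItems()].
#'
#' Genes with fewer than two probes, designs with fewer than two groups,
#' zero residual degrees of freedom, or missing values are flagged
#' untestable (never positive, never an error). Genes whose values are
#' constant have an undefined F and are likewise not positive.
#'
#' Least squares is solved once per probe-count batch on the shared design
#' matrix with a multi-response QR, which gives the same F statistic as a
#' per-gene `anova(lm(...))` fit.
#'
#' @param data a [ProbeLevelData-class].
#' @param design an [ExperimentDesign-class] covering the sample panel.
#' @param alpha significance threshold (default 0.01).
#' @param adjust `"none"` (default; the raw per-gene threshold) or `"BH"`
#'   for Benjamini-Hochberg FDR on the testable genes.
#' @return A [FilterResult-class].
#' @export
anovaGroupTest <- function(data, design, alpha = 0.01,
                           adjust = c("none", "BH")) {
  stopifnot(is(data, "ProbeLevelData"), is(design, "ExperimentDesign"))
  adjust <- match.arg(adjust)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  g <- groupOf(design)
  miss <- setdiff(sampleIds(data), names(g))
  if (length(miss))
    stop("samples without a group in the design: ",
         paste(miss, collapse = ", "))
  grp <- factor(g[sampleIds(data)])
  G <- nlevels(grp)
  S <- length(sampleIds(data))
  geneIds <- itemIds(data)
  p <- rep(NA_real_, length(geneIds))
  names(p) <- geneIds
  nProbes <- vapply(data@genes, nrow, 0L)
  hasNA <- vapply(data@genes, anyNA, logical(1))
  for (np in unique(nProbes)) {
    idx <- which(nProbes == np & !hasNA)
    if (!length(idx) || np < 2L || G < 2L) next
    dfr <- np * S - np - G + 1L  # residual df of the additive model
    if (dfr < 1L) next
    probe <- factor(rep(seq_len(np), times = S))
    group <- factor(rep(as.character(grp), each = np))
    M1 <- stats::model.matrix(~ probe + group)
    M0 <- stats::model.matrix(~ probe)
    Y <- vapply(data@genes[idx], as.vector, numeric(np * S))
    rss1 <- colSums(qr.resid(qr(M1), Y)^2)
    rss0 <- colSums(qr.resid(qr(M0), Y)^2)
    f <- (pmax(rss0 - rss1, 0) / (G - 1)) / (rss1 / dfr)
    # constant genes: no variation left after the probe term, F undefined
    degenerate <- rss0 <= 1e-20 * pmax(colSums(Y^2), .Machine$double.xmin)
    f[degenerate] <- NA_real_
    p[idx] <- stats::pf(f, G - 1, dfr, lower.tail = FALSE)
  }
  testable <- !is.na(p)
  pUsed <- p
  if (adjust == "BH") pUsed[testable] <- stats::p.adjust(p[testable], "BH")
  positive <- testable & !is.na(pUsed) & pUsed < alpha
  tab <- data.frame(gene_id = geneIds, p_value = unname(p),
                    positive = unname(positive), testable = unname(testable),
                    stringsAsFactors = FALSE)
  new("FilterResult", table = tab, alpha = alpha, adjust = adjust)
}

#' One-way group test on gene-level values
#'
#' Fallback for experiments without probe-level data: per gene, a one-way
#' fixed-effects ANOVA of the gene-level expression values on the group
#' factor. This approximates the probe-level two-way test — the probe
#' sensitivity term has already been absorbed by the summarization — and
#' is labeled as such.
#'
#' @param x an [ExpressionMatrix-class].
#' @param design an [ExperimentDesign-class].
#' @inheritParams anovaGroupTest
#' @return A [FilterResult-class].
#' @export
geneLevelGroupTest <- function(x, design, alpha = 0.01,
                               adjust = c("none", "BH")) {
  stopifnot(is(x, "ExpressionMatrix"), is(design, "ExperimentDesign"))
  adjust <- match.arg(adjust)
  g <- groupOf(design)
  miss <- setdiff(sampleIds(x), names(g))
  if (length(miss))
    stop("samples without a group in the design: ",
         paste(miss, collapse = ", "))
  grp <- factor(g[sampleIds(x)])
  G <- nlevels(grp)
  vals <- exprValues(x)
  p <- rep(NA_real_, nrow(vals))
  names(p) <- rownames(vals)
  if (G >= 2L) {
    dfr <- ncol(vals) - G
    complete <- !apply(vals, 1, anyNA)
    if (dfr >= 1L && any(complete)) {
      M1 <- stats::model.matrix(~ grp)
      Y <- t(vals[complete, , drop = FALSE])
      rss1 <- colSums(qr.resid(qr(M1), Y)^2)
      rss0 <- colSums(scale(Y, scale = FALSE)^2)
      f <- (pmax(rss0 - rss1, 0) / (G - 1)) / (rss1 / dfr)
      degenerate <- rss0 <= 1e-20 * pmax(colSums(Y^2), .Machine$double.xmin)
      f[degenerate] <- NA_real_
      p[complete] <- stats::pf(f, G - 1, dfr, lower.tail = FALSE)
    }
    for (i in which(!complete)) {
      ok <- !is.na(vals[i, ])
      gi <- droplevels(grp[ok])
      if (nlevels(gi) < 2L || sum(ok) - nlevels(gi) < 1L) next
      fit <- stats::anova(stats::lm(vals[i, ok] ~ gi))
      p[i] <- fit[["Pr(>F)"]][1]
    }
  }
  testable <- !is.na(p)
  pUsed <- p
  if (adjust == "BH") pUsed[testable] <- stats::p.adjust(p[testable], "BH")
  positive <- testable & !is.na(pUsed) & pUsed < alpha
  tab <- data.frame(gene_id = names(p), p_value = unname(p),
                    positive = unname(positive), testable = unname(testable),
                    stringsAsFactors = FALSE)
  new("FilterResult", table = tab, alpha = alpha, adjust = adjust)
}

#' Split a filter result into positive and negative item sets
#'
#' Partitions the testable genes; the negative set is what
#' [zeroOutItems()] receives. Untestable genes belong to neither set.
#'
#' @param result a [FilterResult-class].
#' @return A list with character vectors `positive` and `negative`.
#' @export
selectItems <- function(result) {
  stopifnot(is(result, "FilterResult"))
  tab <- filterTable(result)
  list(positive = tab$gene_id[tab$positive],
       negative = tab$gene_id[tab$testable & !tab$positive])
}
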