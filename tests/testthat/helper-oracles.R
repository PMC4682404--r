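# Shared fixtures and independent oracles for the suite.

# CenteredMatrix straight from a sample-by-item grid (tests that start from
# already-centered data).
makeCentered <- function(X, excluded = character()) {
  new("CenteredMatrix", X = X, excludedItems = excluded,
      mf = as.integer(ncol(X) - length(excluded)))
}

zeroRef <- function(items) {
  new("ReferenceVector",
      values = stats::setNames(rep(0, length(items)), items),
      rule = "grand_mean", allMissingItems = character())
}

randX <- function(n, m, seed) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m,
         dimnames = list(paste0("s", seq_len(n)), paste0("g", seq_len(m))))
}

# Fit axes treating every row of X as its own training row (T = X).
fitOn <- function(X, mf = ncol(X)) {
  fitAxes(TrainingMatrix(X), zeroRef(colnames(X)), mf = mf)
}

# Flip columns of x so each correlates positively with the matching column
# of ref (axes are defined up to a joint sign).
alignSigns <- function(ref, x) {
  s <- sign(colSums(ref * x))
  s[s == 0] <- 1
  sweep(x, 2, s, "*")
}

# Duplicate every item column k times under fresh unique ids.
duplicateItems <- function(X, k) {
  Xd <- X[, rep(seq_len(ncol(X)), times = k), drop = FALSE]
  colnames(Xd) <- paste0(rep(colnames(X), times = k), "_c",
                         rep(seq_len(k), each = ncol(X)))
  Xd
}

# Independent elementwise reconstruction sum_a U[i,a] d[a] V[j,a].
naiveReconstruct <- function(U, d, V) {
  out <- matrix(0, nrow(U), nrow(V))
  for (i in seq_len(nrow(U)))
    for (j in seq_len(nrow(V)))
      out[i, j] <- sum(U[i, ] * d * V[j, ])
  out
}

# Explicit per-pair Euclidean distance.
naiveDist <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      out[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
  out
}

# Group-effect F test by explicit sum-of-squares decomposition of the
# balanced additive two-way layout (probe x group, equal samples per group
# cell within each probe).
ssAnovaOracle <- function(mat, groups) {
  y <- as.vector(mat)
  probe <- factor(rep(seq_len(nrow(mat)), times = ncol(mat)))
  group <- factor(rep(groups, each = nrow(mat)))
  grand <- mean(y)
  ssProbe <- sum(tapply(y, probe, length) *
                   (tapply(y, probe, mean) - grand)^2)
  ssGroup <- sum(tapply(y, group, length) *
                   (tapply(y, group, mean) - grand)^2)
  fitted <- tapply(y, probe, mean)[probe] + tapply(y, group, mean)[group] -
    grand
  ssRes <- sum((y - fitted)^2)
  dfG <- nlevels(group) - 1
  dfR <- length(y) - nlevels(probe) - nlevels(group) + 1
  f <- (ssGroup / dfG) / (ssRes / dfR)
  list(F = f, p = pf(f, dfG, dfR, lower.tail = FALSE))
}
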