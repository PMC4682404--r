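.fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))

.parseNumeric <- function(fields, line, path) {
  fields[fields == "NA" | fields == ""] <- NA
  out <- suppressWarnings(as.numeric(fields))
  bad <- which(is.na(out) & !is.na(fields))
  if (length(bad))
    stop(sprintf("%s line %d: non-numeric cell '%s'", path, line,
                 fields[bad[1]]))
  out
}

#' Read an expression matrix from tab-delimited text
#'
#' First column holds item ids, the header row holds sample ids, cells are
#' numeric; `NA` or an empty field marks a missing value (files are
#' item-by-sample, the GEO series-matrix convention; the transpose to the
#' internal sample-by-item orientation happens once, at centering).
#'
#' @param path file path.
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop(path, ": need a header and at least one item")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  nf <- length(header)
  if (nf < 2L) stop(path, " line 1: need an id column and >= 1 sample")
  sampleIds <- header[-1]
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  vals <- matrix(NA_real_, length(parts), nf - 1L)
  ids <- character(length(parts))
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    # a trailing missing cell drops the last field in strsplit output
    if (length(f) == nf - 1L && grepl("\t$", body[i])) f <- c(f, "")
    if (length(f) != nf)
      stop(sprintf("%s line %d: %d fields, expected %d", path, i + 1L,
                   length(f), nf))
    ids[i] <- f[1]
    vals[i, ] <- .parseNumeric(f[-1], i + 1L, path)
  }
  if (anyDuplicated(ids))
    stop(path, ": duplicated item ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(sampleIds))
    stop(path, ": duplicated sample ids")
  dimnames(vals) <- list(ids, sampleIds)
  ExpressionMatrix(vals)
}

#' Write an expression matrix as tab-delimited text
#'
#' Numeric cells at `%.12g` precision; missing cells written as `NA`.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  vals <- exprValues(x)
  lines <- c(paste(c("item_id", colnames(vals)), collapse = "\t"),
             vapply(seq_len(nrow(vals)), function(i)
               paste(c(rownames(vals)[i], .fmt(vals[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a design table
#'
#' Tab-delimited with columns `sample_id`, `group` and optionally
#' `is_reference` (TRUE/1 on the rows of the control group). If any
#' reference flag is set, the reference rule is `control_group` with that
#' group; otherwise `grand_mean` — unless overridden by `referenceRule`.
#'
#' @param path file path.
#' @param referenceRule optional override (`"grand_mean"` or
#'   `"control_group"`).
#' @param referenceGroup control-group label when overriding to
#'   `"control_group"`.
#' @return An [ExperimentDesign-class].
#' @export
readDesign <- function(path, referenceRule = NULL, referenceGroup = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(tab)))
    stop(path, ": design needs columns sample_id and group")
  rule <- "grand_mean"; refGroup <- NA_character_
  if ("is_reference" %in% colnames(tab)) {
    flag <- tab$is_reference %in% c(TRUE, "TRUE", "true", 1, "1")
    if (any(flag)) {
      refGroup <- unique(tab$group[flag])
      if (length(refGroup) != 1L)
        stop(path, ": is_reference flags more than one group")
      rule <- "control_group"
    }
  }
  if (!is.null(referenceRule)) {
    rule <- match.arg(referenceRule, c("grand_mean", "control_group"))
    if (rule == "control_group") {
      if (!is.null(referenceGroup)) refGroup <- referenceGroup
      if (is.na(refGroup))
        stop("control_group rule requires a reference group")
    }
  }
  ExperimentDesign(tab$sample_id, tab$group, referenceRule = rule,
                   referenceGroup = refGroup)
}

#' Write a design table
#'
#' @param design an [ExperimentDesign-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeDesign <- function(design, path) {
  stopifnot(is(design, "ExperimentDesign"))
  g <- groupOf(design)
  isRef <- if (referenceRule(design) == "control_group")
    g == design@referenceGroup else rep(FALSE, length(g))
  lines <- c("sample_id\tgroup\tis_reference",
             paste(names(g), g, ifelse(isRef, "TRUE", "FALSE"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read probe-level data
#'
#' Tab-delimited with columns `gene_id`, `probe_id`, then one column per
#' sample.
#'
#' @param path file path.
#' @return A [ProbeLevelData-class].
#' @export
readProbeLevel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "probe_id") %in% colnames(tab)))
    stop(path, ": probe-level data needs columns gene_id and probe_id")
  sampleIds <- setdiff(colnames(tab), c("gene_id", "probe_id"))
  if (!length(sampleIds)) stop(path, ": no sample columns")
  genes <- lapply(split(tab, factor(tab$gene_id, unique(tab$gene_id))),
                  function(d) {
    m <- as.matrix(d[, sampleIds, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- d$probe_id
    m
  })
  ProbeLevelData(genes, sampleIds)
}

#' Write probe-level data
#'
#' @param data a [ProbeLevelData-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeProbeLevel <- function(data, path) {
  stopifnot(is(data, "ProbeLevelData"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("gene_id", "probe_id", sampleIds(data)),
                   collapse = "\t"), con)
  for (gid in itemIds(data)) {
    m <- data@genes[[gid]]
    writeLines(vapply(seq_len(nrow(m)), function(i)
      paste(c(gid, rownames(m)[i], .fmt(m[i, ])), collapse = "\t"),
      character(1)), con)
  }
  invisible(path)
}

#' Write a filter result
#'
#' Tab-delimited `gene_id`, `p_value`, `positive` (plus `testable`).
#'
#' @param result a [FilterResult-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeFilterResult <- function(result, path) {
  stopifnot(is(result, "FilterResult"))
  tab <- filterTable(result)
  lines <- c("gene_id\tp_value\tpositive\ttestable",
             paste(tab$gene_id, .fmt(tab$p_value),
                   ifelse(tab$positive, "TRUE", "FALSE"),
                   ifelse(tab$testable, "TRUE", "FALSE"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a filter result
#'
#' @param path file path (as written by [writeFilterResult()]).
#' @param alpha threshold to record (default 0.01).
#' @return A [FilterResult-class].
#' @export
readFilterResult <- function(path, alpha = 0.01) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "p_value", "positive")
  if (!all(need %in% colnames(tab)))
    stop(path, ": filter result needs columns gene_id, p_value, positive")
  if (!"testable" %in% colnames(tab)) tab$testable <- !is.na(tab$p_value)
  new("FilterResult",
      table = tab[, c("gene_id", "p_value", "positive", "testable")],
      alpha = alpha, adjust = "none")
}

#' Write a component table
#'
#' Tab-delimited: `row_id`, `row_kind`, then one column per axis (`PC1...`
#' unscaled, `sPC1...` scaled), at `%.12g` precision.
#'
#' @param x a [ComponentTable-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeComponentTable <- function(x, path) {
  stopifnot(is(x, "ComponentTable"))
  sc <- componentScores(x)
  kind <- sub("s$", "", rowKind(x))
  lines <- c(if (isScaled(x))
               sprintf("# scale_divisor: %s", .fmt(x@scaleDivisor)),
             paste(c("row_id", "row_kind", colnames(sc)), collapse = "\t"),
             vapply(seq_len(nrow(sc)), function(i)
               paste(c(rownames(sc)[i], kind, .fmt(sc[i, ])),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a component table
#'
#' @param path file path (as written by [writeComponentTable()]).
#' @return A [ComponentTable-class]; the scaled flag is recovered from the
#'   `sPC`/`PC` column names and the divisor from the `# scale_divisor`
#'   metadata line.
#' @export
readComponentTable <- function(path) {
  lines <- readLines(path)
  metaLines <- grep("^# ", lines, value = TRUE)
  divisor <- NA_real_
  hit <- grep("^# scale_divisor: ", metaLines, value = TRUE)
  if (length(hit)) divisor <- as.numeric(sub("^# scale_divisor: ", "", hit))
  tab <- utils::read.delim(text = lines[!startsWith(lines, "# ")],
                           stringsAsFactors = FALSE)
  if (!all(c("row_id", "row_kind") %in% colnames(tab)))
    stop(path, ": component table needs columns row_id and row_kind")
  axCols <- grep("^s?PC[0-9]+$", colnames(tab), value = TRUE)
  if (!length(axCols)) stop(path, ": no axis columns found")
  scaled <- all(startsWith(axCols, "sPC"))
  sc <- as.matrix(tab[, axCols, drop = FALSE])
  rownames(sc) <- tab$row_id
  kind <- unique(tab$row_kind)
  if (length(kind) != 1L) stop(path, ": mixed row kinds")
  if (scaled && is.na(divisor))
    stop(path, ": scaled table without a scale_divisor metadata line")
  new("ComponentTable", scores = sc,
      rowKind = if (kind %in% c("sample", "samples")) "samples" else "items",
      scaled = scaled,
      scaleDivisor = if (scaled) divisor else NA_real_)
}

#' Joint biplot-like table of sample and item scores
#'
#' After scaling, sample and item scores share a size unit and can be
#' presented together on identical axes; unlike a classical biplot the
#' magnitude appears fully in both. Both inputs must be scaled and carry
#' the same number of axes.
#'
#' @param samples a scaled sample [ComponentTable-class].
#' @param items a scaled item [ComponentTable-class] from the same model.
#' @return A data.frame with columns `row_id`, `row_kind` and the shared
#'   `sPC` axis columns.
#' @export
jointComponentTable <- function(samples, items) {
  stopifnot(is(samples, "ComponentTable"), is(items, "ComponentTable"))
  if (!isScaled(samples) || !isScaled(items))
    stop("joint presentation requires scaled tables on both sides")
  if (rowKind(samples) != "samples" || rowKind(items) != "items")
    stop("expected a sample table and an item table")
  if (nAxes(samples) != nAxes(items))
    stop("axis counts differ between the two tables")
  block <- function(x, kind) {
    sc <- componentScores(x)
    data.frame(row_id = rownames(sc), row_kind = kind, sc,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(block(samples, "sample"), block(items, "item"))
}

# ---- axis-model container -------------------------------------------------

#' Save an axis model to a shareable text container
#'
#' Tab-delimited with `#`-metadata lines (`n_t`, `m_f`, `n_axes`,
#' `sign_convention`, `reference_rule`) followed by bracketed blocks:
#' `[REFERENCE]` (item_id, value), `[SINGULAR_VALUES]`, `[LOADINGS]`
#' (item_id + one column per axis of V) and `[LEFT_VECTORS]` (training row
#' label + one column per axis of U). Numbers are written at `%.12g`, so
#' the loadings that define the axis directions can be shared across
#' experiments and laboratories and reproduce scores to ~1e-10.
#'
#' @param model an [AxisModel-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
saveAxisModel <- function(model, path) {
  stopifnot(is(model, "AxisModel"))
  ref <- referenceVector(model)
  k <- nAxes(model)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# depca axis model v1",
               sprintf("# n_t: %d", nTraining(model)),
               sprintf("# m_f: %d", nFunctional(model)),
               sprintf("# n_axes: %d", k),
               sprintf("# sign_convention: %s", model@signConvention),
               sprintf("# reference_rule: %s", ref@rule)), con)
  writeLines("[REFERENCE]", con)
  writeLines(paste(names(referenceValues(ref)),
                   .fmt(referenceValues(ref)), sep = "\t"), con)
  if (length(excludedItems(ref))) {
    writeLines("[EXCLUDED_ITEMS]", con)
    writeLines(excludedItems(ref), con)
  }
  writeLines("[SINGULAR_VALUES]", con)
  writeLines(paste(seq_len(k), .fmt(singularValues(model)), sep = "\t"), con)
  V <- axisLoadings(model)
  writeLines("[LOADINGS]", con)
  writeLines(vapply(seq_len(nrow(V)), function(i)
    paste(c(rownames(V)[i], .fmt(V[i, ])), collapse = "\t"), character(1)),
    con)
  U <- leftVectors(model)
  writeLines("[LEFT_VECTORS]", con)
  writeLines(vapply(seq_len(nrow(U)), function(i)
    paste(c(rownames(U)[i], .fmt(U[i, ])), collapse = "\t"), character(1)),
    con)
  invisible(path)
}

#' Load an axis model from its text container
#'
#' Metadata and block consistency are checked (axis counts across blocks,
#' item sets of reference vs loadings, `m_f` not exceeding the item
#' count); a mismatch is rejected with the offending block named.
#'
#' @param path file path (as written by [saveAxisModel()]).
#' @return An [AxisModel-class] passing all class invariants.
#' @export
loadAxisModel <- function(path) {
  if (!file.exists(path)) stop("axis-model file not found: ", path)
  lines <- readLines(path)
  metaLines <- grep("^# ", lines, value = TRUE)
  meta <- function(key) {
    hit <- grep(sprintf("^# %s: ", key), metaLines, value = TRUE)
    if (!length(hit)) stop(path, ": missing metadata '", key, "'")
    sub(sprintf("^# %s: ", key), "", hit[1])
  }
  nt <- as.integer(meta("n_t")); mf <- as.integer(meta("m_f"))
  k <- as.integer(meta("n_axes"))
  signConv <- meta("sign_convention"); rule <- meta("reference_rule")
  starts <- grep("^\\[", lines)
  blockNames <- gsub("\\[|\\]", "", lines[starts])
  ends <- c(starts[-1] - 1L, length(lines))
  block <- function(name, required = TRUE) {
    i <- match(name, blockNames)
    if (is.na(i)) {
      if (required) stop(path, ": missing block [", name, "]")
      return(character())
    }
    body <- lines[(starts[i] + 1L):ends[i]]
    body[nzchar(body) & !startsWith(body, "#")]
  }
  parseBlock <- function(name, width) {
    rows <- strsplit(block(name), "\t", fixed = TRUE)
    badRow <- which(lengths(rows) != width + 1L)
    if (length(badRow))
      stop(sprintf("%s: block [%s] row %d has %d fields, expected %d",
                   path, name, badRow[1], lengths(rows)[badRow[1]],
                   width + 1L))
    ids <- vapply(rows, `[`, character(1), 1L)
    vals <- matrix(as.numeric(unlist(lapply(rows, `[`, -1L))),
                   nrow = length(rows), byrow = TRUE)
    rownames(vals) <- ids
    vals
  }
  refBlock <- parseBlock("REFERENCE", 1L)
  dBlock <- parseBlock("SINGULAR_VALUES", 1L)
  if (nrow(dBlock) != k)
    stop(sprintf(
      "%s: block [SINGULAR_VALUES] has %d values but metadata n_axes is %d",
      path, nrow(dBlock), k))
  V <- parseBlock("LOADINGS", k)
  U <- parseBlock("LEFT_VECTORS", k)
  if (!setequal(rownames(V), rownames(refBlock)))
    stop(path, ": block [LOADINGS] items do not match block [REFERENCE]")
  if (mf > nrow(V))
    stop(sprintf(
      "%s: metadata m_f (%d) exceeds the %d items of block [LOADINGS]",
      path, mf, nrow(V)))
  if (nrow(U) != nt)
    stop(sprintf(
      "%s: block [LEFT_VECTORS] has %d rows but metadata n_t is %d",
      path, nrow(U), nt))
  excluded <- block("EXCLUDED_ITEMS", required = FALSE)
  ref <- new("ReferenceVector",
             values = stats::setNames(refBlock[, 1], rownames(refBlock)),
             rule = rule, allMissingItems = excluded)
  colnames(V) <- colnames(U) <- paste0("axis", seq_len(k))
  new("AxisModel", V = V, U = U, d = dBlock[, 1], reference = ref,
      nt = nt, mf = mf, signConvention = signConv,
      trainingLabels = rownames(U))
}
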