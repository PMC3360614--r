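# Relative expression from stem-loop RT-PCR band intensities: per-column
# ratios over a U6 snRNA control row, log10 transform, display clamp to
# [-3, 3] (0.001- to 1000-fold), fold-class calls, and average-linkage
# clustering on correlation distance of the clamped log matrix.

#' Compute relative expression from an intensity table
#'
#' Each miRNA value is divided by the control row value of the same column,
#' log10-transformed, and clamped to `[-3, 3]` for display (a zero intensity
#' maps to the lower clamp).
#'
#' @param table numeric matrix or data.frame; rows = miRNAs plus exactly one
#'   control row, columns = samples; values are non-negative band
#'   intensities in arbitrary units.
#' @param config configuration from [mirest_config()]; uses `control_row`
#'   (default `"U6snRNA"`) and `class_reference` (`"max"` for the per-miRNA
#'   maximum ratio across samples, or a column name).
#' @return an `expression_matrix` list: `ratios`, `logs`, `clamped`
#'   (miRNA x sample matrices, control excluded), `classes` (named per-miRNA
#'   labels from [classify_fold()]), `control_row`, `reference_ratio`.
#' @export
relative_expression <- function(table, config = mirest_config()) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("intensity table must be numeric", call. = FALSE)
  ctrl <- config$control_row
  if (sum(rownames(m) == ctrl) != 1) {
    stop("intensity table must contain exactly one control row '", ctrl, "'",
         call. = FALSE)
  }
  if (any(m < 0)) stop("negative intensity value", call. = FALSE)
  control <- m[ctrl, ]
  zero_cols <- colnames(m)[control == 0]
  if (length(zero_cols) > 0) {
    stop("control intensity is zero in column(s): ",
         paste(zero_cols, collapse = ", "), call. = FALSE)
  }
  vals <- m[rownames(m) != ctrl, , drop = FALSE]
  ratios <- sweep(vals, 2, control, "/")
  logs <- log10(ratios)
  clamped <- pmin(pmax(logs, -3), 3)
  ref <- if (identical(config$class_reference, "max")) {
    apply(ratios, 1, max)
  } else {
    if (!config$class_reference %in% colnames(ratios)) {
      stop("class_reference column not found: ", config$class_reference,
           call. = FALSE)
    }
    ratios[, config$class_reference]
  }
  structure(list(ratios = ratios, logs = logs, clamped = clamped,
                 classes = classify_fold(ref), control_row = ctrl,
                 reference_ratio = ref),
            class = "expression_matrix")
}

#' Fold-class label for a miRNA/control expression ratio
#'
#' `high` above 2-fold; `moderate` for ratios in `[0.1, 1]`; `very_low`
#' below 0.01; the bins the source narrative leaves open (`(1, 2]` and
#' `[0.01, 0.1)`) get an explicit `intermediate` label; `undefined` for
#' missing values.
#'
#' @param ratio non-negative numeric vector.
#' @return character vector of class labels (names preserved).
#' @export
classify_fold <- function(ratio) {
  if (any(ratio < 0, na.rm = TRUE)) stop("negative ratio", call. = FALSE)
  out <- ifelse(is.na(ratio), "undefined",
         ifelse(ratio > 2, "high",
         ifelse(ratio < 0.01, "very_low",
         ifelse(ratio >= 0.1 & ratio <= 1, "moderate", "intermediate"))))
  names(out) <- names(ratio)
  out
}

fold_class_labels <- c("high", "moderate", "very_low", "intermediate", "undefined")

#' Count miRNAs in a fold class
#'
#' @param em an `expression_matrix` from [relative_expression()].
#' @param class one of `high`, `moderate`, `very_low`, `intermediate`,
#'   `undefined`.
#' @return integer count.
#' @export
count_classes <- function(em, class) {
  if (!class %in% fold_class_labels) stop("unknown class: ", class, call. = FALSE)
  sum(em$classes == class)
}

#' Cluster expression rows by correlation distance
#'
#' Agglomerative average-linkage clustering on `1 - Pearson correlation` of
#' the clamped log matrix. Rows are canonicalized to name order before
#' clustering, so the result is invariant to input row permutation. A
#' zero-variance row has undefined correlation and is placed at distance 1
#' to every other row, with a warning.
#'
#' @param em an `expression_matrix` (or a plain numeric matrix of clamped
#'   logs with row names).
#' @return list with `order` (leaf labels), `merge`, `height`, and the
#'   underlying `hclust` object.
#' @export
cluster_rows <- function(em) {
  x <- if (inherits(em, "expression_matrix")) em$clamped else as.matrix(em)
  if (nrow(x) < 2) stop("need at least 2 rows to cluster", call. = FALSE)
  if (anyNA(x)) stop("missing values in expression matrix", call. = FALSE)
  x <- x[order(rownames(x)), , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  cc <- suppressWarnings(cor(t(x)))
  if (any(sds == 0)) {
    warning("zero-variance row(s) treated as distance 1 to all: ",
            paste(rownames(x)[sds == 0], collapse = ", "))
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = "average")
  list(order = rownames(x)[hc$order], merge = hc$merge, height = hc$height,
       hclust = hc)
}
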