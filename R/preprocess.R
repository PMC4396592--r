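# Range standardization and log transformation.
#
# Every feature (miRNA, mRNA or protein) is mapped, independently per feature
# across samples, to
#     X* = (X - min X) / (max X - min X) + delta0,     delta0 > 0,
# so that all molecular levels share the range [delta0, 1 + delta0] and are
# strictly positive, hence log-transformable. The default delta0 is 0.1.
# Standardization operates on linear-scale (not log-transformed) values.

#' Construct an expression matrix
#'
#' A features x samples matrix of expression values for one molecular level,
#' with unique feature and sample identifiers.
#'
#' @param values Numeric matrix, features in rows and samples in columns,
#'   with rownames (feature IDs) and colnames (sample IDs).
#' @param level One of `"miRNA"`, `"mRNA"`, `"protein"`.
#' @return A numeric matrix of class `expr_matrix` with a `level` attribute.
#' @export
expression_matrix <- function(values, level = c("miRNA", "mRNA", "protein")) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  structure(unclass(values), level = level,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix: %s, %d features x %d samples>\n",
              attr(x, "level"), nrow(x), ncol(x)))
  invisible(x)
}

expr_level <- function(x) attr(x, "level") %||% "protein"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rebuild an expr_matrix, preserving the level attribute of a template.
rewrap <- function(values, template) {
  if (inherits(template, "expr_matrix")) {
    expression_matrix(values, expr_level(template))
  } else {
    values
  }
}

#' Standardize each feature to the range [delta0, 1 + delta0]
#'
#' Applies the per-feature affine map `(X - min) / (max - min) + delta0`
#' across samples. Input values are expected on the linear scale. Features
#' with zero range (max == min) carry no association signal and leave the
#' map undefined; they are dropped with a warning.
#'
#' @param matrix Features x samples numeric matrix (ideally an
#'   [expression_matrix()]).
#' @param delta0 Positive offset guaranteeing strictly positive output
#'   (default 0.1).
#' @return A list with components `values` (the standardized matrix, same
#'   class as the input) and `params` (a data frame with columns `feature`,
#'   `min`, `max` plus a `delta0` attribute) of class `standardization`.
#' @examples
#' m <- expression_matrix(matrix(c(2, 4, 6), 1, 3,
#'   dimnames = list("f1", c("s1", "s2", "s3"))), "mRNA")
#' standardize(m)$values  # 0.1 0.6 1.1
#' @export
standardize <- function(matrix, delta0 = 0.1) {
  assert_scalar_number(delta0, "delta0", lower = 0, strict_lower = TRUE)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  }
  mins <- apply(matrix, 1L, min, na.rm = TRUE)
  maxs <- apply(matrix, 1L, max, na.rm = TRUE)
  flat <- maxs <= mins
  if (any(flat)) {
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    sum(flat),
                    paste(utils::head(rownames(matrix)[flat], 5L),
                          collapse = ", ")),
            call. = FALSE)
    matrix <- matrix[!flat, , drop = FALSE]
    mins <- mins[!flat]; maxs <- maxs[!flat]
  }
  if (nrow(matrix) == 0L) stop("no feature with positive range", call. = FALSE)
  std <- (matrix - mins) / (maxs - mins) + delta0
  params <- data.frame(feature = rownames(matrix), min = mins, max = maxs,
                       row.names = NULL, stringsAsFactors = FALSE)
  attr(params, "delta0") <- delta0
  structure(list(values = rewrap(std, matrix), params = params),
            class = "standardization")
}

#' Elementwise log transformation
#'
#' Natural logarithm of a strictly positive expression matrix. The fitted
#' miRNA and mRNA exponents are invariant to the log base; the intercept is
#' reported in natural-log units.
#'
#' @param matrix Features x samples numeric matrix with all values > 0.
#' @return Matrix of the same shape (and class) with `log` applied.
#' @export
log_transform <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  }
  bad <- which(matrix <= 0 & !is.na(matrix), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    feats <- unique(rownames(matrix)[bad[, 1L]])
    stop("nonpositive values in feature(s): ",
         paste(utils::head(feats, 5L), collapse = ", "), call. = FALSE)
  }
  rewrap(log(unclass(matrix)), matrix)
}
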