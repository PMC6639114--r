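#' Fit the PC1 composite of psychometric-function shape
#'
#' Standardizes the four fitted parameters (slope, threshold, lower
#' asymptote, upper-asymptote offset) across all rows pooled over conditions
#' and extracts the leading principal component of their correlation
#' structure. The loading sign is chosen so the slope loading is positive, so
#' larger PC1 means a steeper, more categorical function.
#'
#' @param param_table data.frame with columns `slope`, `threshold`, `gamma`,
#'   `lambda` (one row per subject x condition); at least 5 rows, no missing
#'   values.
#' @param use_correlation standardize to unit variance before the
#'   eigendecomposition (correlation-matrix PCA, the default); set `FALSE`
#'   for covariance-matrix PCA.
#' @return an object of class `shape_pca`: `loadings` (unit-norm, length 4),
#'   `variance_fraction_pc1`, `center`, `scale`, `rotation` (full 4 x 4),
#'   `variance_fractions`, `sdev`.
#' @export
fit_shape_pca <- function(param_table, use_correlation = TRUE) {
  cols <- c("slope", "threshold", "gamma", "lambda")
  missing_cols <- setdiff(cols, names(param_table))
  if (length(missing_cols))
    stop("param_table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(param_table[, cols])
  if (nrow(x) < 5L) stop("need at least 5 rows to fit the PCA", call. = FALSE)
  if (anyNA(x)) stop("param_table contains missing values", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ", paste(cols[sds == 0], collapse = ", "),
         call. = FALSE)

  pc <- stats::prcomp(x, center = TRUE, scale. = use_correlation)
  rot <- pc$rotation
  if (rot["slope", 1] < 0) rot[, 1] <- -rot[, 1]
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    loadings = rot[, 1],
    variance_fraction_pc1 = varfrac[1],
    center = pc$center,
    scale = if (use_correlation) pc$scale else rep(1, length(cols)),
    rotation = rot,
    variance_fractions = varfrac,
    sdev = pc$sdev
  ), class = "shape_pca")
}

#' Project parameter rows onto PC1
#'
#' Standardizes rows with the training center/scale and takes the dot product
#' with the PC1 loading vector. Rows equal to the training column means map
#' to 0.
#'
#' @param rows data.frame (or single named row) with columns `slope`,
#'   `threshold`, `gamma`, `lambda`.
#' @param pca a fitted [fit_shape_pca()].
#' @return numeric vector of PC1 scores.
#' @export
project_pc1 <- function(rows, pca) {
  if (!inherits(pca, "shape_pca"))
    stop("'pca' must be a fitted shape_pca", call. = FALSE)
  cols <- c("slope", "threshold", "gamma", "lambda")
  if (is.null(dim(rows))) rows <- as.data.frame(as.list(rows))
  x <- as.matrix(rows[, cols])
  z <- sweep(sweep(x, 2, pca$center), 2, pca$scale, "/")
  as.numeric(z %*% pca$loadings)
}

#' Serialize / restore a fitted shape PCA
#'
#' The transform (loadings, centering, scaling, variance fractions) is stored
#' as JSON so PC1 scores are reproducible across runs.
#'
#' @param pca a fitted [fit_shape_pca()].
#' @param path output JSON path.
#' @return `path` invisibly; `read_shape_pca()` returns the restored
#'   `shape_pca`.
#' @export
write_shape_pca <- function(pca, path) {
  stopifnot(inherits(pca, "shape_pca"))
  obj <- list(loadings = as.list(pca$loadings),
              center = as.list(pca$center),
              scale = as.list(stats::setNames(pca$scale, names(pca$center))),
              variance_fraction_pc1 = pca$variance_fraction_pc1,
              variance_fractions = pca$variance_fractions,
              sdev = pca$sdev)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_shape_pca
#' @export
read_shape_pca <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(
    loadings = unlist(obj$loadings),
    variance_fraction_pc1 = obj$variance_fraction_pc1,
    center = unlist(obj$center),
    scale = unlist(obj$scale),
    rotation = NULL,
    variance_fractions = obj$variance_fractions,
    sdev = obj$sdev
  ), class = "shape_pca")
}
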