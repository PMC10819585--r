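#' Column standardization with recoverable parameters
#'
#' Centers and scales every column to mean 0, SD 1 (sample SD) and stores
#' the transform so it can be inverted.
#'
#' @param table Numeric data frame or matrix.
#' @return Numeric matrix with attributes `center` and `scale`.
#' @export
standardize <- function(table) {
  x <- as.matrix(as.data.frame(table))
  if (!is.numeric(x)) stop("table must be numeric", call. = FALSE)
  s <- apply(x, 2, stats::sd)
  zero <- colnames(x)[s == 0 | !is.finite(s)]
  if (length(zero))
    stop("zero-variance column(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  ctr <- colMeans(x)
  z <- sweep(sweep(x, 2, ctr), 2, s, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- s
  z
}

#' Invert a standardization
#'
#' @param z Matrix produced by [standardize()] (or any matrix plus explicit
#'   `center`/`scale`).
#' @param center,scale Optional overrides; default taken from `z`'s
#'   attributes.
#' @return Matrix on the original scale.
#' @export
unstandardize <- function(z, center = attr(z, "center"),
                          scale = attr(z, "scale")) {
  if (is.null(center) || is.null(scale))
    stop("no center/scale to invert", call. = FALSE)
  sweep(sweep(unclass(z), 2, scale, "*"), 2, center, "+")
}

#' Principal component analysis with contribution ranking support
#'
#' SVD-based PCA of a (standardized) table. Loadings follow a deterministic
#' sign convention: within each component the largest-magnitude loading is
#' made positive. Degenerate rank is handled by reporting fewer components.
#'
#' @param table Numeric table, typically already standardized.
#' @param center Center columns first? Default `TRUE`.
#' @return Object of class `pca_result`: `loadings` (variables x
#'   components, orthonormal), `scores`, `explained` (variance fractions
#'   summing to 1 over reported components), `sdev`.
#' @export
pca_profile <- function(table, center = TRUE) {
  x <- as.matrix(as.data.frame(table))
  if (nrow(x) < 2L) stop("need at least 2 rows", call. = FALSE)
  pc <- stats::prcomp(x, center = center, scale. = FALSE)
  keep <- pc$sdev > max(pc$sdev) * 1e-10
  load <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  v <- pc$sdev[keep]^2
  structure(list(loadings = load, scores = scores,
                 explained = v / sum(v), sdev = pc$sdev[keep]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$loadings), "variables,",
      ncol(x$loadings), "components\n")
  cat("explained variance:",
      paste0(round(100 * x$explained, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' Rank variables by contribution to one principal axis
#'
#' Contribution of a variable to an axis is its squared loading, which over
#' an orthonormal loading column sums to 1 and so reads directly as a
#' share.
#'
#' @param pca A `pca_result`.
#' @param axis Component index.
#' @param k How many variables to return; default all.
#' @return Data frame `variable`, `loading`, `share`, sorted by decreasing
#'   share.
#' @export
top_contributors <- function(pca, axis = 1, k = nrow(pca$loadings)) {
  stopifnot(inherits(pca, "pca_result"))
  if (axis < 1 || axis > ncol(pca$loadings))
    stop("axis out of range (1..", ncol(pca$loadings), ")", call. = FALSE)
  l <- pca$loadings[, axis]
  vars <- rownames(pca$loadings)
  share <- l^2 / sum(l^2)
  ord <- order(share, decreasing = TRUE)
  utils::head(data.frame(variable = vars[ord], loading = l[ord],
                         share = share[ord], row.names = NULL), k)
}

#' Normal-theory confidence ellipse of a 2-D point cloud
#'
#' Fits a bivariate normal (sample mean and covariance) and returns the
#' ellipse containing the requested probability mass under that fit, with
#' radius set by the chi-square(2 df) quantile.
#'
#' @param coords Two-column matrix of coordinates.
#' @param level Coverage level in (0, 1); default 0.9.
#' @return List of class `confidence_ellipse`: `center`, `axes` (semi-axis
#'   lengths), `angle` (radians, first axis vs x), `cov`, `level`, `area`.
#' @export
confidence_ellipse <- function(coords, level = 0.9) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, level > 0, level < 1)
  if (nrow(coords) < 3L) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(coords)
  S <- stats::cov(coords)
  ev <- eigen(S, symmetric = TRUE)
  r2 <- stats::qchisq(level, df = 2)
  axes <- sqrt(pmax(ev$values, 0) * r2)
  structure(list(center = ctr, axes = axes,
                 angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
                 cov = S, level = level, area = pi * prod(axes)),
            class = "confidence_ellipse")
}

#' Test which points fall inside a confidence ellipse
#'
#' @param ellipse A `confidence_ellipse`.
#' @param coords Two-column matrix of points.
#' @return Logical vector.
#' @export
ellipse_contains <- function(ellipse, coords) {
  coords <- as.matrix(coords)
  d <- sweep(coords, 2, ellipse$center)
  md <- rowSums((d %*% solve(ellipse$cov)) * d)
  md <= stats::qchisq(ellipse$level, df = 2)
}

#' Supervised 2-D embedding with per-group confidence ellipses
#'
#' Runs label-supervised UMAP on a (standardized) table and fits a 90%
#' normal-theory confidence ellipse per group from the embedded
#' coordinates. The run is deterministic given `seed` (single-threaded
#' optimizer). Defaults suit very small groups (n = 8 sites per layer):
#' 5 neighbors, min_dist 0.1.
#'
#' @param table Numeric table, typically standardized; one row per sample.
#' @param labels Group label per row (e.g. layer).
#' @param seed Integer seed; mandatory.
#' @param n_neighbors UMAP neighborhood size.
#' @param min_dist UMAP minimum embedded distance.
#' @param level Ellipse coverage level; default 0.9.
#' @return Object of class `embedding_result`: `coords` (n x 2), `labels`,
#'   `ellipses` (one `confidence_ellipse` per group), `params`.
#' @export
supervised_embedding <- function(table, labels, seed,
                                 n_neighbors = 5, min_dist = 0.1,
                                 level = 0.9) {
  x <- as.matrix(as.data.frame(table))
  labels <- as.factor(labels)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (nrow(x) < n_neighbors + 1)
    stop("too few samples (", nrow(x), ") for n_neighbors = ", n_neighbors,
         "; reduce n_neighbors", call. = FALSE)
  coords <- uwot::umap(x, y = labels, n_neighbors = n_neighbors,
                       min_dist = min_dist, n_components = 2,
                       n_threads = 1, n_sgd_threads = 0,
                       seed = as.integer(seed))
  dimnames(coords) <- list(rownames(x), c("U1", "U2"))
  ell <- lapply(split(seq_len(nrow(x)), labels), function(i)
    confidence_ellipse(coords[i, , drop = FALSE], level))
  structure(list(coords = coords, labels = labels, ellipses = ell,
                 params = list(seed = as.integer(seed),
                               n_neighbors = n_neighbors,
                               min_dist = min_dist, level = level)),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("Supervised UMAP embedding of", nrow(x$coords), "samples",
      "(seed", x$params$seed, ")\n")
  for (g in names(x$ellipses))
    cat(sprintf("  %s: %d samples, %.0f%% ellipse area %.3f\n", g,
                sum(x$labels == g), 100 * x$params$level,
                x$ellipses[[g]]$area))
  invisible(x)
}
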