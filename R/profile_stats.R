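#' Significance stars for p-values
#'
#' Two conventions are shipped: the three-tier scheme used for correlation
#' displays (0.05, 0.01, 0.001 -> *, **, ***) and the four-tier model-table
#' scheme that adds a 0.1 "marginal" dot tier.
#'
#' @param p Numeric vector of p-values.
#' @param scheme `"correlation"` (default) or `"model"`.
#' @return Character vector of star codes (may be `""`).
#' @export
sig_stars <- function(p, scheme = c("correlation", "model")) {
  scheme <- match.arg(scheme)
  out <- character(length(p))
  if (scheme == "correlation") {
    out[p < 0.05]  <- "*"
    out[p < 0.01]  <- "**"
    out[p < 0.001] <- "***"
  } else {
    out[p < 0.1]   <- "."
    out[p < 0.05]  <- "*"
    out[p < 0.01]  <- "**"
    out[p < 0.001] <- "***"
  }
  out
}

#' Two-group layer difference test
#'
#' Compares a variable between the two layers with both an exact Wilcoxon
#' rank-sum test and a two-sided Welch t-test; both p-values are always
#' returned and `p` holds the primary one. The default primary test is the
#' exact Wilcoxon: with n = 8 per layer a rank test is robust and its
#' p-values are invariant under strictly monotone per-metal transforms,
#' which is why a metal and its geoaccumulation / risk transforms share one
#' p-value.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping vector (e.g. layer labels).
#' @param primary `"wilcoxon"` (default) or `"welch"`.
#' @return List with `p`, `test`, `p_wilcoxon`, `p_welch`.
#' @export
layer_test <- function(values, groups, primary = c("wilcoxon", "welch")) {
  primary <- match.arg(primary)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("need exactly two groups", call. = FALSE)
  sp <- split(values, droplevels(groups))
  if (any(lengths(sp) < 2L))
    stop("each group needs at least 2 observations; degenerate group: ",
         names(sp)[lengths(sp) < 2][1], call. = FALSE)
  pw <- suppressWarnings(
    stats::wilcox.test(sp[[1]], sp[[2]], exact = TRUE,
                       correct = FALSE)$p.value)
  sds <- vapply(sp, stats::sd, 0)
  pt <- if (all(sds == 0)) {
    # Welch statistic is 0/0 for two constant groups; equal constants mean
    # no evidence of difference, unequal constants mean certain difference
    if (mean(sp[[1]]) == mean(sp[[2]])) 1 else 0
  } else stats::t.test(sp[[1]], sp[[2]])$p.value
  list(p = if (primary == "wilcoxon") pw else pt,
       test = primary, p_wilcoxon = pw, p_welch = pt)
}

#' Per-layer descriptive statistics with layer-difference tests
#'
#' For every numeric column, per layer: first quartile, median, third
#' quartile (linear interpolation between order statistics, the standard
#' type-7 convention), mean, sample SD (n-1 denominator) and n; plus one
#' layer-difference p-value per variable from [layer_test()].
#'
#' @param table Data frame of numeric variables.
#' @param by Two-level grouping vector, `nrow(table)` long.
#' @param primary Primary test passed to [layer_test()].
#' @return Data frame of class `summary_table`: one row per variable x
#'   layer with `q1, median, q3, mean, sd, n`, and per-variable columns
#'   `p_value`, `test`, `p_wilcoxon`, `p_welch` (repeated across the
#'   variable's rows).
#' @export
describe <- function(table, by, primary = c("wilcoxon", "welch")) {
  primary <- match.arg(primary)
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, TRUE)
  table <- table[, num, drop = FALSE]
  by <- as.factor(by)
  if (length(by) != nrow(table))
    stop("`by` must have one label per row", call. = FALSE)
  if (any(table(by) < 2L))
    stop("need >= 2 observations per layer; too few in: ",
         paste(names(which(table(by) < 2)), collapse = ", "), call. = FALSE)
  rows <- list()
  for (v in names(table)) {
    lt <- layer_test(table[[v]], by, primary)
    for (g in levels(by)) {
      x <- table[[v]][by == g]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, layer = g, n = length(x),
        q1 = unname(stats::quantile(x, 0.25, type = 7)),
        median = stats::median(x),
        q3 = unname(stats::quantile(x, 0.75, type = 7)),
        mean = mean(x), sd = stats::sd(x),
        p_value = lt$p, test = lt$test,
        p_wilcoxon = lt$p_wilcoxon, p_welch = lt$p_welch)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Pairwise Pearson correlation with significance stars
#'
#' Pearson r for every variable pair with the classical t-distributed
#' two-sided p-value and three-tier stars (* p < 0.05, ** p < 0.01,
#' *** p < 0.001). A zero-variance variable yields `NA` r for its pairs and
#' is listed in `$degenerate` rather than silently dropped.
#'
#' @param table Data frame or matrix of numeric variables (>= 3 complete
#'   rows).
#' @return Object of class `correlation_result`: matrices `r`, `p`,
#'   `stars`, a plot-ready `long` table (var1, var2, r, p, stars) and
#'   `degenerate` (names of zero-variance variables).
#' @export
correlation_matrix <- function(table) {
  x <- as.matrix(as.data.frame(table))
  if (!is.numeric(x)) stop("table must be numeric", call. = FALSE)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  p <- ncol(x)
  vars <- colnames(x)
  degenerate <- vars[apply(x, 2, stats::sd) == 0]
  r <- suppressWarnings(stats::cor(x))
  r[degenerate, ] <- NA_real_; r[, degenerate] <- NA_real_
  diag(r) <- ifelse(vars %in% degenerate, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  pmat <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  pmat[r == 1 | r == -1] <- 0   # exact linear dependence
  diag(pmat) <- 0
  stars <- matrix(sig_stars(pmat), p, p, dimnames = dimnames(r))
  stars[is.na(pmat)] <- NA_character_
  idx <- which(upper.tri(r), arr.ind = TRUE)
  long <- data.frame(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
                     r = r[idx], p = pmat[idx], stars = stars[idx])
  structure(list(r = r, p = pmat, stars = stars, long = long,
                 degenerate = degenerate, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Pearson correlation over", x$n, "observations\n")
  disp <- matrix(paste0(format(round(x$r, 2)), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  if (length(x$degenerate))
    cat("zero-variance (r undefined):",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Per-layer correlation matrices
#'
#' Convenience wrapper computing [correlation_matrix()] separately within
#' each layer, mirroring the two-panel correlation display of a surface
#' (APMS) versus deep (SOIL) profile comparison.
#'
#' @param table Numeric data frame.
#' @param by Grouping vector (layer labels).
#' @return Named list of `correlation_result`, one per layer.
#' @export
correlation_by_layer <- function(table, by) {
  by <- as.factor(by)
  out <- lapply(levels(by), function(g)
    correlation_matrix(as.data.frame(table)[by == g, , drop = FALSE]))
  stats::setNames(out, levels(by))
}
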