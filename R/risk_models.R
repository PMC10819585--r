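#' Variance inflation factors
#'
#' VIF of each column of a design matrix, computed as \eqn{1/(1-R^2)} from
#' the regression of that column on all the others. Perfect collinearity
#' yields `Inf`.
#'
#' @param x Numeric matrix or data frame (>= 2 columns).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(as.data.frame(x))
  p <- ncol(x)
  if (p < 2L) return(stats::setNames(rep(1, p), colnames(x)))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  stats::setNames(out, colnames(x))
}

#' Iterative collinearity pruning by VIF
#'
#' Repeatedly removes the highest-VIF variable until every remaining VIF is
#' below the cutoff (default 10, the conventional rule of thumb). The
#' removal order is logged. Ending with fewer than 2 survivors raises a
#' warning, not an error.
#'
#' @param x Numeric table of candidate predictors (standardized or not;
#'   VIF is scale-invariant).
#' @param cutoff VIF threshold; default 10.
#' @return List: `keep` (surviving column names), `dropped` (data frame
#'   with `variable`, `vif` at removal, in removal order), `vif`
#'   (final VIFs).
#' @export
prune_collinear <- function(x, cutoff = 10) {
  x <- as.matrix(as.data.frame(x))
  dropped <- data.frame(variable = character(), vif = numeric())
  repeat {
    v <- vif(x)
    if (ncol(x) < 2L || max(v) < cutoff) break
    worst <- which.max(v)
    dropped <- rbind(dropped,
                     data.frame(variable = colnames(x)[worst],
                                vif = unname(v[worst])))
    x <- x[, -worst, drop = FALSE]
  }
  if (ncol(x) < 2L)
    warning("collinearity pruning left fewer than 2 candidates",
            call. = FALSE)
  list(keep = colnames(x), dropped = dropped, vif = vif(x))
}

# R^2 of y on the columns `terms` of X (matrix interface, intercept always)
.r2 <- function(X, y, terms) {
  if (!length(terms)) return(0)
  fit <- stats::lm.fit(cbind(1, X[, terms, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' LMG relative importance decomposition
#'
#' Averages each predictor's sequential \eqn{R^2} increment over all
#' orderings of the predictors (the LMG / dominance decomposition), using
#' the subset-weighted closed form
#' \eqn{lmg_j = \sum_{S \not\ni j} w_{|S|} [R^2(S \cup j) - R^2(S)]}
#' with \eqn{w_k = k!(p-1-k)!/p!}. The per-predictor contributions sum to
#' the full-model \eqn{R^2}; `share` normalizes them to sum to 1. Exact
#' enumeration is used for up to 15 predictors (the suite's realistic
#' sizes); more raises an error.
#'
#' @param x Numeric predictor table.
#' @param y Response vector.
#' @return Data frame `variable`, `lmg` (R^2 units), `share`, sorted as
#'   given.
#' @export
lmg_importance <- function(x, y) {
  X <- as.matrix(as.data.frame(x))
  p <- ncol(X)
  if (p == 0L) stop("need at least one predictor", call. = FALSE)
  if (p == 1L) {
    r2 <- .r2(X, y, 1L)
    return(data.frame(variable = colnames(X), lmg = r2, share = 1))
  }
  if (p > 15L) stop("exact LMG enumeration limited to 15 predictors",
                    call. = FALSE)
  # R^2 of every subset, indexed by bitmask
  r2s <- numeric(2^p)
  for (mask in 1:(2^p - 1))
    r2s[mask + 1L] <- .r2(X, y, which(bitwAnd(mask, 2^(0:(p - 1))) > 0))
  w <- factorial(0:(p - 1)) * factorial(p - 1 - (0:(p - 1))) / factorial(p)
  lmg <- numeric(p)
  for (j in seq_len(p)) {
    bitj <- 2^(j - 1)
    others <- 0:(2^p - 1)
    others <- others[bitwAnd(others, bitj) == 0]
    k <- vapply(others, function(m) sum(bitwAnd(m, 2^(0:(p - 1))) > 0), 0)
    lmg[j] <- sum(w[k + 1] * (r2s[others + bitj + 1L] - r2s[others + 1L]))
  }
  data.frame(variable = colnames(X), lmg = lmg,
             share = lmg / sum(lmg))
}

#' Bidirectional AIC stepwise linear fit
#'
#' Standardizes response and candidates (unless told not to), then runs a
#' bidirectional stepwise search minimizing AIC from the intercept-only
#' model, with ordinary least squares at each step. The final fit is
#' reported with classical standard errors, two-sided p-values, four-tier
#' stars (. p < 0.1, * < 0.05, ** < 0.01, *** < 0.001), adjusted
#' \eqn{R^2}, AIC, BIC (full-likelihood convention, `stats::AIC`) and LMG
#' importance shares over the selected terms. Ties in the step table are
#' broken by lower AIC then earlier candidate order (the `stats::step`
#' rule); identical data and spec give identical paths.
#'
#' @param data Data frame containing response and candidates.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictor names.
#' @param standardize Standardize all used columns first? Default `TRUE`.
#' @return Object of class `model_fit`: `coefficients` (term, estimate,
#'   se, p, stars), `adj_r2`, `r2`, `aic`, `bic`, `importance`, `n`,
#'   `selected`, `candidates`, `fit` (the `lm` object), `meta`
#'   (direction, criterion, standardized flag).
#' @export
stepwise_fit <- function(data, response, candidates, standardize = TRUE) {
  data <- as.data.frame(data)
  stopifnot(response %in% names(data), all(candidates %in% names(data)))
  if (response %in% candidates)
    stop("response must not appear among candidates", call. = FALSE)
  d <- data[, c(response, candidates), drop = FALSE]
  if (standardize) d <- as.data.frame(standardize(d))
  n <- nrow(d)
  if (n <= length(candidates) + 1L)
    warning("n (", n, ") is not larger than candidate count + 1; ",
            "consider stronger collinearity pruning", call. = FALSE)
  null_fit <- stats::lm(stats::reformulate("1", response), data = d)
  scope <- list(lower = ~1, upper = stats::reformulate(candidates))
  fit <- suppressWarnings(
    stats::step(null_fit, scope = scope, direction = "both", trace = 0, k = 2))
  sel <- setdiff(names(stats::coef(fit)), "(Intercept)")
  sm <- suppressWarnings(summary(fit))
  ct <- sm$coefficients
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1],
                      se = ct[, 2], p = ct[, 4],
                      stars = sig_stars(ct[, 4], "model"),
                      row.names = NULL)
  imp <- if (length(sel)) lmg_importance(d[, sel, drop = FALSE],
                                         d[[response]])
         else data.frame(variable = character(), lmg = numeric(),
                         share = numeric())
  structure(list(coefficients = coefs, adj_r2 = sm$adj.r.squared,
                 r2 = sm$r.squared, aic = stats::AIC(fit),
                 bic = stats::BIC(fit), importance = imp, n = n,
                 selected = sel, candidates = candidates, fit = fit,
                 meta = list(direction = "both", criterion = "AIC",
                             start = "intercept-only",
                             standardized = standardize)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Stepwise fit (", x$meta$direction, ", ", x$meta$criterion,
      "): ", length(x$selected), " of ", length(x$candidates),
      " candidates selected, n = ", x$n, "\n", sep = "")
  print(x$coefficients, digits = 3)
  cat(sprintf("adj-R2 %.4f  AIC %.3f  BIC %.3f\n",
              x$adj_r2, x$aic, x$bic))
  invisible(x)
}

#' LMG importance shares of a fitted model
#'
#' @param fit A `model_fit` with at least one selected predictor.
#' @param data Optional data frame to recompute on; defaults to the data
#'   stored in the fit.
#' @return Data frame `variable`, `lmg`, `share` (shares sum to 1).
#' @export
importance_decomposition <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "model_fit"))
  if (!length(fit$selected))
    stop("model has no predictors to decompose", call. = FALSE)
  if (is.null(data)) return(fit$importance)
  d <- as.data.frame(data)
  resp <- all.vars(stats::formula(fit$fit))[1]
  lmg_importance(d[, fit$selected, drop = FALSE], d[[resp]])
}

.model_families <- function() {
  m <- hm_metals()
  list(metals = m, igeo = paste0("Igeo_", m), pei = paste0("PEI_", m),
       pollution = c("PN", "PLI"))
}

#' Assemble the pooled modelling table
#'
#' Joins raw concentrations with the computed index columns into the
#' pooled (both layers, n = sites x 2) table the model suite regresses on.
#'
#' @param samples A `sample_table`.
#' @param refs A `reference_set`.
#' @return Data frame with `site`, `layer`, the seven concentrations,
#'   `Igeo_*`, `PEI_*`, `PN`, `PLI` and the response `TEI`.
#' @export
model_data <- function(samples, refs = default_reference_set()) {
  idx <- index_pipeline(samples, refs)
  wide <- sample_wide(samples)
  fam <- .model_families()
  cbind(wide[, c("site", "layer")], wide[, fam$metals],
        idx$samples[, c(fam$igeo, fam$pei, fam$pollution, "TEI")])
}

#' Stepwise model suite for total ecological risk
#'
#' Fits the four nested adjustment structures used to quantify variable
#' contributions to total risk (response `TEI`, pooled layers):
#' Model 0 regresses on the seven metal concentrations; Model 1 adds the
#' geoaccumulation family; Model 2 adds the single-metal risk family;
#' Model 3 adds the pollution indices (Nemero `PN` and load `PLI`).
#' Each candidate set is collinearity-pruned ([prune_collinear()]) before
#' the bidirectional AIC stepwise search; if the pruned candidate count
#' still reaches `n - 1` the VIF cutoff is halved with a warning until it
#' does not.
#'
#' @param data Modelling table from [model_data()] (or a `sample_table`,
#'   which is converted with `refs`).
#' @param refs Reference set used if `data` is a `sample_table`.
#' @param vif_cutoff Initial VIF threshold; default 10.
#' @return Object of class `model_suite`: `models` (list of four
#'   `model_fit`s named `model0`..`model3`), `comparison` (a term x model
#'   table with "estimate (se) stars" cells and a performance block),
#'   `pruning` (per model, dropped variables).
#' @export
model_suite <- function(data, refs = default_reference_set(),
                        vif_cutoff = 10) {
  if (inherits(data, "sample_table") ||
      (is.data.frame(data) && "conc_mg_kg" %in% names(data)))
    data <- model_data(data, refs)
  data <- as.data.frame(data)
  fam <- .model_families()
  for (f in names(fam)) {
    missing <- setdiff(fam[[f]], names(data))
    if (length(missing))
      stop("model data is missing the ", f, " family column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"TEI" %in% names(data)) stop("model data is missing TEI",
                                    call. = FALSE)
  sets <- list(model0 = fam$metals,
               model1 = c(fam$metals, fam$igeo),
               model2 = c(fam$metals, fam$pei),
               model3 = c(fam$metals, fam$pollution))
  n <- nrow(data)
  pruning <- list()
  fits <- lapply(names(sets), function(nm) {
    cand <- sets[[nm]]
    cutoff <- vif_cutoff
    pr <- prune_collinear(data[, cand, drop = FALSE], cutoff)
    while (length(pr$keep) >= n - 1 && cutoff > 1.5) {
      cutoff <- cutoff / 2
      warning(nm, ": tightening VIF cutoff to ", cutoff,
              " to keep candidates below n", call. = FALSE)
      pr <- prune_collinear(data[, cand, drop = FALSE], cutoff)
    }
    pruning[[nm]] <<- pr$dropped
    stepwise_fit(data, "TEI", pr$keep)
  })
  names(fits) <- names(sets)

  all_terms <- unique(unlist(sets))
  cell <- function(fit, term) {
    ct <- fit$coefficients
    i <- match(term, ct$term)
    if (is.na(i)) return("——")
    sprintf("%.3f (%.3f) %s", ct$estimate[i], ct$se[i], ct$stars[i])
  }
  comp <- data.frame(variable = all_terms)
  for (nm in names(fits))
    comp[[nm]] <- vapply(all_terms, cell, "", fit = fits[[nm]])
  perf <- data.frame(
    variable = c("Adj.R2", "AIC", "BIC"),
    do.call(cbind, lapply(fits, function(f)
      c(sprintf("%.2f%%", 100 * f$adj_r2), sprintf("%.3f", f$aic),
        sprintf("%.3f", f$bic)))))
  names(perf) <- names(comp)
  structure(list(models = fits, comparison = rbind(comp, perf),
                 pruning = pruning, n = n),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("Stepwise model suite, response TEI, n =", x$n, "\n")
  print(x$comparison, right = FALSE)
  invisible(x)
}

#' Export a model suite comparison as CSV and JSON
#'
#' @param suite A `model_suite`.
#' @param stem Output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return The two paths, invisibly.
#' @export
write_model_suite <- function(suite, stem) {
  stopifnot(inherits(suite, "model_suite"))
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  utils::write.csv(suite$comparison, csv, row.names = FALSE)
  obj <- lapply(suite$models, function(f)
    list(selected = f$selected, coefficients = f$coefficients,
         adj_r2 = f$adj_r2, aic = f$aic, bic = f$bic,
         importance = f$importance, n = f$n, meta = f$meta))
  jsonlite::write_json(obj, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv, js))
}
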