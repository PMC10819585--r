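.check_pos <- function(x, what) {
  if (any(!is.finite(x) | x <= 0))
    stop(what, " must be finite and > 0", call. = FALSE)
  invisible(x)
}
.check_seven <- function(x, what) {
  if (length(x) != 7L)
    stop(what, " needs exactly seven values (one per metal), got ",
         length(x), call. = FALSE)
  invisible(x)
}

#' Single-factor pollution index
#'
#' \eqn{P_i = C_i / S_i}: the measured concentration over the regulatory
#' screening value for the same metal. Values above 1 indicate that the
#' metal exceeds its farmland screening limit.
#'
#' @param concentration Measured concentration, mg/kg (vectorized).
#' @param screening Screening value \eqn{S_i}, mg/kg.
#' @return Dimensionless index \eqn{P_i}.
#' @export
single_factor_index <- function(concentration, screening) {
  .check_pos(concentration, "concentration")
  .check_pos(screening, "screening")
  concentration / screening
}

#' Mean single-factor pollution index
#'
#' Arithmetic mean of the seven per-metal single-factor indices: the
#' equal-weighted pollution level of a sample.
#'
#' @param pi_values Seven positive \eqn{P_i} values.
#' @return Dimensionless mean index.
#' @export
mean_pi <- function(pi_values) {
  .check_seven(pi_values, "pi_values")
  .check_pos(pi_values, "pi_values")
  mean(pi_values)
}

#' Nemero comprehensive pollution index
#'
#' \eqn{P_N = \sqrt{(\bar P^2 + P_{max}^2)/2}} over the seven single-factor
#' indices. By combining the mean with the maximum it emphasizes the worst
#' single pollutant; it always lies in \eqn{[P_{max}/\sqrt2,\; P_{max}]}.
#'
#' @param pi_values Seven positive \eqn{P_i} values.
#' @return Dimensionless Nemero index \eqn{P_N}.
#' @export
nemero_index <- function(pi_values) {
  .check_seven(pi_values, "pi_values")
  .check_pos(pi_values, "pi_values")
  sqrt((mean(pi_values)^2 + max(pi_values)^2) / 2)
}

#' Pollution load index
#'
#' Geometric mean of the seven concentration-to-background ratios
#' \eqn{PLI = (\prod C_i/B_i)^{1/7}}. Unlike the single-factor family it is
#' referenced to geochemical background, not to screening values.
#'
#' @param concentrations Seven concentrations, mg/kg.
#' @param background Seven background values \eqn{B_n}, mg/kg.
#' @return Dimensionless load index.
#' @export
pollution_load_index <- function(concentrations, background) {
  .check_seven(concentrations, "concentrations")
  .check_seven(background, "background")
  .check_pos(concentrations, "concentrations")
  .check_pos(background, "background")
  exp(mean(log(concentrations / background)))
}

#' Geoaccumulation index
#'
#' \eqn{I_{geo} = \log_2[C_n / (1.5 B_n)]}; the factor 1.5 absorbs natural
#' fluctuation of the background. Graded 0--6 from unpolluted to heavily
#' polluted.
#'
#' @param concentration Measured concentration, mg/kg (vectorized).
#' @param background Geochemical background \eqn{B_n}, mg/kg.
#' @return Dimensionless geoaccumulation index.
#' @export
igeo <- function(concentration, background) {
  .check_pos(concentration, "concentration")
  .check_pos(background, "background")
  log2(concentration / (1.5 * background))
}

#' Single-metal potential ecological risk index
#'
#' Hakanson's \eqn{PEI = T_r \cdot P_i}: the single-factor index weighted by
#' the metal's toxicity coefficient.
#'
#' @param pi Single-factor index \eqn{P_i} (vectorized).
#' @param toxicity Toxicity coefficient \eqn{T_r}.
#' @return Dimensionless risk index.
#' @export
pei <- function(pi, toxicity) {
  .check_pos(pi, "pi")
  .check_pos(toxicity, "toxicity")
  pi * toxicity
}

#' Total potential ecological risk index
#'
#' Hakanson's total risk \eqn{TEI = \sum_m PEI_m} over the seven metals.
#' The only index allowed to take zero inputs (it is a pure sum).
#'
#' @param pei_values Seven single-metal risk indices.
#' @return Dimensionless total risk index.
#' @export
tei <- function(pei_values) {
  .check_seven(pei_values, "pei_values")
  if (any(!is.finite(pei_values) | pei_values < 0))
    stop("pei_values must be finite and >= 0", call. = FALSE)
  sum(pei_values)
}

.index_columns <- function() {
  m <- hm_metals()
  c(paste0("Pi_", m), "PI_mean", "PN",
    paste0("Igeo_", m), paste0("PEI_", m), "TEI", "PLI")
}

# scheme kind for each numeric index column
.column_scheme <- function(col) {
  if (startsWith(col, "Pi_")) return("PI")
  if (startsWith(col, "Igeo_")) return("Igeo")
  if (startsWith(col, "PEI_")) return("PEI")
  switch(col, PI_mean = "PI", PN = "PN", PLI = "PLI", TEI = "TEI")
}

#' Compute every index system for every sample
#'
#' For each (site, layer) sample the pipeline computes the per-metal
#' single-factor indices, their mean, the Nemero index, the geometric-mean
#' pollution load index, the per-metal geoaccumulation indices, the
#' per-metal risk indices and the total risk index, classifies each value
#' under its grading scheme, and attaches per-layer summaries (mean, SD,
#' Q1, median, Q3) for every index column.
#'
#' Naming note: the mean single-factor index, the Nemero index and the
#' geometric-mean load index are three distinct statistics and are reported
#' under the unambiguous names `PI_mean`, `PN` and `PLI`. In the source
#' study's summary table the row labelled "PI" is numerically the Nemero
#' index (`PN`) and the row labelled "PLI" the geometric-mean load index.
#'
#' @param samples A `sample_table` (or anything [as_sample_table()] accepts).
#' @param refs A `reference_set`; default [default_reference_set()].
#' @param schemes Grading schemes as from [default_schemes()].
#' @return An object of class `index_table`: list with `samples` (one row
#'   per site x layer, all numeric index columns), `classes` (matching
#'   class labels), `summary` (per layer x index column: mean, sd, q1,
#'   median, q3, n) and `reference` (name + hash of the reference set).
#' @export
index_pipeline <- function(samples, refs = default_reference_set(),
                           schemes = default_schemes()) {
  samples <- as_sample_table(samples)
  stopifnot(inherits(refs, "reference_set"))
  m <- hm_metals()
  wide <- sample_wide(samples)
  conc <- as.matrix(wide[, m])

  pi_m <- sweep(conc, 2, refs$screening[m], "/")
  igeo_m <- log2(sweep(conc, 2, 1.5 * refs$background[m], "/"))
  pei_m <- sweep(pi_m, 2, refs$toxicity[m], "*")
  res <- data.frame(wide[, c("site", "layer")])
  res[paste0("Pi_", m)] <- as.data.frame(pi_m)
  res$PI_mean <- rowMeans(pi_m)
  res$PN <- apply(pi_m, 1, nemero_index)
  res[paste0("Igeo_", m)] <- as.data.frame(igeo_m)
  res[paste0("PEI_", m)] <- as.data.frame(pei_m)
  res$TEI <- rowSums(pei_m)
  res$PLI <- apply(conc, 1, pollution_load_index,
                   background = refs$background[m])

  cols <- .index_columns()
  cls <- res[, c("site", "layer")]
  for (col in cols)
    cls[[col]] <- classify(res[[col]], schemes[[.column_scheme(col)]])

  summ <- do.call(rbind, lapply(split(res, res$layer), function(d) {
    do.call(rbind, lapply(cols, function(col) {
      x <- d[[col]]
      data.frame(layer = d$layer[1], index = col, n = length(x),
                 q1 = unname(stats::quantile(x, 0.25)),
                 median = stats::median(x),
                 q3 = unname(stats::quantile(x, 0.75)),
                 mean = mean(x), sd = stats::sd(x))
    }))
  }))
  rownames(summ) <- NULL

  structure(list(samples = res, classes = cls, summary = summ,
                 reference = list(name = refs$name,
                                  hash = reference_hash(refs))),
            class = "index_table")
}

#' @export
print.index_table <- function(x, ...) {
  cat("Index table:", nrow(x$samples), "samples,",
      length(.index_columns()), "index columns\n")
  cat("reference set:", x$reference$name, "(", x$reference$hash, ")\n")
  print(utils::head(x$samples[, c("site", "layer", "PI_mean", "PN",
                                  "PLI", "TEI")]))
  invisible(x)
}

#' Export an index table to CSV
#'
#' Writes `<stem>_samples.csv`, `<stem>_classes.csv` and
#' `<stem>_summary.csv`, each stamped with the reference-set hash.
#'
#' @param x An `index_table`.
#' @param stem Output path stem.
#' @return The three paths, invisibly.
#' @export
write_index_table <- function(x, stem) {
  stopifnot(inherits(x, "index_table"))
  paths <- paste0(stem, "_", c("samples", "classes", "summary"), ".csv")
  parts <- list(x$samples, x$classes, x$summary)
  for (i in seq_along(paths)) {
    d <- parts[[i]]
    d$reference_hash <- x$reference$hash
    utils::write.csv(d, paths[i], row.names = FALSE)
  }
  invisible(paths)
}
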