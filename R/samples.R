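#' Build a validated sample table
#'
#' The canonical container for measured concentrations: a long-format
#' data frame with one row per (site, layer, metal). Every (site, layer)
#' pair must carry all seven metals exactly once, layers are restricted to
#' `"APMS"`/`"SOIL"`, and concentrations must be strictly positive.
#'
#' @param df Data frame with columns `site`, `layer`, `metal`,
#'   `conc_mg_kg` (long) or `site`, `layer`, plus one column per metal
#'   (wide); the layout is auto-detected from the header.
#' @return A data frame of class `sample_table` (long format), metals in
#'   canonical order within each sample.
#' @export
as_sample_table <- function(df) {
  df <- as.data.frame(df)
  m <- hm_metals()
  long <- all(c("site", "layer", "metal", "conc_mg_kg") %in% names(df))
  wide <- !long && all(c("site", "layer") %in% names(df)) &&
    any(names(df) %in% m)
  if (!long && !wide)
    stop("unrecognized sample header; need site,layer,metal,conc_mg_kg ",
         "(long) or site,layer,<metal columns> (wide)", call. = FALSE)
  if (wide) {
    missing <- setdiff(m, names(df))
    if (length(missing))
      stop("wide table is missing metal column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    extra <- setdiff(names(df), c("site", "layer", m))
    if (length(extra))
      stop("unknown column(s): ", paste(extra, collapse = ", "),
           "; valid metal symbols are ", paste(m, collapse = ", "),
           call. = FALSE)
    df <- data.frame(
      site = rep(df$site, each = length(m)),
      layer = rep(df$layer, each = length(m)),
      metal = rep(m, times = nrow(df)),
      conc_mg_kg = as.numeric(t(as.matrix(df[, m]))),
      stringsAsFactors = FALSE)
  }
  df$site <- as.character(df$site)
  df$layer <- as.character(df$layer)
  df$metal <- as.character(df$metal)
  df$conc_mg_kg <- as.numeric(df$conc_mg_kg)

  bad_layer <- setdiff(unique(df$layer), hm_layers())
  if (length(bad_layer))
    stop("unknown layer label(s): ", paste(bad_layer, collapse = ", "),
         "; layers must be APMS or SOIL", call. = FALSE)
  bad_metal <- setdiff(unique(df$metal), m)
  if (length(bad_metal))
    stop("unknown metal symbol(s): ", paste(bad_metal, collapse = ", "),
         "; valid symbols are ", paste(m, collapse = ", "), call. = FALSE)
  nonpos <- which(!is.finite(df$conc_mg_kg) | df$conc_mg_kg <= 0)
  if (length(nonpos))
    stop("non-positive or missing concentration at row(s): ",
         paste(utils::head(nonpos, 5), collapse = ", "), call. = FALSE)
  key <- paste(df$site, df$layer, df$metal)
  if (anyDuplicated(key))
    stop("duplicate (site, layer, metal) row(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "),
         call. = FALSE)
  cnt <- table(paste(df$site, df$layer))
  if (any(cnt != length(m)))
    stop("each (site, layer) needs all seven metals; incomplete: ",
         paste(utils::head(names(cnt)[cnt != length(m)], 3), collapse = "; "),
         call. = FALSE)

  ord <- order(df$layer, df$site, match(df$metal, m))
  df <- df[ord, c("site", "layer", "metal", "conc_mg_kg")]
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample table from CSV
#'
#' Accepts the wide schema (`site,layer,Cr,Ni,Cu,Zn,As,Cd,Pb`) or the long
#' schema (`site,layer,metal,conc_mg_kg`), auto-detected from the header.
#'
#' @param path CSV file path.
#' @return A `sample_table`.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  as_sample_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a sample table to CSV
#'
#' @param samples A `sample_table`.
#' @param path Output path.
#' @param format `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path, format = c("long", "wide")) {
  format <- match.arg(format)
  samples <- as_sample_table(samples)
  out <- if (format == "wide") sample_wide(samples) else samples
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(path)
}

#' Pivot a sample table to wide format
#'
#' @param samples A `sample_table`.
#' @return Data frame with columns `site`, `layer` and one concentration
#'   column per metal, metals in canonical order.
#' @export
sample_wide <- function(samples) {
  samples <- as_sample_table(samples)
  m <- hm_metals()
  keys <- unique(samples[, c("site", "layer")])
  rownames(keys) <- NULL
  mat <- matrix(NA_real_, nrow(keys), length(m),
                dimnames = list(NULL, m))
  idx <- match(paste(samples$site, samples$layer),
               paste(keys$site, keys$layer))
  mat[cbind(idx, match(samples$metal, m))] <- samples$conc_mg_kg
  cbind(keys, as.data.frame(mat))
}
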