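# Per-stage seeds are derived from the single run seed by fixed small
# offsets so every stochastic stage is independently reproducible.
.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, multivariate = 2L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

.write_stamped <- function(df, path, hash) {
  df <- as.data.frame(df)
  df$reference_hash <- hash
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full assessment workflow into an output directory
#'
#' One invocation computes and writes every artifact of the analysis:
#' the index table (per-sample values, class labels, per-layer summaries),
#' the descriptive summary with layer tests, the per-layer correlation
#' tables, PCA loadings and per-axis contributions, the supervised
#' embedding with group ellipses, the stepwise model suite, and a JSON run
#' manifest. Stage failures are caught and recorded in the manifest;
#' later independent stages still run. Every CSV is stamped with the
#' reference-set hash.
#'
#' @param samples A `sample_table`, or `NULL` to simulate one from
#'   `synthetic_spec(seed = ...)`.
#' @param refs A `reference_set`.
#' @param out_dir Output directory (created if needed).
#' @param seed Run seed; expanded per stage by a fixed offset rule.
#' @param skip Character vector of stage names to skip; stages are
#'   `simulate`, `indices`, `describe`, `correlation`, `multivariate`,
#'   `models`.
#' @param primary_test Primary layer test, `"wilcoxon"` or `"welch"`.
#' @return Invisible list of stage results plus `manifest`.
#' @export
run_report <- function(samples = NULL, refs = default_reference_set(),
                       out_dir, seed = 1, skip = character(),
                       primary_test = "wilcoxon") {
  stopifnot(inherits(refs, "reference_set"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- reference_hash(refs)
  manifest <- list(package_version = as.character(utils::packageVersion("metalrisk")),
                   seed = as.integer(seed),
                   reference = list(name = refs$name, hash = hash),
                   parameters = list(primary_test = primary_test),
                   stages = list())
  results <- list()
  status <- function(name, state, detail = NULL) {
    manifest$stages[[name]] <<- list(status = state, detail = detail)
  }
  stage <- function(name, expr) {
    if (name %in% skip) { status(name, "skipped"); return(NULL) }
    tryCatch({ v <- force(expr); status(name, "ok"); v },
             error = function(e) {
               status(name, "failed", conditionMessage(e)); NULL })
  }

  results$samples <- stage("simulate", {
    if (is.null(samples)) {
      s <- generate_samples(
        synthetic_spec(seed = .stage_seed(seed, "simulate")))
    } else s <- as_sample_table(samples)
    .write_stamped(s, file.path(out_dir, "samples.csv"), hash)
    s
  })
  s <- results$samples
  if (is.null(s)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(c(results, list(manifest = manifest))))
  }
  wide <- sample_wide(s)

  results$indices <- stage("indices", {
    idx <- index_pipeline(s, refs)
    write_index_table(idx, file.path(out_dir, "index"))
    idx
  })
  results$summary <- stage("describe", {
    d <- describe(wide[, hm_metals()], wide$layer, primary_test)
    if (!is.null(results$indices)) {
      di <- describe(results$indices$samples[, .index_columns()],
                     results$indices$samples$layer, primary_test)
      d <- rbind(d, di)
    }
    .write_stamped(d, file.path(out_dir, "summary.csv"), hash)
    d
  })
  results$correlation <- stage("correlation", {
    tab <- if (!is.null(results$indices))
      cbind(wide[, hm_metals()],
            results$indices$samples[, c(paste0("Igeo_", hm_metals()),
                                        paste0("PEI_", hm_metals()),
                                        "PN", "PLI")])
    else wide[, hm_metals()]
    cl <- correlation_by_layer(tab, wide$layer)
    for (g in names(cl))
      .write_stamped(cl[[g]]$long,
                     file.path(out_dir, paste0("correlation_", g, ".csv")),
                     hash)
    cl
  })
  results$multivariate <- stage("multivariate", {
    tab <- cbind(wide[, hm_metals()],
                 results$indices$samples[, c(paste0("Igeo_", hm_metals()),
                                             paste0("PEI_", hm_metals()),
                                             "PN", "PLI")])
    z <- standardize(tab)
    pca <- pca_profile(z, center = FALSE)
    contrib <- do.call(rbind, lapply(
      seq_len(min(4L, ncol(pca$loadings))), function(a)
        cbind(axis = a, top_contributors(pca, a))))
    emb <- supervised_embedding(z, wide$layer,
                                seed = .stage_seed(seed, "multivariate"))
    .write_stamped(as.data.frame(pca$loadings),
                   file.path(out_dir, "pca_loadings.csv"), hash)
    .write_stamped(contrib, file.path(out_dir, "pca_contributions.csv"),
                   hash)
    .write_stamped(data.frame(site = wide$site, layer = wide$layer,
                              emb$coords),
                   file.path(out_dir, "embedding.csv"), hash)
    list(pca = pca, contributions = contrib, embedding = emb)
  })
  results$models <- stage("models", {
    suite <- model_suite(model_data(s, refs))
    write_model_suite(suite, file.path(out_dir, "models"))
    suite
  })

  for (nm in c("indices", "describe", "correlation", "multivariate",
               "models"))
    if (is.null(manifest$stages[[nm]]))
      manifest$stages[[nm]] <- list(status = "not run")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}
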