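test_that("single-factor index is the concentration/screening ratio", {
  expect_equal(single_factor_index(1.129, 0.6), 1.8816667, tolerance = 1e-7)
  expect_equal(single_factor_index(300, 300), 1)
  # cross-check: five times the Ni ratio is the published mean risk index
  expect_equal(5 * single_factor_index(205.84, 190), 5.417, tolerance = 1e-4)
  expect_error(single_factor_index(-1, 10), "> 0")
  expect_error(single_factor_index(10, 0), "> 0")
})

test_that("mean index and Nemero index follow their closed forms", {
  expect_equal(mean_pi(rep(1, 7)), 1)
  expect_error(mean_pi(rep(1, 6)), "seven")
  expect_error(mean_pi(c(rep(1, 6), 0)), "> 0")
  expect_equal(nemero_index(rep(1, 7)), 1)
  pi7 <- c(0.2, 0.4, 1.1, 2.0, 0.6, 0.9, 1.5)
  expect_equal(nemero_index(pi7),
               sqrt((mean(pi7)^2 + max(pi7)^2) / 2))
})

test_that("Nemero index is bounded by [max/sqrt(2), max] on random vectors", {
  set.seed(101)
  for (i in 1:1000) {
    p <- stats::rlnorm(7, 0, 1)
    pn <- nemero_index(p)
    expect_gte(pn, max(p) / sqrt(2))
    expect_lte(pn, max(p))
    expect_gte(pn, mean(p) / sqrt(2))
  }
})

test_that("load index is the geometric mean of concentration/background", {
  B <- target_means("APMS")
  expect_equal(pollution_load_index(B, B), 1)
  expect_equal(pollution_load_index(2 * B, B), 2)
  got <- pollution_load_index(target_means("APMS"),
                              default_reference_set()$background)
  # reconstructed backgrounds: agreement with the published 3.010 is loose
  expect_equal(got, 3.010, tolerance = 0.05)
})

test_that("geoaccumulation and risk indices follow their formulas", {
  expect_equal(igeo(1.5 * 40, 40), 0)
  expect_equal(igeo(3 * 40, 40), 1)
  expect_equal(igeo(1.129, 0.0763), 3.302, tolerance = 1e-3)
  expect_equal(pei(1.8816667, 30), 56.45, tolerance = 1e-5)
  expect_equal(pei(1, 1), 1)
  expect_equal(tei(rep(0, 7)), 0)
  expect_error(tei(rep(1, 6)), "seven")
  p <- published_pei_means("APMS")
  expect_equal(tei(p), 73.897, tolerance = 1e-6)
  expect_equal(tei(published_pei_means("SOIL")), 65.006, tolerance = 1e-6)
})

test_that("pipeline reproduces the closed-form toy profile", {
  refs <- toy_refs()
  idx <- index_pipeline(toy_samples(refs), refs)
  s <- idx$samples
  expect_equal(nrow(s), 2)
  expect_equal(unname(unlist(s[, paste0("Pi_", hm_metals())])),
               rep(1, 14))
  expect_equal(s$PI_mean, c(1, 1))
  expect_equal(s$PN, c(1, 1))
  expect_equal(unname(unlist(s[, paste0("Igeo_", hm_metals())])),
               rep(0, 14))
  expect_equal(s$TEI, c(58, 58))
  expect_equal(s$PLI, c(1.5, 1.5))
  expect_equal(idx$classes$TEI, rep("low risk", 2))
  expect_equal(idx$classes$PEI_Cd, rep("low risk", 2))
})

test_that("total risk is additive and linear in the layer means", {
  idx <- index_pipeline(fixture_samples(seed = 3))
  peim <- as.matrix(idx$samples[, paste0("PEI_", hm_metals())])
  expect_true(all(abs(idx$samples$TEI - rowSums(peim)) < 1e-9))
  # moment matching makes the layer-mean TEI equal TEI of the layer means
  sm <- idx$summary
  refs <- default_reference_set()
  for (layer in hm_layers()) {
    want <- sum(refs$toxicity * target_means(layer) / refs$screening)
    expect_equal(sm$mean[sm$layer == layer & sm$index == "TEI"], want,
                 tolerance = 1e-9)
  }
})

test_that("indices obey the scaling laws under concentration doubling", {
  s <- random_samples(6, seed = 9)
  s2 <- s; s2$conc_mg_kg <- 2 * s2$conc_mg_kg
  a <- index_pipeline(s)$samples
  b <- index_pipeline(as_sample_table(s2))$samples
  for (col in c(paste0("Pi_", hm_metals()), paste0("PEI_", hm_metals()),
                "PI_mean", "PN", "TEI", "PLI"))
    expect_equal(b[[col]], 2 * a[[col]], tolerance = 1e-12, info = col)
  for (col in paste0("Igeo_", hm_metals()))
    expect_equal(b[[col]], a[[col]] + 1, tolerance = 1e-12, info = col)
})

test_that("pipeline summaries cover every index column with sane quantiles", {
  idx <- index_pipeline(fixture_samples(seed = 2))
  sm <- idx$summary
  cols <- unique(sm$index)
  expect_setequal(cols, c(paste0("Pi_", hm_metals()), "PI_mean", "PN",
                          paste0("Igeo_", hm_metals()),
                          paste0("PEI_", hm_metals()), "TEI", "PLI"))
  expect_true(all(sm$q1 <= sm$median & sm$median <= sm$q3))
  expect_true(all(sm$sd >= 0) && all(sm$n == 8))
  expect_match(idx$reference$hash, "^[0-9a-f]{32}$")
})
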