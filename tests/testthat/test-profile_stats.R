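test_that("describe computes type-7 quantiles and n-1 standard deviations", {
  x <- data.frame(v = c(1:8, 11:18))
  by <- rep(c("APMS", "SOIL"), each = 8)
  d <- describe(x, by)
  a <- d[d$layer == "APMS", ]
  expect_equal(a$median, 4.5)
  expect_equal(a$mean, 4.5)
  expect_equal(a$sd, sqrt(6), tolerance = 1e-9)
  expect_equal(a$q1, unname(stats::quantile(1:8, 0.25)))
  expect_equal(a$n, 8)
  expect_true(all(c("p_value", "p_wilcoxon", "p_welch") %in% names(d)))
})

test_that("describe reproduces the fixture's exact layer moments", {
  w <- sample_wide(fixture_samples(seed = 5))
  d <- describe(w[, hm_metals()], w$layer)
  for (layer in hm_layers()) {
    mu <- target_means(layer); sg <- target_sds(layer)
    for (m in hm_metals()) {
      row <- d[d$variable == m & d$layer == layer, ]
      expect_equal(row$mean, unname(mu[m]), tolerance = 1e-9)
      expect_equal(row$sd, unname(sg[m]), tolerance = 1e-9)
    }
  }
  expect_error(describe(data.frame(v = c(1, 2)), c("APMS", "SOIL")),
               ">= 2 observations")
})

test_that("layer test returns both tests; degenerate cases behave", {
  g <- rep(c("APMS", "SOIL"), each = 4)
  same <- c(1, 2, 3, 4, 1, 2, 3, 4)
  lt <- layer_test(same, g)
  expect_equal(lt$p_wilcoxon, 1)
  expect_equal(lt$p_welch, 1)          # equal means and SDs: t = 0
  expect_equal(lt$test, "wilcoxon")
  expect_equal(layer_test(same, g, primary = "welch")$p, lt$p_welch)
  expect_error(layer_test(1:5, c("a", "a", "a", "a", "b")), "at least 2")
})

test_that("exact Wilcoxon p matches full enumeration of rank assignments", {
  x <- c(1:8, 9:16)
  g <- rep(c("APMS", "SOIL"), each = 8)
  got <- layer_test(x, g)$p_wilcoxon
  # oracle: enumerate all C(16,8) ways to assign ranks to group 1
  ranks <- rank(x)
  obs <- sum(ranks[1:8])
  all_sums <- combn(16, 8, function(i) sum(ranks[i]))
  ew <- mean(all_sums)
  p_exact <- mean(abs(all_sums - ew) >= abs(obs - ew) - 1e-9)
  expect_equal(got, p_exact, tolerance = 1e-12)

  # a non-extreme configuration as well
  set.seed(8); y <- stats::rnorm(16)
  goty <- layer_test(y, g)$p_wilcoxon
  ry <- rank(y); obsy <- sum(ry[1:8])
  sums <- combn(16, 8, function(i) sum(ry[i]))
  py <- mean(abs(sums - mean(sums)) >= abs(obsy - mean(sums)) - 1e-9)
  expect_equal(goty, py, tolerance = 1e-12)
})

test_that("rank-test p-values are invariant under monotone index transforms", {
  s <- fixture_samples(seed = 11)
  idx <- index_pipeline(s)$samples
  w <- sample_wide(s)
  for (m in c("Zn", "Cd")) {
    p_conc <- layer_test(w[[m]], w$layer)$p_wilcoxon
    p_igeo <- layer_test(idx[[paste0("Igeo_", m)]], idx$layer)$p_wilcoxon
    p_pei  <- layer_test(idx[[paste0("PEI_", m)]], idx$layer)$p_wilcoxon
    expect_identical(p_conc, p_igeo)
    expect_identical(p_conc, p_pei)
  }
})

test_that("correlation matrix matches the direct Pearson formula", {
  set.seed(21)
  x <- stats::rnorm(8); y <- stats::rnorm(8)
  cm <- correlation_matrix(data.frame(x = x, y = y, z = 2 * x + 1))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    ((length(x) - 1) * stats::sd(x) * stats::sd(y))
  expect_equal(cm$r["x", "y"], r_hand, tolerance = 1e-12)
  expect_equal(cm$r["x", "z"], 1, tolerance = 1e-12)
  expect_equal(cm$p["x", "z"], 0)
  cm2 <- correlation_matrix(data.frame(x = x, y = -x))
  expect_equal(cm2$r["x", "y"], -1, tolerance = 1e-12)
  expect_equal(diag(cm$r), c(x = 1, y = 1, z = 1))
  expect_true(isSymmetric(cm$r))
})

test_that("zero-variance variables are flagged, not dropped", {
  cm <- correlation_matrix(data.frame(a = 1:5, b = rep(2, 5)))
  expect_equal(cm$degenerate, "b")
  expect_true(is.na(cm$r["a", "b"]))
  expect_true("b" %in% cm$long$var2)
})

test_that("star assignment agrees with recomputed p on random tables", {
  set.seed(33)
  for (i in 1:300) {
    tab <- matrix(stats::rnorm(8 * 4), 8, 4,
                  dimnames = list(NULL, letters[1:4]))
    cm <- correlation_matrix(tab)
    for (k in seq_len(nrow(cm$long))) {
      p_ref <- stats::cor.test(tab[, cm$long$var1[k]],
                               tab[, cm$long$var2[k]])$p.value
      expect_equal(cm$long$p[k], p_ref, tolerance = 1e-9)
      expect_identical(cm$long$stars[k], sig_stars(p_ref))
    }
  }
})

test_that("per-layer wrapper computes each layer separately", {
  w <- sample_wide(fixture_samples(seed = 4))
  cl <- correlation_by_layer(w[, hm_metals()], w$layer)
  expect_named(cl, hm_layers())
  ref <- correlation_matrix(w[w$layer == "SOIL", hm_metals()])
  expect_equal(cl$SOIL$r, ref$r)
})
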