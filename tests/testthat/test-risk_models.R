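test_that("VIF matches the 1/(1-R2) regression oracle", {
  set.seed(41)
  x1 <- stats::rnorm(30); x2 <- stats::rnorm(30)
  x3 <- x1 + x2 + stats::rnorm(30, sd = 0.01)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  r2 <- summary(stats::lm(x3 ~ x1 + x2))$r.squared
  expect_equal(unname(vif(X)["x3"]), 1 / (1 - r2), tolerance = 1e-8)
})

test_that("collinearity pruning removes duplicates, keeps orthogonal sets", {
  set.seed(42)
  a <- stats::rnorm(20)
  pr <- prune_collinear(cbind(a = a, b = a, c = stats::rnorm(20)))
  expect_true(sum(pr$keep %in% c("a", "b")) == 1)
  Q <- qr.Q(qr(matrix(stats::rnorm(20 * 3), 20, 3)))
  colnames(Q) <- c("q1", "q2", "q3")
  pr2 <- prune_collinear(Q)
  expect_equal(pr2$keep, c("q1", "q2", "q3"))
  expect_equal(nrow(pr2$dropped), 0)
  expect_warning(prune_collinear(cbind(a = a, b = a)), "fewer than 2")
})

test_that("LMG importance equals brute-force ordering enumeration", {
  set.seed(43)
  n <- 30
  X <- matrix(stats::rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, 0.5, 0.2) + stats::rnorm(n)
  got <- lmg_importance(X, y)
  # independent oracle: average sequential R2 increments over all 6 orders
  r2of <- function(cols) {
    if (!length(cols)) return(0)
    summary(stats::lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  contrib <- matrix(0, 6, 3)
  for (i in 1:6) for (k in 1:3) {
    before <- perms[i, seq_len(k - 1)]
    contrib[i, perms[i, k]] <- r2of(c(before, perms[i, k])) - r2of(before)
  }
  oracle <- colMeans(contrib)
  expect_equal(got$lmg, oracle, tolerance = 1e-10)
  expect_equal(sum(got$lmg), r2of(1:3), tolerance = 1e-10)
  expect_equal(sum(got$share), 1, tolerance = 1e-12)
})

test_that("LMG closed forms hold for orthogonal and duplicated predictors", {
  set.seed(44)
  Q <- qr.Q(qr(matrix(stats::rnorm(40 * 2), 40, 2)))
  Q <- scale(Q); colnames(Q) <- c("u", "v")
  y <- 2 * Q[, 1] + 0.5 * Q[, 2] + stats::rnorm(40, sd = 0.3)
  got <- lmg_importance(Q, y)
  beta <- stats::coef(stats::lm(y ~ Q))[-1]
  expect_equal(got$share, unname(beta^2 / sum(beta^2)), tolerance = 0.02)

  a <- stats::rnorm(25); y2 <- a + stats::rnorm(25, sd = 0.1)
  twin <- lmg_importance(cbind(p = a, q = a), y2)
  expect_equal(twin$share, c(0.5, 0.5), tolerance = 1e-10)
  single <- lmg_importance(cbind(only = a), y2)
  expect_equal(single$share, 1)
})

test_that("stepwise search recovers exact structure and respects AIC", {
  s <- fixture_samples(seed = 6)
  d <- model_data(s)
  fit <- suppressWarnings(
    stepwise_fit(d, "TEI", paste0("PEI_", hm_metals())))
  expect_gt(fit$adj_r2, 0.999)
  # AIC guarantee, on data without an exact fit so criteria are stable
  set.seed(46)
  dn <- data.frame(y = stats::rnorm(20))
  dn$x1 <- dn$y + stats::rnorm(20, sd = 0.8)
  dn$x2 <- stats::rnorm(20); dn$x3 <- stats::rnorm(20)
  fn <- stepwise_fit(dn, "y", c("x1", "x2", "x3"))
  zn <- as.data.frame(standardize(dn))
  expect_lte(fn$aic, stats::AIC(stats::lm(y ~ 1, data = zn)))
  expect_lte(fn$aic,
             stats::AIC(stats::lm(y ~ x1 + x2 + x3, data = zn)) + 1e-9)
  fit2 <- suppressWarnings(
    stepwise_fit(d, "TEI", paste0("PEI_", hm_metals())))
  expect_identical(fit$selected, fit2$selected)
  expect_equal(fit$coefficients, fit2$coefficients)
  expect_error(stepwise_fit(d, "TEI", c("TEI", "Cu")), "response")
})

test_that("reported fit statistics are invariant to input rescaling", {
  set.seed(45)
  d <- data.frame(y = stats::rnorm(20))
  d$x1 <- d$y + stats::rnorm(20, sd = 0.5)
  d$x2 <- stats::rnorm(20)
  f1 <- stepwise_fit(d, "y", c("x1", "x2"))
  d2 <- d; d2$x1 <- d2$x1 * 1000
  f2 <- stepwise_fit(d2, "y", c("x1", "x2"))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-9)
  expect_equal(f1$adj_r2, f2$adj_r2, tolerance = 1e-12)
  expect_equal(f1$importance$share, f2$importance$share, tolerance = 1e-9)
})

test_that("pure-noise candidates never beat the AIC guarantee", {
  kept_null <- 0L
  for (r in 1:50) {
    set.seed(r)
    d <- as.data.frame(matrix(stats::rnorm(16 * 6), 16, 6))
    names(d) <- c("y", paste0("x", 1:5))
    fit <- stepwise_fit(d, "y", paste0("x", 1:5))
    null_aic <- stats::AIC(stats::lm(
      y ~ 1, data = as.data.frame(standardize(d))))
    expect_lte(fit$aic, null_aic)
    if (!length(fit$selected)) kept_null <- kept_null + 1L
  }
  expect_gt(kept_null, 0L)   # the null model is reachable and sometimes kept
})

test_that("model suite fits the four adjustment structures on the fixture", {
  d <- model_data(fixture_samples(seed = 12))
  suite <- suppressWarnings(model_suite(d))
  expect_named(suite$models, paste0("model", 0:3))
  # the exact identity TEI = sum of risk terms makes the suite saturate
  expect_gt(suite$models$model2$adj_r2, 0.999)
  expect_gt(suite$models$model3$adj_r2, 0.99)
  # the comparison table mirrors terms x models with a performance block
  expect_true(all(paste0("model", 0:3) %in% names(suite$comparison)))
  expect_true(all(c("Adj.R2", "AIC", "BIC") %in% suite$comparison$variable))
  expect_error(model_suite(d[, setdiff(names(d), "PLI")]), "pollution")
  # importance shares over selected terms sum to one
  for (f in suite$models)
    if (length(f$selected))
      expect_equal(sum(f$importance$share), 1, tolerance = 1e-9)
})

test_that("information criteria recompute from the stored residuals", {
  d <- model_data(fixture_samples(seed = 13))
  fit <- suppressWarnings(stepwise_fit(d, "TEI", hm_metals()))
  lmfit <- fit$fit
  n <- fit$n; k <- length(stats::coef(lmfit))
  rss <- sum(stats::residuals(lmfit)^2)
  aic_hand <- n * log(2 * pi * rss / n) + n + 2 * (k + 1)
  bic_hand <- n * log(2 * pi * rss / n) + n + log(n) * (k + 1)
  expect_equal(fit$aic, aic_hand, tolerance = 1e-8)
  expect_equal(fit$bic, bic_hand, tolerance = 1e-8)
  expect_gte(fit$bic, fit$aic)   # log(16) > 2
})
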