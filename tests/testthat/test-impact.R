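test_that("a perfect covariate yields beta near 1 and near-zero level noise", {
  set.seed(1)
  y <- 0.05 + cumsum(rnorm(20, 0, 0.01))
  f <- fit_pre_period(y, y)
  expect_true(f$estimable)
  expect_equal(f$beta, 1, tolerance = 0.05)
  expect_lt(f$sigma_lvl, 0.01 * sd(y))
  expect_equal(f$fitted[-(1:2)], y[-(1:2)], tolerance = 1e-3)
})

test_that("degenerate inputs are handled without blowing up", {
  set.seed(2)
  y <- rnorm(15, 0.02, 0.002)
  f <- fit_pre_period(y, rep(0.5, 15))      # constant covariate
  expect_true(f$estimable)
  expect_true(all(is.finite(c(f$sigma_obs, f$sigma_lvl, f$beta, f$mu0))))
  expect_lt(f$sigma_lvl, 0.5 * sd(y))
  f0 <- fit_pre_period(rep(0, 15), y)       # constant-zero target
  expect_false(f0$estimable)
  expect_match(f0$reason, "constant")
  expect_error(fit_pre_period(c(1, 2, NA), c(1, 2, 3)), "length|finite")
  expect_error(fit_pre_period(1:4, 1:4), ">= 5")
})

test_that("the noiseless counterfactual is the closed form mu_T + beta x_t", {
  f <- impact_fit(sigma_obs = 0, sigma_lvl = 0, beta = 2, mu0 = 0)
  tr <- predict_counterfactual(f, c(0.1, 0.2), n_sim = 200, seed = 1)
  expect_true(all(abs(tr[, 1] - 0.2) < 1e-12))
  expect_true(all(abs(tr[, 2] - 0.4) < 1e-12))
  # fixed seed: identical draw matrices
  f2 <- impact_fit(0.01, 0.005, beta = 1, mu0 = 0.02, P_T = 1e-4)
  a <- predict_counterfactual(f2, rep(0.02, 5), n_sim = 100, seed = 42)
  b <- predict_counterfactual(f2, rep(0.02, 5), n_sim = 100, seed = 42)
  expect_identical(a, b)
})

test_that("relative effect is exact in the noiseless limit", {
  f <- impact_fit(0, 0, beta = 1, mu0 = 0.2)
  x_post <- rep(0, 10)
  tr <- predict_counterfactual(f, x_post, n_sim = 150, seed = 1)
  # observed 1.25x the prediction -> +25% exactly
  res <- summarize_effect(rep(0.25, 10), tr, impact_config(n_sim = 150))
  expect_equal(res$summary$relative_effect, 0.25, tolerance = 1e-12)
  # observed equal to the prediction -> 0
  res0 <- summarize_effect(rep(0.2, 10), tr, impact_config(n_sim = 150))
  expect_equal(res0$summary$relative_effect, 0, tolerance = 1e-12)
})

test_that("cumulative effect is exactly the running sum of pointwise effects", {
  set.seed(3)
  f <- impact_fit(0.01, 0.002, beta = 0.8, mu0 = 0.02, P_T = 1e-5)
  for (i in 1:5) {
    y_post <- rnorm(8, 0.03, 0.005)
    tr <- predict_counterfactual(f, rnorm(8, 0.02, 0.003), n_sim = 120)
    r <- summarize_effect(y_post, tr, impact_config(n_sim = 120))
    expect_identical(r$series$cumulative, cumsum(r$series$pointwise))
    expect_equal(r$series$cumulative[8], sum(r$series$pointwise))
    s <- r$summary
    expect_true(s$ci_lower <= s$relative_effect &&
                  s$relative_effect <= s$ci_upper)
    expect_true(s$p_value > 0 && s$p_value <= 1)
  }
})

test_that("the estimator is scale-equivariant", {
  set.seed(4)
  x <- 0.02 + rnorm(30, 0, 0.002)
  y <- x + rnorm(30, 0, 0.002)
  y[16:30] <- y[16:30] * 1.1
  d <- tibble::tibble(relative_day = -15:14, target = y, control = x)
  cfg <- impact_config(n_sim = 300, seed = 11)
  r1 <- estimate_impact(d, cfg)
  d2 <- dplyr::mutate(d, target = target * 50, control = control * 50)
  r2 <- estimate_impact(d2, cfg)
  expect_equal(r1$summary$relative_effect, r2$summary$relative_effect,
               tolerance = 1e-6)
  expect_equal(r1$summary$p_value, r2$summary$p_value, tolerance = 1e-12)
})

test_that("long-series simulation recovers the generating parameters", {
  set.seed(5)
  est <- t(replicate(100, {
    n <- 200
    mu <- cumsum(rnorm(n, 0, 0.005))
    x <- rnorm(n, 0, 1) + 2
    y <- mu + 0.8 * x + rnorm(n, 0, 0.01)
    f <- fit_pre_period(y, x)
    c(f$sigma_obs, f$sigma_lvl, f$beta)
  }))
  truth <- c(0.01, 0.005, 0.8)
  rel_err <- abs(colMeans(est) - truth) / truth
  expect_true(all(rel_err < 0.25))
})

test_that("significance tiers apply the per-group Bonferroni correction", {
  expect_equal(bonferroni_level(0.05, 51), 0.05 / 51)
  expect_equal(bonferroni_level(0.05, 1), 0.05)
  expect_error(bonferroni_level(1.5, 10), "probability")

  set.seed(6)
  ser <- tidyr::expand_grid(category = c("A", "B"), group = "all",
                            role = c("target", "baseline"),
                            relative_day = -15:14) |>
    dplyr::mutate(value = 0.02 + rnorm(dplyr::n(), 0, 0.002), n_users = 50)
  # make category A's post period clearly elevated
  ser$value[ser$category == "A" & ser$role == "target" &
              ser$relative_day >= 0] <- 0.08
  res <- run_impact(ser, impact_config(n_sim = 300, seed = 7))
  expect_equal(nrow(res), 2)
  expect_equal(res$category[1], "A")           # sorted by effect
  expect_equal(unique(res$corrected_level), 0.05 / 2)
  expect_equal(res$significance[res$category == "A"], "bonferroni")
  # identical seed, identical table
  res2 <- run_impact(ser, impact_config(n_sim = 300, seed = 7))
  expect_identical(dplyr::select(res, -result), dplyr::select(res2, -result))
})

test_that("tidy and glance methods expose fits and results broom-style", {
  set.seed(8)
  y <- 0.02 + rnorm(15, 0, 0.002)
  f <- fit_pre_period(y, y + rnorm(15, 0, 0.001))
  td <- tidy(f)
  expect_equal(td$term, c("sigma_obs", "sigma_lvl", "beta", "mu0"))
  expect_true(all(is.finite(td$estimate)))
  expect_equal(glance(f)$nobs, 15)
  d <- tibble::tibble(relative_day = -15:14,
                      target = 0.02 + rnorm(30, 0, 0.002),
                      control = 0.02 + rnorm(30, 0, 0.002))
  r <- estimate_impact(d, impact_config(n_sim = 150, seed = 1))
  expect_equal(nrow(tidy(r)), 15)
  expect_equal(names(glance(r))[1:2], c("category", "group"))
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
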