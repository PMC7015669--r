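test_that("AICc follows the Gaussian least-squares convention", {
  expect_equal(as.numeric(aicc(1e-4, 10, 2)), -109.41497, tolerance = 1e-5)
  # penalty monotone in k at equal rss
  expect_gt(as.numeric(aicc(1e-4, 10, 3)), as.numeric(aicc(1e-4, 10, 2)))
  # rss -> 0 is floored with a flag instead of returning -Inf
  a0 <- aicc(0, 10, 2)
  expect_true(is.finite(as.numeric(a0)))
  expect_true(attr(a0, "rss_floored"))
  expect_error(aicc(1e-4, 4, 3), "need n > k")
})

test_that("fitting the generating model is an exact fixed point", {
  dec <- make_tpl_decay(beta = 0.35, Da_perp = 8.6e-4)
  fit <- fit_decay_model(dec, "vii", b_min = 6)
  expect_true(fit$converged)
  expect_equal(fit$params[["beta"]], 0.35, tolerance = 1e-6)
  expect_equal(fit$params[["Da_perp"]], 8.6e-4, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-18)
  # any b_min gives the same fixed point
  fit20 <- fit_decay_model(dec, "vii", b_min = 12)
  expect_equal(fit20$params[["beta"]], 0.35, tolerance = 1e-6)
})

test_that("a free-intercept power law fit to truncated-power-law data extrapolates negative", {
  dec <- make_tpl_decay(beta = 0.35, Da_perp = 2e-3, f_im = 0)
  fit <- fit_decay_model(dec, "ii", b_min = 6)
  expect_lt(fit$gamma, 0)
})

test_that("the free exponent recovers 1/2 on pure power-law data", {
  p <- protocol_preset("connectom")
  b <- protocol_bvalues(p)
  dec <- spherical_mean_decay(b, 0.4 * b^(-0.5))
  fit <- fit_decay_model(dec, "v", b_min = 6)
  expect_equal(fit$params[["alpha"]], 0.5, tolerance = 1e-4)
  expect_equal(fit$params[["beta"]], 0.4, tolerance = 1e-4)
})

test_that("nested models never fit worse than their restriction", {
  set.seed(3)
  b <- protocol_bvalues(protocol_preset("connectom"))
  b <- b[b >= 6]
  y <- truncated_powerlaw(0.35, 1.5e-3, 0.02, b) + rnorm(length(b), 0, 2e-3)
  dec <- spherical_mean_decay(b, y)
  pairs <- list(c("v", "vi"), c("vii", "vi"), c("viii", "vi"),
                c("i", "ii"), c("iii", "ii"), c("iv", "ii"), c("ii", "vi"))
  for (pr in pairs) {
    full <- fit_decay_model(dec, pr[1], b_min = 6)
    nested <- fit_decay_model(dec, pr[2], b_min = 6)
    expect_lte(full$rss, nested$rss * (1 + 1e-8))
  }
})

test_that("fits are invariant to shell order and equivariant under rescaling", {
  dec <- make_tpl_decay(beta = 0.3, Da_perp = 1e-3)
  fit <- fit_decay_model(dec, "vii", b_min = 6)
  # shuffled shells
  o <- c(5, 2, 9, 1, 12, 3, 11, 6, 13, 4, 8, 10, 7)
  dec2 <- spherical_mean_decay(dec$b_values[o], dec$S_bar[o])
  fit2 <- fit_decay_model(dec2, "vii", b_min = 6)
  expect_equal(fit2$params, fit$params, tolerance = 1e-9)
  # rescaling the signal scales beta, leaves Da_perp
  dec3 <- dec; dec3$S_bar <- dec$S_bar * 0.5
  fit3 <- fit_decay_model(dec3, "vii", b_min = 6)
  expect_equal(fit3$params[["beta"]], fit$params[["beta"]] * 0.5,
               tolerance = 1e-6)
  expect_equal(fit3$params[["Da_perp"]], fit$params[["Da_perp"]],
               tolerance = 1e-6)
})

test_that("negative fitted Da_perp is flagged implausible, not an error", {
  # a decay shallower than b^{-1/2} (uncorrected dot floor) drives the fitted
  # radial diffusivity negative
  b <- seq(20, 100, length.out = 10)
  y <- truncated_powerlaw(0.59, 1e-3, 0.13, b)
  fit <- fit_decay_model(spherical_mean_decay(b, y), "vii", b_min = 20)
  expect_lt(fit$params[["Da_perp"]], 0)
  expect_false(fit$plausible)
})

test_that("constrained mode keeps the intercept non-negative", {
  dec <- make_tpl_decay(beta = 0.35, Da_perp = 2e-3, f_im = 0)
  free <- fit_decay_model(dec, "ii", b_min = 6)
  constrained <- fit_decay_model(dec, "ii", b_min = 6, constrain_fim = TRUE)
  expect_lt(free$gamma, 0)
  expect_gte(constrained$gamma, 0)
  expect_gte(constrained$rss, free$rss)
})

test_that("model comparison ranks by AICc with the delta >= 2 convention", {
  dec <- make_tpl_decay(beta = 0.35, Da_perp = 7e-3)
  cmp <- compare_decay_models(dec, c("vi", "vii", "viii"), b_min = 6)
  expect_equal(cmp$best, "vii")
  expect_equal(min(cmp$table$delta_aicc), 0)
  expect_true(all(diff(cmp$table$aicc) >= 0))
})

test_that("too few shells in the fit range raises an informative error", {
  dec <- spherical_mean_decay(c(7, 9, 11), truncated_powerlaw(0.3, 1e-3, 0, c(7, 9, 11)))
  expect_error(fit_decay_model(dec, "i", b_min = 6), "at least 5 shells")
})

test_that("tangent intercept matches its closed form and the scan oracle", {
  # Da_perp = 0 collapses to the dot fraction
  ti0 <- tangent_intercept(1, 0, 0.1, 0.2)
  expect_equal(ti0$gamma, 0.1)
  expect_equal(ti0$epsilon, 0)
  # worked example: |eps_max| = beta sqrt(2 Da / e) at xi0 = sqrt(2 Da)
  ti <- tangent_intercept(1, 0.02, 0, sqrt(2 * 0.02))
  expect_equal(ti$epsilon, -sqrt(2 * 0.02 / exp(1)), tolerance = 1e-6)
  # brute-force scan over xi0 locates the inflection point
  xi <- seq(1e-4, 1, by = 1e-5)
  eps <- tangent_intercept(0.4, 0.005, 0, xi)$epsilon
  expect_equal(xi[which.max(abs(eps))], sqrt(2 * 0.005), tolerance = 1e-3)
  expect_equal(max(abs(eps)), 0.4 * sqrt(2 * 0.005 / exp(1)), tolerance = 1e-6)
  # identity with the stick coefficient: |eps_max| = f sqrt(pi/(2e) Da/Dpar)
  f <- 0.6; Dpar <- 2.4; Da <- 0.003
  expect_equal(stick_beta(f, Dpar) * sqrt(2 * Da / exp(1)),
               f * sqrt(pi / (2 * exp(1)) * Da / Dpar), tolerance = 1e-12)
  expect_error(tangent_intercept(1, 0.02, 0, 0), "xi0 must be > 0")
})
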