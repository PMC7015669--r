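test_that("Rician ML amplitude recovers the noiseless and pure-noise limits", {
  expect_equal(rician_ml_amplitude(rep(3.3, 5), 1e-9), 3.3, tolerance = 1e-6)
  set.seed(42)
  y <- sqrt(rnorm(1000)^2 + rnorm(1000)^2)   # nu = 0, sigma = 1
  expect_lt(rician_ml_amplitude(y, 1), 0.5)
  expect_error(rician_ml_amplitude(c(1, 2), 0), "sigma must be > 0")
})

test_that("Rician ML amplitude is near-efficient at moderate SNR", {
  # nu/sigma = 4, N = 60: the estimate should track nu within a few CRLB SDs
  set.seed(7)
  sigma <- 1; nu <- 4; N <- 60
  # Rician CRLB oracle by numeric Fisher information (per observation)
  dll <- function(y, v) (axonradius:::rician_I1I0(y * v / sigma^2) * y - v) / sigma^2
  ygrid <- seq(1e-3, 12, by = 1e-3)
  # Rician density written with the scaled Bessel to avoid overflow
  dens <- ygrid / sigma^2 * exp(-(ygrid - nu)^2 / (2 * sigma^2)) *
    besselI(ygrid * nu / sigma^2, 0, expon.scaled = TRUE)
  fisher1 <- sum(dll(ygrid, nu)^2 * dens) * 1e-3
  crlb_sd <- 1 / sqrt(N * fisher1)
  est <- replicate(300, {
    y <- sqrt((nu + rnorm(N, 0, sigma))^2 + rnorm(N, 0, sigma)^2)
    rician_ml_amplitude(y, sigma)
  })
  expect_gt(mean(abs(est - nu) <= 3 * crlb_sd), 0.9)
  expect_equal(sd(est), crlb_sd, tolerance = 0.2)
})

test_that("even SH basis is orthonormal under dense uniform sampling", {
  u <- fibonacci_directions(5000)
  B <- sh_basis_even(u, 6)
  G <- crossprod(B) * (4 * pi / nrow(u))
  expect_equal(G, diag(ncol(B)), tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(ncol(B), 28)
})

test_that("spherical mean estimation is exact for isotropic data", {
  u <- fibonacci_directions(60)
  est <- spherical_mean_sh(rep(0.5, 60), u, sigma = 1e-6)
  expect_equal(as.numeric(est), 0.5, tolerance = 1e-6)
})

test_that("spherical mean of a noiseless stick matches the closed form", {
  # lmax = 6 fit of a sharply peaked signal: the magnitude-ML estimate
  # carries a small truncation-induced offset (see vignette); the
  # least-squares limit is accurate to ~3e-4
  u <- fibonacci_directions(60)
  sig <- exp(-10 * u[, 3]^2)
  est <- spherical_mean_sh(sig, u, sigma = 1 / 52)
  expect_lt(abs(as.numeric(est) - stick_powder_mean(1, 1, 10)), 0.01)
})

test_that("spherical mean estimation is rotation invariant", {
  # a band-limited even signal (degree 4) and its rotated copy must give the
  # same spherical mean: this pins down the basis normalization
  u <- fibonacci_directions(60)
  R <- rotation_matrix(c(1, 2, 0.5), 1.1)
  f_even <- function(v) 0.5 + 0.1 * (v %*% c(0, 0, 1))^2 +
    0.05 * (v %*% c(1, 0, 0))^4
  s1 <- spherical_mean_sh(as.numeric(f_even(u)), u, sigma = 1e-5)
  s2 <- spherical_mean_sh(as.numeric(f_even(u %*% R)), u, sigma = 1e-5)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-6)
})

test_that("odd-order contamination does not shift the even-basis mean", {
  # with antipodally paired directions the even basis is exactly blind to
  # odd-order terms
  uh <- fibonacci_directions(45)
  u <- rbind(uh, -uh)
  base <- 0.5 + 0.1 * u[, 3]^2               # band-limited even signal
  odd <- 0.05 * u[, 1]                       # pure l = 1 term
  s1 <- spherical_mean_sh(base, u, sigma = 1e-5)
  s2 <- spherical_mean_sh(base + odd, u, sigma = 1e-5)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-8)
})

test_that("at high SNR the Rician ML estimate equals the least-squares fit", {
  u <- fibonacci_directions(60)
  sig <- 0.5 * exp(-2.5 * u[, 3]^2)          # band-limited, nonneg LS recon
  B <- sh_basis_even(u, 6)
  c_ls <- qr.coef(qr(B), sig)
  est <- spherical_mean_sh(sig, u, sigma = 1e-7)
  expect_equal(as.numeric(est), unname(c_ls[1]) / sqrt(4 * pi),
               tolerance = 1e-10)
})

test_that("too few directions fall back to a lower SH order", {
  u <- fibonacci_directions(20)               # < 28 coefficients of lmax 6
  expect_warning(est <- spherical_mean_sh(rep(0.3, 20), u, sigma = 1e-5),
                 "falling back to lmax = 4")
  expect_equal(as.numeric(est), 0.3, tolerance = 1e-6)
})

test_that("dot fraction is recovered from parallel-direction repeats", {
  set.seed(5)
  sigma <- 1 / 195
  # ex vivo-like voxel: mobile parallel signal fully decayed at b = 100,
  # leaving the immobile fraction
  f_im <- 0.13
  reps <- replicate(200, {
    y <- sqrt((f_im + rnorm(60, 0, sigma))^2 + rnorm(60, 0, sigma)^2)
    as.numeric(estimate_dot_fraction(y, 1, sigma))
  })
  # Monte-Carlo CI covers the truth
  expect_lt(abs(mean(reps) - f_im), 3 * sd(reps) / sqrt(length(reps)) + 1e-3)
  # zero-dot voxel: estimate collapses toward zero
  reps0 <- replicate(50, {
    y <- sqrt(rnorm(60, 0, sigma)^2 + rnorm(60, 0, sigma)^2)
    as.numeric(estimate_dot_fraction(y, 1, sigma))
  })
  expect_lt(max(reps0), 0.01)
  # bound case: signal equal to S0 at vanishing noise
  expect_equal(as.numeric(estimate_dot_fraction(rep(2, 10), 2, 1e-9)), 1)
  expect_error(estimate_dot_fraction(c(0.1), 0, 0.01), "S0 must be > 0")
})

test_that("dot correction subtracts exactly and refuses double application", {
  b <- c(7, 9, 12, 20)
  s_free <- truncated_powerlaw(0.35, 1e-3, 0, b)
  dec <- spherical_mean_decay(b, s_free + 0.1)
  corr <- dot_correct(dec, 0.1)
  expect_equal(corr$S_bar, s_free, tolerance = 1e-12)
  expect_true(corr$dot_corrected)
  expect_equal(corr$f_im_hat, 0.1)
  expect_error(dot_correct(corr, 0.05), "already dot-corrected")
  # identity at zero
  expect_equal(dot_correct(dec, 0)$S_bar, dec$S_bar)
  # negative corrected values are allowed (flagged downstream, not clipped)
  over <- dot_correct(spherical_mean_decay(b, s_free), 0.2)
  expect_true(any(over$S_bar < 0))
})
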