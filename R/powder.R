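## Per-shell spherical means from directional data: Rician maximum-likelihood
## estimation of the even-order spherical-harmonic coefficients, with the
## spherical mean read off the l = 0 coefficient; dot-fraction estimation
## from repeated parallel-direction measurements; dot correction.

## Rician log-likelihood machinery. All evaluations use exponentially scaled
## Bessel functions so large arguments (high SNR) do not overflow.

rician_logI0 <- function(z) {
  # log I0(z), even in z; asymptotic expansion where the scaled Bessel
  # routine loses accuracy (besselI(z, 0, TRUE) underflows near z ~ 1e6)
  z <- abs(z)
  out <- numeric(length(z))
  big <- z > 700
  if (any(!big)) {
    zs <- z[!big]
    out[!big] <- log(besselI(zs, 0, expon.scaled = TRUE)) + zs
  }
  if (any(big)) {
    zb <- z[big]
    out[big] <- zb - 0.5 * log(2 * pi * zb) +
      log1p(1 / (8 * zb) + 9 / (128 * zb^2))
  }
  out
}

rician_I1I0 <- function(z) {
  # I1(z)/I0(z), odd in z
  s <- sign(z)
  z <- abs(z)
  out <- numeric(length(z))
  big <- z > 700
  if (any(!big)) {
    zs <- z[!big]
    out[!big] <- besselI(zs, 1, expon.scaled = TRUE) /
      besselI(zs, 0, expon.scaled = TRUE)
  }
  if (any(big)) {
    zb <- z[big]
    out[big] <- 1 - 1 / (2 * zb) - 1 / (8 * zb^2)
  }
  s * out
}

rician_nll <- function(nu, y, sigma) {
  s2 <- sigma^2
  -sum(log(y / s2) - (y^2 + nu^2) / (2 * s2) + rician_logI0(y * nu / s2))
}

#' Rician maximum-likelihood amplitude
#'
#' Estimates the underlying amplitude `nu` of repeated Rician-distributed
#' magnitude measurements with known noise level, by maximizing the Rician
#' log-likelihood over `nu >= 0`. Initialized at the method-of-moments value
#' `sqrt(max(mean(y^2) - 2 sigma^2, 0))`.
#'
#' @param y Magnitude measurements (`>= 0`, length `>= 1`).
#' @param sigma Noise standard deviation of the underlying complex channels
#'   (`> 0`).
#' @return The ML amplitude estimate (`>= 0`).
#' @export
rician_ml_amplitude <- function(y, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (!length(y)) stop("need at least one measurement")
  mom <- sqrt(max(mean(y^2) - 2 * sigma^2, 0))
  upper <- max(max(y), mom) + 6 * sigma / sqrt(length(y))
  opt <- stats::optimize(rician_nll, c(0, upper), y = y, sigma = sigma,
                         tol = 1e-10 * (upper + 1))
  # the boundary nu = 0 can beat the interior optimum for pure-noise data
  if (rician_nll(0, y, sigma) < opt$objective) 0 else opt$minimum
}

## Real, orthonormal, even-order spherical-harmonic design matrix.
## Associated Legendre functions come from pracma::legendre (MATLAB
## convention, Condon-Shortley phase included); the phase is irrelevant for
## an orthonormal fit and for the l = 0 readout.

#' Real even-order spherical-harmonic basis
#'
#' Design matrix of the real orthonormal spherical harmonics of even degree
#' `l = 0, 2, ..., lmax` evaluated at unit direction vectors. Column order is
#' degree-major, within degree `m = -l..l` (sin terms for `m < 0`, cos for
#' `m > 0`).
#'
#' @param dirs `n x 3` matrix of unit vectors.
#' @param lmax Maximum (even) degree.
#' @return `n x K` matrix, `K = (lmax + 1)(lmax + 2)/2 - lmax(lmax + 1)/2`
#'   restricted to even degrees (28 columns at `lmax = 6`).
#' @export
sh_basis_even <- function(dirs, lmax = 6) {
  if (lmax %% 2 != 0) stop("lmax must be even")
  theta_cos <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  cols <- list()
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, theta_cos)      # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in -l:l) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      base <- N * P[am + 1, ]
      cols[[length(cols) + 1]] <- if (m == 0) base
        else if (m > 0) sqrt(2) * base * cos(m * phi)
        else sqrt(2) * base * sin(am * phi)
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- unlist(lapply(seq(0, lmax, 2), function(l)
    paste0("l", l, "m", -l:l)))
  mat
}

n_even_sh_coef <- function(lmax) (lmax / 2 + 1) * (lmax + 1)

#' Spherical mean of one shell by Rician-ML spherical-harmonic fitting
#'
#' Fits the real even-order spherical-harmonic coefficients (default up to
#' degree 6, 28 coefficients) to the per-direction magnitude signals of one
#' b-shell by maximizing the Rician likelihood with known noise level, and
#' returns the spherical mean `S_bar = c00 / sqrt(4 pi)`.
#'
#' The ML stationarity condition `B' (nu - y I1/I0(y nu / sigma^2)) = 0` is
#' solved by damped fixed-point iteration: each step least-squares-fits the
#' "Gaussianized" pseudo-data `y * I1/I0(y nu / sigma^2)`, starting from the
#' ordinary least-squares solution. At high SNR the Bessel ratio tends to 1,
#' so the estimate coincides with the least-squares fit; at low SNR the
#' ratio shrinks floor-dominated measurements toward zero, which removes the
#' Rician bias of the spherical mean. If the shell has fewer directions than
#' coefficients, `lmax` falls back to the largest feasible even degree with
#' a warning.
#'
#' @param signals Per-direction magnitude values (length `n`).
#' @param directions `n x 3` unit vectors.
#' @param sigma Noise SD of the directional data (`> 0`).
#' @param lmax Maximum even spherical-harmonic degree (default 6).
#' @param max_iter,tol Fixed-point iteration controls.
#' @return The spherical mean estimate, with attributes `coefficients`,
#'   `lmax` and `converged`.
#' @export
spherical_mean_sh <- function(signals, directions, sigma, lmax = 6,
                              max_iter = 150, tol = 1e-9) {
  if (sigma <= 0) stop("sigma must be > 0")
  n <- length(signals)
  if (is.null(dim(directions)) || nrow(directions) != n) {
    stop("directions must be an n x 3 matrix matching signals")
  }
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit-norm")
  while (n_even_sh_coef(lmax) > n && lmax > 0) {
    lmax <- lmax - 2
    warning(sprintf("too few directions; falling back to lmax = %d", lmax))
  }
  B <- sh_basis_even(directions, lmax)
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) stop("rank-deficient spherical-harmonic design")
  cf <- qr.coef(qrB, signals)
  s2 <- sigma^2
  converged <- FALSE
  scale <- max(abs(cf), 1e-12)
  for (i in seq_len(max_iter)) {
    nu <- as.numeric(B %*% cf)
    pseudo <- signals * rician_I1I0(signals * nu / s2)
    cf_new <- qr.coef(qrB, pseudo)
    step <- max(abs(cf_new - cf)) / scale
    cf <- 0.5 * (cf + cf_new)
    if (step < tol) { converged <- TRUE; break }
  }
  structure(cf[1] / sqrt(4 * pi), coefficients = cf, lmax = lmax,
            converged = converged)
}

#' Spherical-mean decay curve
#'
#' Per-voxel (or per-ROI) sequence of (b, S_bar) pairs, normalized to
#' `S_bar(b = 0) = 1`.
#'
#' @param b_values Shell b-values in ms/um^2 (ascending order enforced).
#' @param S_bar Spherical means (same length; normalized to the b = 0
#'   signal).
#' @param sigma Noise level(s) of the underlying directional data (optional).
#' @param dot_corrected Has the dot fraction been subtracted?
#' @param f_im_hat Estimated dot fraction (required when `dot_corrected`).
#' @return An object of class `"axr_decay"`.
#' @export
spherical_mean_decay <- function(b_values, S_bar, sigma = NULL,
                                 dot_corrected = FALSE, f_im_hat = NULL) {
  if (length(b_values) != length(S_bar)) stop("b_values and S_bar lengths differ")
  if (any(S_bar > 1 + 1e-9)) {
    warning("spherical means exceed 1; check normalization")
  }
  if (dot_corrected && is.null(f_im_hat)) {
    stop("dot-corrected decays must carry f_im_hat")
  }
  o <- order(b_values)
  structure(list(b_values = b_values[o], S_bar = S_bar[o], sigma = sigma,
                 dot_corrected = dot_corrected, f_im_hat = f_im_hat),
            class = "axr_decay")
}

#' @export
print.axr_decay <- function(x, ...) {
  cat(sprintf("Spherical-mean decay: %d shells, b in [%g, %g] ms/um^2%s\n",
              length(x$b_values), min(x$b_values), max(x$b_values),
              if (x$dot_corrected)
                sprintf(" (dot-corrected, f_im_hat = %.3f)", x$f_im_hat)
              else ""))
  invisible(x)
}

#' Dot (immobile water) fraction from parallel-direction measurements
#'
#' Estimates the fully restricted water fraction from repeated high-b
#' measurements with diffusion weighting parallel to the mean fiber axis —
#' where the mobile intra-axonal signal is suppressed by the parallel decay —
#' as the Rician-ML amplitude normalized by the non-diffusion-weighted
#' signal. Estimates outside [0, 1] are clipped, with attribute `clipped`.
#'
#' @param y_parallel Repeated magnitude measurements at maximal b, parallel
#'   direction.
#' @param S0 Non-diffusion-weighted signal (`> 0`).
#' @param sigma Noise SD (`> 0`).
#' @return `f_im_hat` in [0, 1], with attribute `clipped`.
#' @export
estimate_dot_fraction <- function(y_parallel, S0, sigma) {
  if (S0 <= 0) stop("S0 must be > 0")
  nu <- rician_ml_amplitude(y_parallel, sigma)
  f <- nu / S0
  clipped <- f < 0 || f > 1
  structure(min(max(f, 0), 1), clipped = clipped)
}

#' Subtract the dot fraction from a decay
#'
#' `S_bar_star(b) = S_bar(b) - f_im_hat` elementwise. Corrected values may go
#' negative at high b; they are kept (and flagged by downstream plausibility
#' checks) rather than clipped. Re-correcting an already corrected decay is
#' an error.
#'
#' @param decay An [spherical_mean_decay()].
#' @param f_im_hat Dot fraction to subtract.
#' @return The corrected decay with `dot_corrected = TRUE`.
#' @export
dot_correct <- function(decay, f_im_hat) {
  stopifnot(inherits(decay, "axr_decay"))
  if (decay$dot_corrected) stop("decay is already dot-corrected")
  decay$S_bar <- decay$S_bar - as.numeric(f_im_hat)
  decay$dot_corrected <- TRUE
  decay$f_im_hat <- as.numeric(f_im_hat)
  decay
}
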