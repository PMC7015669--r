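## Powder-averaged forward models: the stick orientational average, the
## truncated power law for a finite radial diffusivity, the large-b exchange
## expansion, distribution-weighted cylinder ensembles, and the composite
## (intra + extra + dot) voxel signal used by the synthetic phantom.

#' Spherical mean of the stick model
#'
#' Orientational average of `exp(-b Da_par cos^2 theta)` over uniformly
#' distributed sticks, scaled by the axonal signal fraction:
#' `S = f * sqrt(pi / (4 b Da_par)) * erf(sqrt(b Da_par))`, continuous at
#' `b = 0` where it equals `f`. For `b Da_par >> 1` it approaches the power
#' law `beta * b^(-1/2)` with `beta = sqrt(pi/4) * f / sqrt(Da_par)`.
#'
#' @param f Axonal (T2-weighted) signal fraction.
#' @param Da_par Parallel intra-axonal diffusivity in um^2/ms (`> 0`).
#' @param b Diffusion weighting in ms/um^2 (vectorized, `>= 0`).
#' @return Spherical-mean signal (same normalization as `f`).
#' @export
stick_powder_mean <- function(f, Da_par, b) {
  if (Da_par <= 0) stop("Da_par must be > 0")
  if (any(b < 0)) stop("b must be >= 0")
  x <- b * Da_par
  out <- rep(f, length(b))
  pos <- x > 0
  out[pos] <- f * sqrt(pi / (4 * x[pos])) * pracma::erf(sqrt(x[pos]))
  out
}

#' Power-law coefficient of the stick model
#'
#' `beta = sqrt(pi/4) * f / sqrt(Da_par)`, the coefficient of the asymptotic
#' `b^(-1/2)` decay. Units: signal * (ms/um^2)^(1/2).
#'
#' @inheritParams stick_powder_mean
#' @export
stick_beta <- function(f, Da_par) {
  sqrt(pi / 4) * f / sqrt(Da_par)
}

#' Truncated power law
#'
#' High-b spherical-mean decay for sticks of finite radial diffusivity plus a
#' fully restricted immobile ("dot") compartment:
#' `S = beta * exp(-b Da_perp) * b^(-1/2) + f_im`.
#'
#' @param beta Power-law coefficient (signal * sqrt(ms/um^2)).
#' @param Da_perp Radial intra-axonal diffusivity in um^2/ms.
#' @param f_im Immobile (dot) signal fraction, the `b -> Inf` plateau.
#' @param b Diffusion weighting in ms/um^2 (`> 0`, vectorized).
#' @export
truncated_powerlaw <- function(beta, Da_perp, f_im, b) {
  if (any(b <= 0)) stop("b must be > 0")
  beta * exp(-b * Da_perp) * b^(-0.5) + f_im
}

#' Large-b exchange expansion
#'
#' Spherical average of the two-compartment Karger model with exchange rate
#' R > 0 expands at large b as `S = beta * (b^(-1/2) + c * b^(-3/2)) + f_im`
#' with `c` proportional to `R * TE / De_perp`. As a function of
#' `xi = b^(-1/2)` this decay is convex, unlike the concave truncated power
#' law — the shape distinction the model comparison exploits.
#'
#' @param beta Power-law coefficient.
#' @param c Exchange coefficient in ms/um^2 (`>= 0`).
#' @param f_im Immobile signal fraction.
#' @param b Diffusion weighting in ms/um^2 (`> 0`, vectorized).
#' @export
exchange_expansion <- function(beta, c, f_im, b) {
  if (any(b <= 0)) stop("b must be > 0")
  if (c < 0) stop("c must be >= 0")
  beta * (b^(-0.5) + c * b^(-1.5)) + f_im
}

#' Spherical mean of a radius-distributed cylinder ensemble
#'
#' Volume-weighted radial attenuation over a radius distribution,
#' `S_perp = sum h(r_i) r_i^2 Sc_perp(r_i) / sum h(r_i) r_i^2`, with
#' `Sc_perp` from [vangelderen_lnS()] at the gradient amplitude implied by
#' the shell, multiplied by the stick orientational average (factorized
#' radial x axial kernel):
#' `S = f * sqrt(pi/(4 b Da_par)) * erf(sqrt(b Da_par)) * S_perp`.
#'
#' @param h A [radius_distribution()] (at least one positive-radius entry
#'   with weight).
#' @param f,Da_par Axonal fraction and parallel diffusivity.
#' @param D0 Axoplasm diffusivity in um^2/ms.
#' @param protocol An [acquisition_protocol()] supplying the pulse timings.
#' @param b Shell b-value(s) in ms/um^2 (`> 0`).
#' @param M Series terms for [vangelderen_lnS()].
#' @return Spherical-mean signal, one value per `b`.
#' @export
distribution_powder_signal <- function(h, f, Da_par, D0, protocol, b, M = 20) {
  stopifnot(inherits(h, "axr_radius_dist"))
  if (any(b <= 0)) stop("b must be > 0")
  r <- h$bin_centers
  w <- h$counts
  vw <- w * r^2
  if (sum(vw) <= 0) stop("distribution has no positive-radius weight")
  delta <- protocol$delta; Delta <- protocol$Delta
  sperp <- vapply(b, function(bb) {
    g <- gradient_for_b(bb, delta, Delta)
    sc <- vapply(r, function(ri)
      exp(as.numeric(vangelderen_lnS(cylinder_spec(ri, D0), g, delta, Delta, M))),
      numeric(1))
    sum(vw * sc) / sum(vw)
  }, numeric(1))
  stick_powder_mean(f, Da_par, b) * sperp
}

#' Deterministic directions on the sphere
#'
#' Spherical Fibonacci point set, optionally restricted to a hemisphere
#' (antipodally symmetric designs for axially symmetric signals).
#'
#' @param n Number of directions.
#' @param hemisphere If `TRUE` (default), map all points to the upper
#'   hemisphere (z >= 0); antipodal symmetry makes this lossless for
#'   even (antipodally symmetric) signals.
#' @return An `n x 3` matrix of unit vectors.
#' @export
fibonacci_directions <- function(n, hemisphere = TRUE) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(rho * cos(phi), rho * sin(phi), z)
  if (hemisphere) {
    flip <- u[, 3] < 0
    u[flip, ] <- -u[flip, ]
  }
  u
}

#' Watson orientation-distribution quadrature
#'
#' Deterministic quadrature `{n_k, w_k}` of the antipodally symmetric Watson
#' ODF `W(n) ~ exp(kappa (mu . n)^2)`. The ODF is axially symmetric, so a
#' product rule is used: Gauss-Legendre nodes in `cos(theta)` on the upper
#' hemisphere (antipodal symmetry makes the lower hemisphere redundant for
#' even signal kernels) crossed with a uniform azimuthal grid, which is
#' spectrally accurate for the smooth exponential kernels the phantom
#' integrates. Weights carry the Gauss-Legendre weight times the ODF value,
#' normalized to sum to one. `kappa = Inf` returns a single node at the mean
#' axis.
#'
#' @param kappa Watson concentration (`>= 0`; `Inf` for coherent fibers).
#' @param mu Mean axis (length-3, normalized internally).
#' @param n_theta Gauss-Legendre nodes in the polar angle (default 32).
#' @param n_phi Uniform azimuthal nodes (default 24).
#' @return A list with `nodes` (matrix) and `weights` (vector).
#' @export
watson_quadrature <- function(kappa, mu = c(0, 0, 1), n_theta = 32,
                              n_phi = 24) {
  mu <- mu / sqrt(sum(mu^2))
  if (is.infinite(kappa)) {
    return(list(nodes = matrix(mu, 1, 3), weights = 1))
  }
  if (kappa < 0) stop("kappa must be >= 0 (bipolar Watson)")
  gl <- pracma::gaussLegendre(n_theta, 0, 1)      # cos(theta) on [0, 1]
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  ct <- rep(gl$x, each = n_phi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, times = n_theta)
  nodes <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$w, each = n_phi) * exp(kappa * ct^2)
  # rotate the polar axis onto the mean axis
  if (sum((mu - c(0, 0, 1))^2) > 1e-24) {
    v <- c(-mu[2], mu[1], 0)
    s <- sqrt(sum(v^2)); cth <- mu[3]
    if (s < 1e-12) {
      R <- diag(c(1, 1, sign(cth)))
    } else {
      K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                  byrow = TRUE)
      R <- diag(3) + K + K %*% K * (1 - cth) / s^2
    }
    nodes <- nodes %*% t(R)
  }
  list(nodes = nodes, weights = w / sum(w))
}

#' Composite voxel signal for the synthetic phantom
#'
#' Per-direction signal of a three-compartment voxel (intra-axonal sticks or
#' cylinders with radial diffusivity `Da_perp`, Gaussian extra-axonal
#' compartment, immobile dot fraction) under an axially symmetric fiber ODF:
#' \deqn{S(u) = \sum_k w_k [ f e^{-b D_{a\perp}} e^{-b (D_{a\|}-D_{a\perp})(u
#' \cdot n_k)^2} + f_e e^{-b D_{e\perp}} e^{-b (D_{e\|}-D_{e\perp})(u \cdot
#' n_k)^2} ] + f_{im}}
#' Noise is applied downstream by the phantom generator.
#'
#' @param u Unit direction(s): length-3 vector or `n x 3` matrix.
#' @param b Shell b-value in ms/um^2.
#' @param f,Da_par,Da_perp Intra-axonal fraction and diffusivities.
#' @param f_e,De_par,De_perp Extra-axonal fraction and diffusivities.
#' @param f_im Immobile fraction. `f + f_e + f_im` must equal 1.
#' @param odf Quadrature from [watson_quadrature()].
#' @return Signal value(s), one per row of `u`; equals 1 at `b = 0`.
#' @export
composite_voxel_signal <- function(u, b, f, Da_par, Da_perp = 0,
                                   f_e = 0, De_par = 0, De_perp = 0,
                                   f_im = 0, odf = watson_quadrature(Inf)) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 3)
  fr <- c(f, f_e, f_im)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    stop("signal fractions must be >= 0 and sum to 1")
  }
  ct2 <- (u %*% t(odf$nodes))^2              # n_dirs x n_nodes
  intra <- f * exp(-b * Da_perp) * exp(-b * (Da_par - Da_perp) * ct2)
  extra <- f_e * exp(-b * De_perp) * exp(-b * (De_par - De_perp) * ct2)
  as.numeric((intra + extra) %*% odf$weights) + f_im
}
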