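## Radial signal attenuation of water restricted in an impermeable cylinder:
## Gaussian phase approximation (van Gelderen series), its long-pulse Neuman
## limit, and the bidirectional maps between radial diffusivity and radius.

# cache of Bessel-derivative roots, grown on demand
.bessel_cache <- new.env(parent = emptyenv())

#' Roots of the derivative of the Bessel function J1
#'
#' Ascending positive roots `alpha_m` of `d J1(alpha) / d alpha = 0`. These
#' are the eigenvalues of the radial diffusion problem in a cylinder with
#' reflecting walls. Computed by sign-change bracketing on a fine grid and
#' polished with [stats::uniroot()] to ~1e-12 absolute; results are cached.
#'
#' @param M Number of roots (`>= 1`).
#' @return Numeric vector of length `M`, strictly increasing; the first root
#'   is ~1.841184.
#' @export
bessel_prime_roots <- function(M) {
  if (M < 1) stop("M must be >= 1")
  M <- as.integer(M)
  have <- .bessel_cache$roots
  if (!is.null(have) && length(have) >= M) return(have[seq_len(M)])
  j1p <- function(x) 0.5 * (besselJ(x, 0) - besselJ(x, 2))
  # asymptotically alpha_m ~ (m - 1/4) * pi; bracket generously
  upper <- (M + 2) * pi
  xs <- seq(1e-3, upper, by = 0.01)
  fx <- j1p(xs)
  sgn <- which(fx[-1] * fx[-length(fx)] < 0)
  roots <- vapply(sgn, function(i)
    uniroot(j1p, c(xs[i], xs[i + 1]), tol = 1e-14)$root, numeric(1))
  roots <- roots[roots > 1]  # drop the trivial stationary point at 0
  if (length(roots) < M) stop("failed to bracket enough roots")
  .bessel_cache$roots <- roots
  roots[seq_len(M)]
}

#' Cylinder specification
#'
#' @param r Cylinder radius in um (`>= 0`).
#' @param D0 Axoplasm (intrinsic) diffusivity in um^2/ms (`> 0`).
#' @return A list of class `"axr_cylinder"` with the derived correlation time
#'   `t_c = r^2 / D0` in ms.
#' @export
cylinder_spec <- function(r, D0) {
  if (r < 0) stop("radius must be >= 0")
  if (D0 <= 0) stop("D0 must be > 0")
  structure(list(r = r, D0 = D0, t_c = r^2 / D0), class = "axr_cylinder")
}

#' Van Gelderen radial log-attenuation
#'
#' Log signal attenuation perpendicular to an impermeable cylinder under a
#' pulsed-gradient spin echo, in the Gaussian phase approximation:
#' \deqn{\ln S = -\frac{2 g^2 r^4}{D_0} \sum_m
#'   \frac{t_c}{\alpha_m^6(\alpha_m^2-1)}
#'   \left[\frac{2\alpha_m^2\delta}{t_c} - 2 + 2e^{-\alpha_m^2\delta/t_c}
#'   + 2e^{-\alpha_m^2\Delta/t_c} - e^{-\alpha_m^2(\Delta-\delta)/t_c}
#'   - e^{-\alpha_m^2(\Delta+\delta)/t_c}\right]}
#' with `t_c = r^2/D0`. The `r = 0` (stick) and `g = 0` limits return 0
#' exactly.
#'
#' @param spec A [cylinder_spec()].
#' @param g Larmor-frequency gradient in rad * ms^-1 * um^-1 (`>= 0`).
#' @param delta,Delta Pulse duration and separation in ms.
#' @param M Number of series terms (default 20; the residual term is checked
#'   against 1e-9 and a warning is raised on non-convergence, with attribute
#'   `converged` set accordingly).
#' @return `ln S` (dimensionless, `<= 0`), with attribute `converged`.
#' @export
vangelderen_lnS <- function(spec, g, delta, Delta, M = 20) {
  stopifnot(inherits(spec, "axr_cylinder"))
  check_timings(delta, Delta)
  if (g < 0) stop("g must be >= 0")
  if (M < 1) stop("M must be >= 1")
  if (spec$r == 0 || g == 0) {
    return(structure(0, converged = TRUE))
  }
  tc <- spec$t_c
  a2 <- bessel_prime_roots(M)^2
  bracket <- 2 * a2 * delta / tc - 2 +
    2 * exp(-a2 * delta / tc) + 2 * exp(-a2 * Delta / tc) -
    exp(-a2 * (Delta - delta) / tc) - exp(-a2 * (Delta + delta) / tc)
  terms <- tc / (a2^3 * (a2 - 1)) * bracket
  s <- sum(terms)
  converged <- abs(terms[M] / s) <= 1e-9
  if (!converged) {
    warning(sprintf("van Gelderen series not converged at M = %d terms", M))
  }
  structure(-(2 * g^2 * spec$r^4 / spec$D0) * s, converged = converged)
}

#' Neuman long-pulse radial log-attenuation
#'
#' Long-pulse limit (`delta >> t_c = r^2/D0`) of the cylinder attenuation:
#' `ln S = -kappa r^4` with `kappa = (7/48) g^2 delta / D0`. A warning is
#' issued when `delta < 5 t_c`, where the limit is inaccurate.
#'
#' @inheritParams vangelderen_lnS
#' @return `ln S` (dimensionless, `<= 0`).
#' @export
neuman_lnS <- function(spec, g, delta) {
  stopifnot(inherits(spec, "axr_cylinder"))
  if (g < 0) stop("g must be >= 0")
  if (delta <= 0) stop("delta must be > 0")
  if (spec$r > 0 && delta < 5 * spec$t_c) {
    warning("delta < 5 * t_c: Neuman limit may be inaccurate here")
  }
  kappa <- (7 / 48) * g^2 * delta / spec$D0
  -kappa * spec$r^4
}

#' Radial intra-axonal diffusivity implied by a cylinder radius
#'
#' Long-pulse relation `D_a_perp = 7 r^4 / (48 D0 delta (Delta - delta/3))`,
#' obtained by writing the Neuman attenuation as `exp(-b D_a_perp)`. The
#' gradient amplitude cancels, so the result depends only on the timings.
#'
#' @param r Cylinder (effective) radius in um (`>= 0`, vectorized).
#' @param D0 Axoplasm diffusivity in um^2/ms.
#' @param delta,Delta Pulse timings in ms.
#' @return `D_a_perp` in um^2/ms.
#' @seealso [radius_from_daperp()] for the exact inverse.
#' @export
daperp_from_radius <- function(r, D0, delta, Delta) {
  check_timings(delta, Delta)
  if (any(r < 0)) stop("radius must be >= 0")
  7 * r^4 / (48 * D0 * delta * (Delta - delta / 3))
}

#' Effective MR radius from a fitted radial diffusivity
#'
#' Inverts the long-pulse relation:
#' `r_MR = (48/7 * delta (Delta - delta/3) * D0 * D_a_perp)^(1/4)`.
#' Negative `Da_perp` values are biophysically implausible but occur in noisy
#' voxelwise fits; they are propagated as `NA` with the `plausible` attribute
#' set to `FALSE` for that entry, never as an error, so that downstream maps
#' can report the implausible fraction.
#'
#' @param Da_perp Radial intra-axonal diffusivity in um^2/ms (vectorized; may
#'   be negative).
#' @inheritParams daperp_from_radius
#' @return `r_MR` in um with logical attribute `plausible` (same length).
#' @export
radius_from_daperp <- function(Da_perp, D0, delta, Delta) {
  check_timings(delta, Delta)
  plausible <- !is.na(Da_perp) & Da_perp >= 0
  D0 <- rep_len(D0, length(Da_perp))
  r <- rep(NA_real_, length(Da_perp))
  r[plausible] <- (48 / 7 * delta * (Delta - delta / 3) * D0[plausible] *
                     Da_perp[plausible])^0.25
  structure(r, plausible = plausible)
}
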