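## Candidate high-b decay models, nonlinear least-squares fitting with a
## deterministic multi-start grid, AICc ranking, and the tangent-intercept
## diagnostics of the power-law extrapolation.

#' Candidate decay models
#'
#' The eight spherical-mean decay models compared by AICc. All are special
#' cases of `S(b) = f_im + beta * (exp(-b Da_perp) * b^(-alpha) + c * b^(-3/2))`:
#'
#' | id   | form                                      | free parameters      |
#' |------|-------------------------------------------|----------------------|
#' | i    | `f_im + beta b^-alpha`                    | f_im, beta, alpha    |
#' | ii   | `f_im + beta b^-1/2`                      | f_im, beta           |
#' | iii  | `f_im + beta exp(-b Da_perp) b^-1/2`      | f_im, beta, Da_perp  |
#' | iv   | `f_im + beta (b^-1/2 + c b^-3/2)`         | f_im, beta, c        |
#' | v    | `beta b^-alpha`                           | beta, alpha          |
#' | vi   | `beta b^-1/2`                             | beta                 |
#' | vii  | `beta exp(-b Da_perp) b^-1/2`             | beta, Da_perp        |
#' | viii | `beta (b^-1/2 + c b^-3/2)`                | beta, c              |
#'
#' The intercept parameter of models i-iv is fit unconstrained by default and
#' reported as `gamma` when negative; model iii's simultaneous (f_im,
#' Da_perp) estimation is known to be very poorly conditioned and is flagged
#' experimental.
#'
#' @return Character vector of the model ids.
#' @export
decay_model_ids <- function() {
  c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii")
}

.model_pars <- list(
  i    = c("f_im", "beta", "alpha"),
  ii   = c("f_im", "beta"),
  iii  = c("f_im", "beta", "Da_perp"),
  iv   = c("f_im", "beta", "c"),
  v    = c("beta", "alpha"),
  vi   = c("beta"),
  vii  = c("beta", "Da_perp"),
  viii = c("beta", "c")
)

#' Evaluate a decay model
#'
#' @param b b-values in ms/um^2 (`> 0`).
#' @param pars Named list/vector with any of `f_im`, `beta`, `alpha`,
#'   `Da_perp`, `c`; missing entries default to `f_im = 0`, `alpha = 0.5`,
#'   `Da_perp = 0`, `c = 0`.
#' @return Model signal values.
#' @export
decay_model_signal <- function(b, pars) {
  p <- as.list(pars)
  f_im <- p$f_im %||% 0
  alpha <- p$alpha %||% 0.5
  Da <- p$Da_perp %||% 0
  cc <- p$c %||% 0
  f_im + p$beta * (exp(-b * Da) * b^(-alpha) + cc * b^(-1.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Corrected Akaike information criterion
#'
#' Gaussian least-squares convention:
#' `AICc = n log(rss / n) + 2k + 2k(k + 1)/(n - k - 1)`. An `rss` of zero is
#' floored at machine epsilon (attribute `rss_floored`).
#'
#' @param rss Residual sum of squares (`>= 0`).
#' @param n Number of data points.
#' @param k Number of fitted parameters (`n - k - 1 > 0` required).
#' @return The AICc value.
#' @export
aicc <- function(rss, n, k) {
  if (n - k - 1 <= 0) stop("AICc undefined: need n > k + 1")
  floored <- rss < .Machine$double.eps
  if (floored) rss <- .Machine$double.eps
  structure(n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1),
            rss_floored = floored)
}

# deterministic multi-start grid for one model
.start_grid <- function(model_id, b, y) {
  beta0 <- stats::median(y * sqrt(b))
  if (!is.finite(beta0) || beta0 <= 0) beta0 <- max(abs(y * sqrt(b)), 1e-3)
  grids <- list(
    beta = beta0 * c(0.5, 1, 1.5),
    f_im = c(0, max(0, min(y))),
    alpha = c(0.3, 0.5, 0.7),
    Da_perp = c(0, 1e-4, 1e-3, 1e-2),
    c = c(0, 1, 5)
  )
  pars <- .model_pars[[model_id]]
  expand.grid(grids[pars], KEEP.OUT.ATTRS = FALSE)
}

#' Fit one decay model
#'
#' Unweighted nonlinear least squares of one candidate model on the shells
#' with `b >= b_min`, using a deterministic multi-start grid (Levenberg-
#' Marquardt via \pkg{minpack.lm}) to cope with the shallow optimization
#' landscape. The intercept `f_im` is unconstrained by default (negative
#' values are reported as the extrapolated intercept `gamma`); set
#' `constrain_fim = TRUE` for a bounded `f_im >= 0` fit. `Da_perp` is always
#' unconstrained: a negative estimate is biophysically implausible but is
#' carried as a result (`plausible = FALSE`), because the implausible-voxel
#' fraction is itself a quantity of interest.
#'
#' @param decay An [spherical_mean_decay()], or a list with `b_values` and
#'   `S_bar`.
#' @param model_id One of [decay_model_ids()].
#' @param b_min Lower b-value bound of the fit range in ms/um^2 (default 6,
#'   the in vivo convention; use 20 for ex vivo data).
#' @param constrain_fim Bound the intercept at zero?
#' @return An object of class `"axr_fit"`: `model_id`, `params` (named),
#'   `gamma` (the intercept, for models with one), `rss`, `n_points`, `aicc`,
#'   `converged`, `plausible`.
#' @export
fit_decay_model <- function(decay, model_id, b_min = 6, constrain_fim = FALSE) {
  model_id <- match.arg(model_id, decay_model_ids())
  b_all <- decay$b_values
  keep <- b_all >= b_min & b_all > 0
  b <- b_all[keep]
  y <- decay$S_bar[keep]
  pars <- .model_pars[[model_id]]
  k <- length(pars)
  if (length(b) < k + 2) {
    stop(sprintf("model %s needs at least %d shells with b >= %g (have %d)",
                 model_id, k + 2, b_min, length(b)))
  }
  resid_fn <- function(p) y - decay_model_signal(b, as.list(p))
  lower <- rep(-Inf, k)
  names(lower) <- pars
  if (constrain_fim && "f_im" %in% pars) lower["f_im"] <- 0
  starts <- .start_grid(model_id, b, y)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- vapply(pars, function(nm) starts[[nm]][i], numeric(1))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(model_id = model_id, params = NULL, gamma = NA,
                          rss = NA, n_points = length(b), aicc = NA,
                          converged = FALSE, plausible = FALSE),
                     class = "axr_fit"))
  }
  est <- best$fit$par
  converged <- best$fit$info %in% 1:4
  plausible <- if ("Da_perp" %in% pars) est[["Da_perp"]] >= 0 else TRUE
  structure(list(
    model_id = model_id,
    params = est,
    gamma = if ("f_im" %in% pars) est[["f_im"]] else NA_real_,
    rss = best$rss,
    n_points = length(b),
    aicc = as.numeric(aicc(best$rss, length(b), k)),
    converged = converged,
    plausible = plausible,
    b_min = b_min), class = "axr_fit")
}

#' @export
print.axr_fit <- function(x, ...) {
  cat(sprintf("Decay model (%s): rss = %.3e, AICc = %.2f, n = %d%s\n",
              x$model_id, x$rss, x$aicc, x$n_points,
              if (!x$plausible) " [implausible Da_perp < 0]" else ""))
  print(signif(x$params, 6))
  invisible(x)
}

#' Compare decay models by AICc
#'
#' Fits each requested model to the same decay and ranks by AICc. A model is
#' reported "significantly better" than another when its AICc is lower by at
#' least 2 (the conventional evidence threshold).
#'
#' @inheritParams fit_decay_model
#' @param model_ids Models to compare (default all eight).
#' @return An object of class `"axr_comparison"`: `results` (named list of
#'   fits), `table` (data frame with aicc and delta_aicc), `best` (model id),
#'   `best_significant` (is the best lower by >= 2 than all others?).
#' @export
compare_decay_models <- function(decay, model_ids = decay_model_ids(),
                                 b_min = 6, constrain_fim = FALSE) {
  fits <- lapply(model_ids, function(m)
    fit_decay_model(decay, m, b_min = b_min, constrain_fim = constrain_fim))
  names(fits) <- model_ids
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  delta <- a - min(a, na.rm = TRUE)
  tab <- data.frame(model = model_ids, k = lengths(.model_pars[model_ids]),
                    rss = vapply(fits, `[[`, numeric(1), "rss"),
                    aicc = a, delta_aicc = delta,
                    plausible = vapply(fits, `[[`, logical(1), "plausible"),
                    row.names = NULL)
  best <- model_ids[which.min(a)]
  structure(list(results = fits, table = tab[order(tab$aicc), ], best = best,
                 best_significant = sort(delta)[2] >= 2),
            class = "axr_comparison")
}

#' @export
print.axr_comparison <- function(x, ...) {
  cat("Model comparison (AICc):\n")
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("best: %s%s\n", x$best,
              if (x$best_significant) " (delta AICc >= 2 over all others)" else ""))
  invisible(x)
}

#' Tangent intercept of the truncated power law
#'
#' Linearizing the truncated power law `S(xi) = beta xi exp(-Da_perp/xi^2) +
#' f_im` (with `xi = 1/sqrt(b)`) around a finite `xi0` and extrapolating the
#' tangent to `xi -> 0` yields the intercept
#' `gamma = f_im - 2 beta Da_perp exp(-Da_perp/xi0^2) / xi0` and the always
#' non-positive offset `epsilon = gamma - f_im`. `|epsilon|` is maximal at
#' the inflection point `xi0 = sqrt(2 Da_perp)`, where it equals
#' `beta * sqrt(2 Da_perp / e)` — the negative-intercept hallmark of a finite
#' axon radius.
#'
#' @param beta Power-law coefficient.
#' @param Da_perp Radial intra-axonal diffusivity (`>= 0`).
#' @param f_im Immobile fraction.
#' @param xi0 Expansion point in 1/sqrt(b) units (`> 0`, vectorized).
#' @return A list with `gamma` and `epsilon` (vectors matching `xi0`).
#' @export
tangent_intercept <- function(beta, Da_perp, f_im, xi0) {
  if (any(xi0 <= 0)) stop("xi0 must be > 0")
  eps <- -2 * beta * Da_perp * exp(-Da_perp / xi0^2) / xi0
  list(gamma = f_im + eps, epsilon = eps)
}
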