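#' @keywords internal
"_PACKAGE"

## Canonical units throughout the package: time in ms, length in um,
## b in ms/um^2, diffusivities in um^2/ms, gradient amplitude in mT/m,
## Larmor-frequency gradient g in rad * ms^-1 * um^-1.

#' Proton gyromagnetic ratio
#'
#' gamma for 1H in rad * ms^-1 * um^-1 per mT/m, i.e. the factor converting a
#' gradient amplitude in mT/m to the gradient of the Larmor frequency in the
#' package's canonical units. Fixed: the package is single-nucleus (1H) by
#' design.
#' @export
GAMMA_H <- 2.6752219e-4

#' Gradient of the Larmor frequency
#'
#' Converts a gradient amplitude `G` (mT/m) to the gradient of the Larmor
#' frequency `g = GAMMA_H * G` in rad * ms^-1 * um^-1.
#'
#' @param G Gradient amplitude in mT/m (scalar or vector, `>= 0`).
#' @return `g` in rad * ms^-1 * um^-1.
#' @examples
#' larmor_gradient(300)   # ~0.0803
#' @export
larmor_gradient <- function(G) {
  if (any(G < 0)) stop("gradient amplitude G must be >= 0")
  GAMMA_H * G
}

#' Diffusion weighting from pulse parameters
#'
#' Pulsed-gradient spin-echo b-value `b = g^2 delta^2 (Delta - delta/3)`.
#'
#' @param g Larmor-frequency gradient in rad * ms^-1 * um^-1.
#' @param delta Gradient pulse duration in ms (`> 0`).
#' @param Delta Pulse separation in ms (`>= delta`).
#' @return b in ms/um^2.
#' @seealso [gradient_for_b()] for the inverse.
#' @export
b_value <- function(g, delta, Delta) {
  check_timings(delta, Delta)
  g^2 * delta^2 * (Delta - delta / 3)
}

#' Gradient needed for a target b-value
#'
#' Unique positive root of `b = g^2 delta^2 (Delta - delta/3)`.
#'
#' @param b Target diffusion weighting in ms/um^2 (`>= 0`).
#' @inheritParams b_value
#' @return `g` in rad * ms^-1 * um^-1.
#' @export
gradient_for_b <- function(b, delta, Delta) {
  check_timings(delta, Delta)
  if (any(b < 0)) stop("b must be >= 0")
  sqrt(b / (delta^2 * (Delta - delta / 3)))
}

check_timings <- function(delta, Delta) {
  if (any(delta <= 0)) stop("delta must be > 0")
  if (any(Delta < delta)) stop("Delta must be >= delta")
  invisible(TRUE)
}

#' Acquisition shell
#'
#' One b-shell of a multi-shell acquisition.
#'
#' @param b Diffusion weighting in ms/um^2 (`>= 0`).
#' @param n_dirs Number of gradient directions on the shell (`>= 1`).
#' @param G Optional gradient amplitude in mT/m. If supplied it must be
#'   consistent with `b` through the timings of the enclosing protocol.
#' @return A list of class `"axr_shell"`.
#' @export
shell <- function(b, n_dirs = 60L, G = NULL) {
  if (b < 0) stop("shell b must be >= 0")
  if (n_dirs < 1) stop("n_dirs must be >= 1")
  structure(list(b = b, n_dirs = as.integer(n_dirs), G = G),
            class = "axr_shell")
}

#' Acquisition protocol
#'
#' Pulse timings and shell table of a single-diffusion-encoding multi-shell
#' protocol.
#'
#' @param delta Gradient pulse duration in ms.
#' @param Delta Pulse separation in ms (`>= delta`).
#' @param shells List of [shell()] objects, or a numeric vector of b-values
#'   (in which case `n_dirs` is applied to every shell).
#' @param n_dirs Directions per shell when `shells` is numeric.
#' @param TE Echo time in ms (optional; used by the exchange residence-time
#'   conversion).
#' @param snr_b0 Scalar SNR of the b = 0 image (optional; used as the default
#'   noise level downstream when no noise map is supplied).
#' @param name Optional protocol label.
#' @return An object of class `"axr_protocol"` with shells sorted by b.
#' @examples
#' p <- acquisition_protocol(13, 30, c(1, 5, 25), snr_b0 = 52)
#' protocol_bvalues(p)
#' @export
acquisition_protocol <- function(delta, Delta, shells, n_dirs = 60L,
                                 TE = NULL, snr_b0 = NULL, name = NULL) {
  check_timings(delta, Delta)
  if (is.numeric(shells)) {
    shells <- lapply(shells, shell, n_dirs = n_dirs)
  }
  if (!length(shells)) stop("at least one shell is required")
  stopifnot(all(vapply(shells, inherits, logical(1), "axr_shell")))
  bs <- vapply(shells, `[[`, numeric(1), "b")
  shells <- shells[order(bs)]
  for (s in shells) {
    if (!is.null(s$G)) {
      b_chk <- b_value(larmor_gradient(s$G), delta, Delta)
      if (s$b > 0 && abs(b_chk - s$b) / s$b > 1e-6) {
        stop(sprintf("shell b = %g inconsistent with G = %g mT/m (implies b = %g)",
                     s$b, s$G, b_chk))
      }
    }
  }
  structure(list(delta = delta, Delta = Delta, shells = shells,
                 TE = TE, snr_b0 = snr_b0, name = name),
            class = "axr_protocol")
}

#' @export
print.axr_protocol <- function(x, ...) {
  cat(sprintf("Acquisition protocol%s\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else ""))
  cat(sprintf("  delta/Delta = %g/%g ms%s%s\n", x$delta, x$Delta,
              if (!is.null(x$TE)) sprintf(", TE = %g ms", x$TE) else "",
              if (!is.null(x$snr_b0)) sprintf(", SNR(b=0) = %g", x$snr_b0) else ""))
  b <- protocol_bvalues(x)
  cat(sprintf("  %d shells, b = %s ms/um^2\n", length(b),
              paste(signif(b, 4), collapse = ", ")))
  invisible(x)
}

#' Shell b-values of a protocol
#' @param protocol An [acquisition_protocol()].
#' @return Numeric vector of shell b-values, ascending, in ms/um^2.
#' @export
protocol_bvalues <- function(protocol) {
  vapply(protocol$shells, `[[`, numeric(1), "b")
}

#' Directions per shell of a protocol
#' @inheritParams protocol_bvalues
#' @return Integer vector, one entry per shell.
#' @export
protocol_ndirs <- function(protocol) {
  vapply(protocol$shells, `[[`, integer(1), "n_dirs")
}

#' Scanner presets
#'
#' The two acquisition setups the package emulates:
#' \describe{
#'   \item{`"connectom"`}{In vivo human, 300 mT/m gradient system:
#'     delta/Delta = 13/30 ms, 60 directions per shell,
#'     b = 1, 3, 5, 7, 9, 11, 12.1, 13.5, 15, 16.9, 19.1, 21.7, 25 ms/um^2,
#'     TE = 62 ms, SNR(b=0) = 52.}
#'   \item{`"aeon"`}{Ex vivo 16.4 T, 1500 mT/m: delta/Delta = 7.1/20 ms, 60
#'     directions per shell, 18 shells up to b = 100 ms/um^2, TE = 30.4 ms,
#'     SNR(b=0) = 195. The exact 18 shell positions of the original
#'     acquisition are not public; the default is a uniform grid from 2.5 to
#'     100 ms/um^2, overridable via `aeon_bvals`.}
#' }
#'
#' @param name `"connectom"` or `"aeon"`.
#' @param aeon_bvals Optional replacement b-value vector for the aeon preset.
#' @return An [acquisition_protocol()].
#' @export
protocol_preset <- function(name = c("connectom", "aeon"), aeon_bvals = NULL) {
  name <- match.arg(name)
  if (name == "connectom") {
    acquisition_protocol(
      delta = 13, Delta = 30,
      shells = c(1, 3, 5, 7, 9, 11, 12.1, 13.5, 15, 16.9, 19.1, 21.7, 25),
      n_dirs = 60L, TE = 62, snr_b0 = 52, name = "connectom")
  } else {
    b <- if (is.null(aeon_bvals)) seq(2.5, 100, length.out = 18) else aeon_bvals
    acquisition_protocol(delta = 7.1, Delta = 20, shells = b, n_dirs = 60L,
                         TE = 30.4, snr_b0 = 195, name = "aeon")
  }
}

#' Serialize a protocol to YAML
#' @inheritParams protocol_bvalues
#' @param path Optional file path; if `NULL` the YAML string is returned.
#' @return `path` (invisibly) or a YAML string.
#' @export
protocol_to_yaml <- function(protocol, path = NULL) {
  x <- list(delta = protocol$delta, Delta = protocol$Delta,
            TE = protocol$TE, snr_b0 = protocol$snr_b0, name = protocol$name,
            shells = lapply(protocol$shells, function(s)
              list(b = s$b, n_dirs = s$n_dirs, G = s$G)))
  x <- x[!vapply(x, is.null, logical(1))]
  if (is.null(path)) return(yaml::as.yaml(x))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a protocol from YAML
#' @param path File path or YAML string produced by [protocol_to_yaml()].
#' @return An [acquisition_protocol()].
#' @export
protocol_from_yaml <- function(path) {
  x <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  shells <- lapply(x$shells, function(s)
    shell(s$b, n_dirs = if (is.null(s$n_dirs)) 60L else s$n_dirs, G = s$G))
  acquisition_protocol(x$delta, x$Delta, shells,
                       TE = x$TE, snr_b0 = x$snr_b0, name = x$name)
}

#' Read an FSL-style gradient table
#'
#' Reads `bval` (one row of b-values in s/mm^2) and `bvec` (3 x N unit
#' vectors, image frame) text files, converts b to ms/um^2, normalizes the
#' direction vectors, and clusters b-values into shells.
#'
#' @param bval_path,bvec_path Paths to the whitespace-separated text files.
#' @param shell_tolerance Clustering tolerance in s/mm^2 (default 50):
#'   b-values closer than this are assigned to the same shell.
#' @param b0_threshold b-values (s/mm^2) at or below this are treated as b=0.
#' @return A list with `b` (ms/um^2, per volume), `bvecs` (N x 3), `shell`
#'   (integer shell index per volume, 0 for b=0), `shell_b` (mean b per shell,
#'   ms/um^2), and `n_volumes`.
#' @export
read_gradient_table <- function(bval_path, bvec_path, shell_tolerance = 50,
                                b0_threshold = 50) {
  bval <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(read.table(bvec_path))
  if (nrow(bvec) != 3 && ncol(bvec) == 3) bvec <- t(bvec)
  if (nrow(bvec) != 3) stop("bvec file must have 3 rows (FSL convention)")
  if (ncol(bvec) != length(bval)) {
    stop(sprintf("bval has %d entries but bvec has %d columns",
                 length(bval), ncol(bvec)))
  }
  dw <- bval > b0_threshold
  nrm <- sqrt(colSums(bvec^2))
  if (any(dw & abs(nrm - 1) > 1e-3)) {
    bad <- which(dw & abs(nrm - 1) > 1e-3)
    stop(sprintf("%d bvecs deviate from unit norm by more than 1e-3", length(bad)))
  }
  bvec[, dw] <- sweep(bvec[, dw, drop = FALSE], 2, nrm[dw], "/")
  # greedy 1D clustering of the diffusion-weighted b-values
  shell_idx <- integer(length(bval))
  ub <- sort(unique(bval[dw]))
  centers <- numeric(0)
  for (b in ub) {
    if (length(centers) && abs(b - centers[length(centers)]) <= shell_tolerance) {
      next
    }
    centers <- c(centers, b)
  }
  for (i in which(dw)) {
    shell_idx[i] <- which.min(abs(centers - bval[i]))
  }
  shell_b <- vapply(seq_along(centers), function(k)
    mean(bval[dw][shell_idx[dw] == k]), numeric(1)) / 1000
  list(b = bval / 1000, bvecs = t(bvec), shell = shell_idx,
       shell_b = shell_b, n_volumes = length(bval))
}
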