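## Dataset I/O: 4D NIfTI volumes with FSL bval/bvec gradient tables, plus an
## optional mask and noise map. Voxel indices are 0-based only at the NIfTI
## level; within R everything is ordinary 1-based array indexing, and world
## coordinates exist only through the NIfTI affine.

#' Read a diffusion-weighted dataset
#'
#' Loads a 4D NIfTI volume with its FSL-style gradient table (b converted to
#' ms/um^2, directions normalized, shells clustered), and optionally a binary
#' mask and a voxelwise noise map.
#'
#' @param dwi_path Path to the 4D NIfTI.
#' @param bval_path,bvec_path Gradient table paths.
#' @param mask_path Optional 3D mask NIfTI.
#' @param sigma_path Optional 3D noise-SD NIfTI (same units as the data).
#' @param shell_tolerance Shell clustering tolerance in s/mm^2.
#' @return A list with `img` (4D array, input affine preserved in the
#'   `niftiHeader` attribute), `grad` (see [read_gradient_table()]), `mask`
#'   (logical array or `NULL`), `sigma` (array or `NULL`).
#' @export
read_dwi <- function(dwi_path, bval_path, bvec_path, mask_path = NULL,
                     sigma_path = NULL, shell_tolerance = 50) {
  img <- RNifti::readNifti(dwi_path)
  if (length(dim(img)) != 4) stop("expected a 4D diffusion-weighted volume")
  grad <- read_gradient_table(bval_path, bvec_path,
                              shell_tolerance = shell_tolerance)
  if (dim(img)[4] != grad$n_volumes) {
    stop(sprintf("volume count mismatch: image has %d volumes, table has %d",
                 dim(img)[4], grad$n_volumes))
  }
  mask <- if (!is.null(mask_path)) RNifti::readNifti(mask_path) > 0 else NULL
  sigma <- if (!is.null(sigma_path)) RNifti::readNifti(sigma_path) else NULL
  list(img = img, grad = grad, mask = mask, sigma = sigma,
       header = RNifti::niftiHeader(img))
}

#' Per-voxel spherical means for every shell
#'
#' Runs the Rician-ML spherical-harmonic powder averaging over all masked
#' voxels of a dataset and returns normalized decays.
#'
#' @param ds Dataset from [read_dwi()].
#' @param lmax Spherical-harmonic degree.
#' @param sigma Scalar noise SD used where no noise map is present.
#' @return A list with `S_bar` (voxels x shells matrix, normalized), `S0`
#'   (vector), `b` (shell b-values), `voxels` (linear indices of the masked
#'   voxels).
#' @export
powder_average_dataset <- function(ds, lmax = 6, sigma = NULL) {
  dims <- dim(ds$img)[1:3]
  nvox <- prod(dims)
  flat <- matrix(ds$img, nvox, dim(ds$img)[4])
  vox <- if (!is.null(ds$mask)) which(as.logical(ds$mask)) else seq_len(nvox)
  sig_vec <- if (!is.null(ds$sigma)) as.numeric(ds$sigma)
             else rep(sigma %||% 0, nvox)
  b0_idx <- which(ds$grad$shell == 0)
  shells <- sort(unique(ds$grad$shell[ds$grad$shell > 0]))
  out <- matrix(NA_real_, length(vox), length(shells))
  S0 <- numeric(length(vox))
  for (j in seq_along(vox)) {
    v <- vox[j]
    sg <- sig_vec[v]
    S0[j] <- if (sg > 0 && length(b0_idx) > 0)
      rician_ml_amplitude(flat[v, b0_idx], sg) else mean(flat[v, b0_idx])
    out[j, ] <- vapply(shells, function(s) {
      idx <- which(ds$grad$shell == s)
      if (sg > 0) {
        as.numeric(spherical_mean_sh(flat[v, idx],
                                     ds$grad$bvecs[idx, , drop = FALSE],
                                     sg, lmax = lmax))
      } else mean(flat[v, idx])
    }, numeric(1)) / S0[j]
  }
  list(S_bar = out, S0 = S0, b = ds$grad$shell_b[shells], voxels = vox,
       dims = dims)
}

#' Write a 3D map as NIfTI
#'
#' @param map Numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param template Optional NIfTI image or header whose geometry to copy.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path, template = NULL) {
  if (!is.null(template)) {
    RNifti::writeNifti(RNifti::asNifti(map, reference = template), path)
  } else {
    RNifti::writeNifti(map, path)
  }
  invisible(path)
}
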