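test_that("noiseless phantom volumes equal the composite forward signal", {
  p <- acquisition_protocol(13, 30, c(7, 15, 25), n_dirs = 30, snr_b0 = 52)
  tr <- phantom_ground_truth(p, dims = c(3, 2, 1), radius_range = c(1, 2),
                             snr = Inf, n_b0 = 1, dot_nrep = 0, seed = 4)
  dir <- withr::local_tempdir()
  generate_dwi_phantom(tr, dir, force = TRUE)
  ds <- read_dwi(file.path(dir, "dwi.nii.gz"), file.path(dir, "dwi.bval"),
                 file.path(dir, "dwi.bvec"))
  odf <- watson_quadrature(tr$kappa, tr$axis)
  # voxel (1,1,1) carries the first stripe radius
  v <- 1
  idx <- which(ds$grad$shell == 2)             # the b = 15 shell
  expected <- composite_voxel_signal(
    ds$grad$bvecs[idx, ], 15, f = tr$f, Da_par = tr$Da_par,
    Da_perp = tr$Da_perp_true[1, 1, 1], f_e = tr$f_e, De_par = tr$De_par,
    De_perp = tr$De_perp, f_im = tr$f_im, odf = odf)
  flat <- matrix(ds$img, prod(tr$dims), dim(ds$img)[4])
  expect_equal(as.numeric(flat[v, idx]), expected, tolerance = 1e-6)
  # b = 0 volumes are exactly 1 in noiseless mode
  expect_true(all(flat[, ds$grad$shell == 0] == 1))
})

test_that("phantom generation is reproducible from its seed", {
  p <- acquisition_protocol(13, 30, c(7, 25), n_dirs = 20, snr_b0 = 40)
  tr <- phantom_ground_truth(p, dims = c(2, 2, 1), seed = 77, dot_nrep = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dwi_phantom(tr, d1, force = TRUE)
  generate_dwi_phantom(tr, d2, force = TRUE)
  a1 <- RNifti::readNifti(file.path(d1, "dwi.nii.gz"))
  a2 <- RNifti::readNifti(file.path(d2, "dwi.nii.gz"))
  expect_identical(as.numeric(a1), as.numeric(a2))
  # refuses to clobber without force
  expect_error(generate_dwi_phantom(tr, d1), "force = TRUE")
})

test_that("b = 0 volumes carry Rician moments at the requested SNR", {
  p <- acquisition_protocol(13, 30, c(7), n_dirs = 6, snr_b0 = 20)
  tr <- phantom_ground_truth(p, dims = c(12, 12, 4), snr = 20, n_b0 = 2,
                             dot_nrep = 0, seed = 5)
  dir <- withr::local_tempdir()
  generate_dwi_phantom(tr, dir, force = TRUE)
  img <- RNifti::readNifti(file.path(dir, "dwi.nii.gz"))
  b0 <- as.numeric(img[, , , 1:2])
  sigma <- 1 / 20
  # Rician mean oracle sigma sqrt(pi/2) L_{1/2}(-x/2) with x = nu^2/sigma^2,
  # written with scaled Bessels so the exponentials cancel analytically
  x <- 1 / sigma^2
  mean_oracle <- sigma * sqrt(pi / 2) *
    ((1 + x / 2) * besselI(x / 4, 0, TRUE) + x / 2 * besselI(x / 4, 1, TRUE))
  expect_equal(mean(b0), mean_oracle, tolerance = 0.01)
  var_oracle <- 1 + 2 * sigma^2 - mean_oracle^2
  expect_equal(sd(b0), sqrt(var_oracle), tolerance = 0.05)
})

test_that("synthetic radius samples match their population moments", {
  # gamma family against closed-form moments
  h <- generate_radius_sample("gamma", list(shape = 3, scale = 0.2),
                              n = 1e5, seed = 31)
  expect_equal(mean_radius(h), 0.6, tolerance = 0.01)
  reff_pop <- (gamma(3 + 6) / gamma(3) / (gamma(3 + 2) / gamma(3)))^(1 / 4) * 0.2
  expect_equal(effective_radius(h), reff_pop, tolerance = 0.02)
  # GEV family against numeric-integration moments
  hg <- generate_radius_sample("gev", list(mu = 0.5, sigma = 0.15, xi = 0.1),
                               n = 1e5, seed = 32)
  m1 <- gev_moment(1, 0.5, 0.15, 0.1)
  r6 <- gev_moment(6, 0.5, 0.15, 0.1); r2 <- gev_moment(2, 0.5, 0.15, 0.1)
  expect_equal(mean_radius(hg), m1, tolerance = 0.01)
  expect_equal(effective_radius(hg), (r6 / r2)^0.25, tolerance = 0.05)
  # point mass via a degenerate GEV
  hp <- generate_radius_sample("gev", list(mu = 1.2, sigma = 0, xi = 0),
                               n = 50, seed = 33)
  expect_true(all(hp$bin_centers == 1.2))
  # reproducibility
  h2 <- generate_radius_sample("gamma", list(shape = 3, scale = 0.2),
                               n = 100, seed = 31)
  h3 <- generate_radius_sample("gamma", list(shape = 3, scale = 0.2),
                               n = 100, seed = 31)
  expect_identical(h2$bin_centers, h3$bin_centers)
  expect_error(generate_radius_sample("gamma", list(shape = -1, scale = 1),
                                      10, seed = 1), "shape > 0")
})

test_that("dataset round trip preserves volumes and gradient table", {
  p <- acquisition_protocol(13, 30, c(7, 25), n_dirs = 15, snr_b0 = 52)
  tr <- phantom_ground_truth(p, dims = c(2, 2, 2), seed = 6, dot_nrep = 0)
  dir <- withr::local_tempdir()
  generate_dwi_phantom(tr, dir, force = TRUE)
  ds <- read_dwi(file.path(dir, "dwi.nii.gz"), file.path(dir, "dwi.bval"),
                 file.path(dir, "dwi.bvec"),
                 mask_path = file.path(dir, "mask.nii.gz"),
                 sigma_path = file.path(dir, "sigma.nii.gz"))
  expect_equal(dim(ds$img), c(2, 2, 2, 1 + 2 * 15 + 2))
  expect_equal(sort(unique(ds$grad$shell)), 0:2)
  expect_equal(ds$grad$shell_b, c(7, 25), tolerance = 1e-9)
  expect_true(all(ds$mask))
  expect_equal(as.numeric(ds$sigma)[1], 1 / 52, tolerance = 1e-9)
  # ground-truth sidecar is machine-readable and complete
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 6)
  expect_length(truth$r_true, 8)
})

test_that("the full pipeline recovers radii exactly on noiseless intra-axonal data", {
  # pure intra-axonal voxels (f = 1): the only error left is quadrature
  p <- protocol_preset("connectom")
  tr <- phantom_ground_truth(p, dims = c(4, 1, 1), radius_range = c(1.5, 3),
                             f = 1, Da_par = 2.4, snr = Inf, n_b0 = 1,
                             dot_nrep = 0, seed = 8)
  rec <- end_to_end_recovery(tr, dir = withr::local_tempdir(), b_min = 6)
  expect_lt(max(abs(rec$rel_error)), 0.01)
  expect_equal(rec$implausible_fraction, 0)
})

test_that("residual extra-axonal signal gives a small positive radius bias", {
  # with a realistic extra-axonal compartment the b > 6 range is not fully
  # clean, which inflates the fitted radial diffusivity slightly
  p <- protocol_preset("connectom")
  tr <- phantom_ground_truth(p, dims = c(4, 1, 1), radius_range = c(1.5, 3),
                             snr = Inf, n_b0 = 1, dot_nrep = 0, seed = 8)
  rec <- end_to_end_recovery(tr, dir = withr::local_tempdir(), b_min = 6)
  expect_true(all(rec$rel_error > 0))
  expect_lt(max(rec$rel_error), 0.15)
})
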