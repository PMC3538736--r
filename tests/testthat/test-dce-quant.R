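toy_dce <- function(curve_fun, shape = c(3, 3), n_slices = 1, n_t = 40,
                    dt = 0.9, n_baseline = 15) {
  vols <- array(0, dim = c(shape, n_slices, n_t))
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (s in seq_len(n_slices)) vols[i, j, s, ] <- curve_fun(i, j)
  dce_series(vols, dt = dt, n_baseline = n_baseline)
}

test_that("baseline normalisation subtracts the pre-contrast mean exactly", {
  const <- toy_dce(function(i, j) rep(11, 40))
  expect_true(all(normalize_baseline(const)$volumes == 0))

  step <- toy_dce(function(i, j) c(rep(4, 15), rep(4 + 2.5, 25)))
  norm <- normalize_baseline(step)
  expect_true(norm$concentration)
  expect_equal(norm$volumes[1, 1, 1, 16:40], rep(2.5, 25))
  expect_equal(norm$volumes[1, 1, 1, 1:15], rep(0, 15))
  # 15 baselines on a 50-volume series leave 35 contrast-carrying volumes
  expect_equal(50L - step$n_baseline, 35L)

  expect_error(dce_series(array(1, c(2, 2, 1, 10)), n_baseline = 10),
               "smaller than the number of volumes")
})

test_that("first-pass truncation keeps exactly the requested prefix", {
  long <- toy_dce(function(i, j) seq_len(80), n_t = 80)
  expect_equal(dim(truncate_first_pass(long, 50)$volumes)[4], 50L)
  expect_equal(dim(truncate_first_pass(long, 60)$volumes)[4], 60L)
  expect_identical(truncate_first_pass(long, 80)$volumes, long$volumes)
  expect_equal(truncate_first_pass(long, 50)$volumes[1, 1, 1, ], 1:50 + 0)
  expect_error(truncate_first_pass(long, 16), "no post-baseline dynamics")
  expect_error(truncate_first_pass(long, 81), "exceeds")
})

test_that("AIF extraction averages the aortic voxels", {
  times <- (0:39) * 0.9
  bolus <- gamma_variate_aif(aif_model(t0 = 13.5), times)$conc
  s <- toy_dce(function(i, j) if (i == 1 && j == 1) bolus else rep(0, 40))
  mask1 <- matrix(FALSE, 3, 3); mask1[1, 1] <- TRUE
  a <- extract_aif(s, mask1)
  expect_equal(a$conc, bolus)
  expect_equal(a$times[which.max(a$conc)], 13.5 + 3 * 2, tolerance = 0.45)  # dt/2

  s2 <- toy_dce(function(i, j) bolus)
  expect_equal(extract_aif(s2, matrix(TRUE, 3, 3))$conc, bolus)

  expect_error(extract_aif(s, matrix(FALSE, 3, 3)), "empty")
  expect_error(extract_aif(toy_dce(function(i, j) rep(0, 40)),
                           matrix(TRUE, 3, 3)), "peak")
})

test_that("deconvolution solves the triangular system exactly when unregularised", {
  dt <- 0.9
  times <- (0:39) * dt
  ca <- gamma_variate_aif(aif_model(t0 = 0.9), times)$conc
  # tissue = AIF shifted by one sample <=> h is an impulse of height 1/dt at lag 1
  ct <- c(0, ca[-40])
  ir <- deconvolve(ct, ca, dt = dt, threshold_fraction = 0)
  expect_equal(which.max(ir$h), 2L)            # lag 1 (0-based) = index 2
  expect_equal(max(ir$h), 1 / dt, tolerance = 1e-8)
  expect_lt(max(abs(ir$h[-2])), 1e-8)

  zero <- deconvolve(rep(0, 40), ca, dt = dt, threshold_fraction = 0)
  expect_true(all(abs(zero$h) < 1e-12))

  expect_error(deconvolve(ct[-1], ca, dt = dt), "length")
  expect_error(deconvolve(ct, rep(0, 40), dt = dt), "peak")
})

test_that("noise-free pixel recovery and forward re-convolution are faithful", {
  dt <- 0.9
  times <- (0:49) * dt
  ca <- gamma_variate_aif(aif_model(t0 = 13.5), times)$conc
  r <- residue_values(residue_model("exponential", tc = 3), times)
  f <- 350
  ct <- (f / 6000) * conv_oracle(ca, r, dt)
  ir <- deconvolve(ct, ca, dt = dt, threshold_fraction = 1e-12)
  expect_equal(ir$rbf, f, tolerance = 0.05)

  # re-convolving the recovered response reproduces the tissue curve
  reconv <- vapply(seq_along(ca), function(i) dt * sum(ca[1:i] * ir$h[i:1]),
                   numeric(1))
  expect_lt(sqrt(sum((reconv - ct)^2) / sum(ct^2)), 1e-6)
})

test_that("deconvolution is invariant to common delay and global scaling", {
  dt <- 0.9
  times <- (0:49) * dt
  ca <- gamma_variate_aif(aif_model(t0 = 4.5), times)$conc
  r <- residue_values(residue_model(), times)
  ct <- (300 / 6000) * conv_oracle(ca, r, dt)
  base <- deconvolve(ct, ca, dt = dt, threshold_fraction = 1e-12)$rbf
  shift <- function(x, k) c(rep(0, k), x[seq_len(length(x) - k)])
  shifted <- deconvolve(shift(ct, 4), shift(ca, 4), dt = dt,
                        threshold_fraction = 1e-12)$rbf
  expect_lt(abs(shifted - base) / base, 0.01)

  scaled <- deconvolve(5.5 * ct, 5.5 * ca, dt = dt,
                       threshold_fraction = 1e-12)$rbf
  expect_equal(scaled, base, tolerance = 1e-9)
})

test_that("stronger truncation never increases estimator variance", {
  set.seed(202)
  dt <- 0.9
  times <- (0:49) * dt
  ca <- gamma_variate_aif(aif_model(t0 = 13.5), times)$conc
  r <- residue_values(residue_model(), times)
  ct0 <- (400 / 6000) * conv_oracle(ca, r, dt)
  vars <- vapply(c(0.01, 0.05, 0.1, 0.15, 0.3), function(th) {
    est <- replicate(40, deconvolve(ct0 + rnorm(50, sd = 0.002), ca,
                                    dt = dt, threshold_fraction = th)$rbf)
    var(est)
  }, numeric(1))
  expect_true(all(diff(vars) <= 0))
})

test_that("pixelwise RBF mapping scales and masks correctly", {
  truth <- make_phantom(small_spec(noise_sigma = 0))
  conc <- truncate_first_pass(normalize_baseline(simulate_dce(truth)), 50)
  aifc <- extract_aif(conc, truth$aorta)
  cortex <- truth$cortex_left | truth$cortex_right

  maps <- rbf_map(conc, aifc, cortex, threshold_fraction = 1e-12)
  expect_length(maps, 3L)
  expect_identical(maps[[1]]$provenance, "DCE")
  expect_equal(roi_mean(maps[[1]], truth$cortex_right), 416, tolerance = 1e-6)

  # all-zero tissue gives a zero map
  zero_truth <- make_phantom(small_spec(f_cortex_left = 0, f_cortex_right = 0,
                                        f_medulla = 0, noise_sigma = 0))
  conc0 <- truncate_first_pass(normalize_baseline(simulate_dce(zero_truth)), 50)
  aif0 <- extract_aif(conc0, zero_truth$aorta)
  m0 <- rbf_map(conc0, aif0, cortex, threshold_fraction = 1e-12)
  expect_lt(max(abs(m0[[1]]$values[m0[[1]]$mask])), 1e-9)

  # doubling the AIF amplitude halves every perfusion value
  aif2 <- aif(aifc$times, 2 * aifc$conc)
  maps2 <- rbf_map(conc, aif2, cortex, threshold_fraction = 1e-12)
  expect_equal(maps2[[1]]$values[maps2[[1]]$mask],
               maps[[1]]$values[maps[[1]]$mask] / 2, tolerance = 1e-9)

  # raw (non-normalised) input is refused
  raw <- truncate_first_pass(simulate_dce(truth), 50)
  expect_error(rbf_map(raw, aifc, cortex), "normalis")
})

test_that("multislice ROI mean averages per-slice means", {
  vals <- matrix(1, 2, 2); mask <- matrix(TRUE, 2, 2)
  maps <- lapply(c(300, 400, 500), function(v)
    perfusion_map(vals * v, mask, "DCE"))
  expect_equal(multislice_roi_mean(maps, mask), 400)
  expect_equal(multislice_roi_mean(list(maps[[2]], maps[[2]], maps[[2]]), mask),
               roi_mean(maps[[2]], mask))
  # a slice with empty mask is skipped with a warning; all empty errors
  empty <- perfusion_map(matrix(NA_real_, 2, 2), matrix(FALSE, 2, 2), "DCE")
  expect_warning(v <- multislice_roi_mean(list(maps[[1]], empty), mask),
                 "skipped")
  expect_equal(v, 300)
  expect_error(suppressWarnings(multislice_roi_mean(list(empty, empty), mask)),
               "every slice")
})

test_that("ROI-curve estimate agrees with the pixel map on noise-free data", {
  truth <- make_phantom(small_spec(noise_sigma = 0))
  series <- simulate_dce(truth)
  via_map <- {
    dq <- dce_quantify(series, truth$aorta, truth$cortex_left,
                       threshold_fraction = 1e-12)
    multislice_roi_mean(dq$maps, truth$cortex_left)
  }
  via_roi <- dce_roi_rbf(series, truth$cortex_left, truth$aorta,
                         threshold_fraction = 1e-12)
  expect_equal(via_roi, via_map, tolerance = 1e-9)
  expect_equal(via_roi, 316, tolerance = 1e-6)
})
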