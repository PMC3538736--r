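test_that("ASL series structure matches the acquisition protocol", {
  truth <- make_phantom(small_spec(noise_sigma = 0))
  series <- simulate_asl(truth, n_pairs = 30)
  expect_equal(dim(series$frames)[3], 90L)
  expect_equal(sum(series$labels == "M0"), 30L)
  expect_equal(sum(series$labels == "ssIR"), 30L)
  expect_equal(sum(series$labels == "nsIR"), 30L)
  expect_equal(series$ti, 1.2)
})

test_that("noise-free tag/control difference matches the closed-form signal", {
  # hand oracle: dM/M0 = 2 (f/6000) TI / lambda * exp(-TI/T1)
  f <- 400
  dm_m0 <- 2 * (f / 6000) * 1.2 / 0.8 * exp(-1.2 / 1.14)
  expect_equal(dm_m0, 0.0698, tolerance = 1e-3)
  expect_equal(fair_forward_delta_m(f, 1), dm_m0)

  truth <- make_phantom(small_spec(f_cortex_right = 400, m0_tissue = 1,
                                   noise_sigma = 0))
  means <- average_by_preparation(simulate_asl(truth))
  dm <- delta_m(means$ssir, means$nsir)
  px <- which(truth$cortex_right)[1]
  expect_equal(dm[px] / means$m0[px], 0.0698, tolerance = 1e-3)
})

test_that("noise-free simulation round-trips through quantification", {
  truth <- make_phantom(small_spec(noise_sigma = 0))
  map <- asl_quantify(simulate_asl(truth))
  expect_lt(max_rel_err(map$values[map$mask], truth$perfusion_map[map$mask]),
            1e-9)
})

test_that("identical spec and seed give bit-identical series", {
  truth <- make_phantom(small_spec(noise_sigma = 1.5, seed = 42L))
  a <- simulate_asl(truth, seed = 42L)
  b <- simulate_asl(truth, seed = 42L)
  expect_identical(a$frames, b$frames)
  c_ <- simulate_asl(truth, seed = 43L)
  expect_false(identical(a$frames, c_$frames))

  d1 <- simulate_dce(truth, noise_sigma = 1, seed = 7L)
  d2 <- simulate_dce(truth, noise_sigma = 1, seed = 7L)
  expect_identical(d1$volumes, d2$volumes)
})

test_that("ROI-mean noise shrinks roughly as 1/sqrt(n_pairs)", {
  truth <- make_phantom(small_spec(noise_sigma = 2))
  sds <- vapply(c(5L, 20L, 80L), function(np) {
    est <- vapply(1:50, function(s) {
      m <- asl_quantify(simulate_asl(truth, n_pairs = np, seed = 1000L * np + s))
      roi_mean(m, truth$cortex_right)
    }, numeric(1))
    sd(est)
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
  # 4x more pairs -> sd halves; 16x -> quarter (Monte-Carlo slack)
  expect_equal(sds[1] / sds[2], 2, tolerance = 0.45)
  expect_equal(sds[1] / sds[3], 4, tolerance = 0.45)
})

test_that("gamma-variate AIF obeys causality, peak location and integral", {
  mod <- aif_model(t0 = 10, alpha = 3, beta = 2, amplitude = 1.7)
  early <- gamma_variate_aif(mod, seq(0, 9.5, by = 0.5))
  expect_true(all(early$conc == 0))

  tt <- seq(0, 80, by = 0.001)
  curve <- gamma_variate_aif(mod, tt)
  expect_equal(tt[which.max(curve$conc)], 10 + 3 * 2, tolerance = 1e-2)
  # closed form integral of amplitude * ((t-t0)/beta)^alpha exp(-(t-t0)/beta)
  # is amplitude * beta * gamma(alpha + 1); trapezoid quadrature as oracle
  trap <- sum(diff(tt) * (head(curve$conc, -1) + tail(curve$conc, -1)) / 2)
  expect_equal(trap, 1.7 * 2 * gamma(3 + 1), tolerance = 1e-4)

  expect_error(gamma_variate_aif(mod, c(1, 1, 2)), "ascending")
})

test_that("DCE forward model is causal, linear in f and baseline-anchored", {
  truth <- make_phantom(small_spec(noise_sigma = 0))
  series <- simulate_dce(truth, dt = 0.9, n_baseline = 15, n_volumes = 50)
  expect_equal(dim(series$volumes), c(48L, 48L, 3L, 50L))

  # bolus arrival coincides with the first volume after the 15 baselines
  times <- (seq_len(50) - 1) * 0.9
  expect_equal(which(times >= 15 * 0.9)[1], 16L)
  aorta_px <- which(truth$aorta)[1]
  ij <- arrayInd(aorta_px, dim(truth$perfusion_map))
  aorta_curve <- series$volumes[ij[1], ij[2], 1, ]
  expect_equal(aorta_curve[1:16], rep(100, 16))  # zero concentration up to t0
  expect_gt(max(aorta_curve[17:50]), 100)

  # an f = 0 pixel stays at baseline
  bg <- which(truth$medulla_left)[1]
  truth0 <- make_phantom(small_spec(f_medulla = 0, noise_sigma = 0))
  s0 <- simulate_dce(truth0)
  ij0 <- arrayInd(bg, dim(truth0$perfusion_map))
  expect_equal(s0$volumes[ij0[1], ij0[2], 1, ], rep(100, 50))

  # doubling f doubles the post-baseline excess everywhere
  t1 <- make_phantom(small_spec(f_cortex_left = 200, f_cortex_right = 300,
                                f_medulla = 100, noise_sigma = 0))
  t2 <- make_phantom(small_spec(f_cortex_left = 400, f_cortex_right = 600,
                                f_medulla = 200, noise_sigma = 0))
  e1 <- normalize_baseline(simulate_dce(t1))
  e2 <- normalize_baseline(simulate_dce(t2))
  tissue <- !t1$aorta
  sel <- array(tissue, dim = dim(e1$volumes)[1:3])
  for (tix in c(20, 30, 49)) {
    v1 <- e1$volumes[, , , tix][sel]
    v2 <- e2$volumes[, , , tix][sel]
    # linear to machine precision relative to the peak enhancement (~0.2)
    expect_lt(max(abs(v2 - 2 * v1)), 1e-10)
  }
})
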