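#' Forward-simulate a FAIR ASL series from a phantom
#'
#' Emits `3 * n_pairs` interleaved frames (M0, ssIR, nsIR repeating) whose
#' tag/control difference is, noise aside, exactly the signal the
#' single-compartment FAIR model predicts at the phantom's ground-truth
#' perfusion ([fair_forward_delta_m()]). The simulator is the algebraic
#' inverse of [quantify_fair()], so the noise-free quantification round-trip
#' is exact to floating precision. Equilibrium signal is `m0_tissue` on
#' kidney and aorta pixels and zero on background (air); both inversion
#' preparations share the inversion-recovery level
#' `|1 - 2 exp(-TI/T1)| * M0`, which cancels in the subtraction. Frame noise
#' is additive zero-mean Gaussian with sd `spec$noise_sigma`, seeded from
#' `seed` (default `spec$seed`).
#'
#' @param truth a [make_phantom()] result.
#' @param spec the phantom spec (defaults to the one stored in `truth`).
#' @param ti inflow time, s.
#' @param n_pairs number of tag-control pairs; the series also carries
#'   `n_pairs` M0 frames, so the default 30 gives 90 frames.
#' @param lambda_bt blood-tissue partition coefficient, ml/g.
#' @param seed RNG seed for frame noise.
#' @return an [asl_series()].
#' @export
simulate_asl <- function(truth, spec = truth$spec, ti = 1.2, n_pairs = 30,
                         lambda_bt = 0.8, seed = spec$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  stopifnot_scalar_pos(ti, "ti")
  if (n_pairs < 1) stop("`n_pairs` must be >= 1", call. = FALSE)
  gs <- spec$grid_shape
  consts <- quant_constants(lambda_bt = lambda_bt, t1 = spec$t1_tissue)

  body <- truth$cortex_left | truth$cortex_right |
    truth$medulla_left | truth$medulla_right | truth$aorta
  m0 <- matrix(0, gs[1], gs[2])
  m0[body] <- spec$m0_tissue
  dm <- fair_forward_delta_m(truth$perfusion_map, m0, consts, ti)

  ir_base <- abs(1 - 2 * exp(-ti / consts$t1)) * m0
  n_frames <- 3L * as.integer(n_pairs)
  labels <- rep(c("M0", "ssIR", "nsIR"), n_pairs)
  frames <- array(0, dim = c(gs[1], gs[2], n_frames))
  for (i in seq_len(n_frames)) {
    frames[, , i] <- switch(labels[i],
      M0 = m0,
      ssIR = ir_base + dm,
      nsIR = ir_base)
  }
  if (spec$noise_sigma > 0) {
    frames <- frames + with_seed(seed,
      array(stats::rnorm(length(frames), sd = spec$noise_sigma), dim = dim(frames)))
  }
  asl_series(frames, labels, ti = ti)
}
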