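#' Tissue residue function model
#'
#' The residue function `R(t)` is the fraction of an ideal arterial tracer
#' impulse still present in the tissue at time `t`; `R(0) = 1` and `R` is
#' non-increasing. Two standard forms are provided: single-compartment
#' exponential washout `exp(-t/tc)` and a plug-flow boxcar `1{t < tc}`.
#'
#' @param form `"exponential"` or `"boxcar"`.
#' @param tc mean transit time, s.
#' @return object of class `residue_model`.
#' @export
residue_model <- function(form = c("exponential", "boxcar"), tc = 3) {
  form <- match.arg(form)
  stopifnot_scalar_pos(tc, "tc")
  structure(list(form = form, tc = tc), class = "residue_model")
}

#' Evaluate a residue model on a time grid (t >= 0)
#' @param model a [residue_model()].
#' @param times non-negative times, s.
#' @return numeric vector, `R(times)`.
#' @export
residue_values <- function(model, times) {
  stopifnot(inherits(model, "residue_model"))
  switch(model$form,
         exponential = exp(-times / model$tc),
         boxcar = as.numeric(times < model$tc))
}

#' Dynamic contrast-enhanced series container
#'
#' @param volumes 4-d array (rows, cols, slices, time), arbitrary signal
#'   units (or concentration units after [normalize_baseline()]).
#' @param dt volume spacing, s.
#' @param n_baseline number of pre-contrast baseline volumes.
#' @param concentration logical; `TRUE` once baseline-normalised.
#' @return object of class `dce_series`.
#' @export
dce_series <- function(volumes, dt = 0.9, n_baseline = 15, concentration = FALSE) {
  if (length(dim(volumes)) != 4L)
    stop("`volumes` must be a 4-d array (rows, cols, slices, time)", call. = FALSE)
  stopifnot_scalar_pos(dt, "dt")
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 1L) stop("`n_baseline` must be >= 1", call. = FALSE)
  if (n_baseline >= dim(volumes)[4])
    stop("`n_baseline` must be smaller than the number of volumes", call. = FALSE)
  structure(list(volumes = volumes, dt = dt, n_baseline = n_baseline,
                 concentration = isTRUE(concentration)),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<dce_series> %dx%dx%d, %d volumes @ dt = %g s (%d baseline)%s\n",
              d[1], d[2], d[3], d[4], x$dt, x$n_baseline,
              if (x$concentration) ", concentration-scaled" else ""))
  invisible(x)
}

#' Discrete tracer-kinetic forward convolution (rectangle rule)
#'
#' `(ca %conv% r)[i] = dt * sum_j ca[j] * r[i - j + 1]`, the same discrete
#' linear system the deconvolution stage solves, so noise-free recovery is
#' exact up to regularisation.
#' @keywords internal
#' @noRd
rect_convolve <- function(ca, r, dt) {
  n <- length(ca)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- dt * sum(ca[seq_len(i)] * r[i:1])
  out
}

#' Forward-simulate a dynamic contrast-enhanced series from a phantom
#'
#' Per tissue pixel the signal is
#' `baseline + (f / 6000) * (C_A (*) R)(t)` with the convolution discretised
#' by the rectangle rule at step `dt`; aorta pixels carry
#' `baseline + C_A(t)` directly (signal-to-concentration proportionality 1,
#' identical for blood and tissue, so it cancels in quantification).
#' Volume `n_baseline + 1` is the first that can carry contrast: the AIF
#' `t0` defaults to `n_baseline * dt` via [aif_model()]. The 2-d phantom is
#' replicated over `n_slices` slices; additive Gaussian noise is seeded.
#'
#' @param truth a [make_phantom()] result.
#' @param aif_mod an [aif_model()]; default arrives at `n_baseline * dt`.
#' @param residue a [residue_model()].
#' @param dt volume spacing, s.
#' @param n_baseline pre-contrast volumes.
#' @param n_volumes total volumes (> `n_baseline`).
#' @param n_slices slices the phantom is replicated over.
#' @param noise_sigma additive Gaussian noise sd (default from the spec).
#' @param seed RNG seed (default from the spec).
#' @return a [dce_series()].
#' @export
simulate_dce <- function(truth, aif_mod = NULL, residue = residue_model(),
                         dt = 0.9, n_baseline = 15, n_volumes = 50,
                         n_slices = 3,
                         noise_sigma = truth$spec$noise_sigma,
                         seed = truth$spec$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  n_baseline <- as.integer(n_baseline); n_volumes <- as.integer(n_volumes)
  if (n_baseline < 1L) stop("`n_baseline` must be >= 1", call. = FALSE)
  if (n_volumes <= n_baseline)
    stop("`n_volumes` must exceed `n_baseline`", call. = FALSE)
  # default bolus arrives with the first post-baseline volume; its peak
  # arterial concentration is set to the baseline tissue signal so that the
  # simulated enhancement-to-noise ratio is realistic (the constant cancels
  # in quantification)
  if (is.null(aif_mod))
    aif_mod <- aif_model(t0 = n_baseline * dt,
                         amplitude = exp(3) / 3^3 * truth$spec$m0_tissue)
  stopifnot(inherits(aif_mod, "aif_model"), inherits(residue, "residue_model"))

  times <- (seq_len(n_volumes) - 1) * dt
  ca <- gamma_variate_aif(aif_mod, times)$conc
  r <- residue_values(residue, times)
  conv <- rect_convolve(ca, r, dt)

  spec <- truth$spec
  gs <- spec$grid_shape
  body <- truth$cortex_left | truth$cortex_right |
    truth$medulla_left | truth$medulla_right | truth$aorta
  baseline <- matrix(0, gs[1], gs[2])
  baseline[body] <- spec$m0_tissue

  vols <- array(0, dim = c(gs[1], gs[2], n_slices, n_volumes))
  fmap <- truth$perfusion_map
  for (tix in seq_len(n_volumes)) {
    frame <- baseline + (fmap / 6000) * conv[tix]
    frame[truth$aorta] <- spec$m0_tissue + ca[tix]
    for (s in seq_len(n_slices)) vols[, , s, tix] <- frame
  }
  if (noise_sigma > 0) {
    vols <- vols + with_seed(seed,
      array(stats::rnorm(length(vols), sd = noise_sigma), dim = dim(vols)))
  }
  dce_series(vols, dt = dt, n_baseline = n_baseline)
}
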