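#' Baseline-normalise a DCE series to relative concentration
#'
#' Subtracts, per voxel, the mean of the first `n_baseline` pre-contrast
#' volumes. A linear relationship between contrast-agent concentration and
#' signal intensity is assumed (proportionality constant 1); the constant
#' cancels in the tissue/arterial ratio of the deconvolution as long as it
#' is the same for blood and tissue, so perfusion estimates do not depend
#' on it.
#'
#' @param series a [dce_series()] in raw signal units.
#' @return a [dce_series()] marked as concentration-scaled.
#' @export
normalize_baseline <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  nb <- series$n_baseline
  d <- dim(series$volumes)
  if (nb >= d[4])
    stop("`n_baseline` must be smaller than the number of volumes", call. = FALSE)
  base <- apply(series$volumes[, , , seq_len(nb), drop = FALSE], c(1, 2, 3), mean)
  out <- series$volumes - array(base, dim = d)  # recycles over time
  dce_series(out, dt = series$dt, n_baseline = nb, concentration = TRUE)
}

#' Truncate a DCE series to the first pass of the bolus
#'
#' Keeps the first `n_volumes` volumes (baseline included) and discards the
#' rest, excluding errors caused by tracer clearance and recirculation after
#' the first pass.
#'
#' @param series a [dce_series()].
#' @param n_volumes volumes to retain; must leave at least two post-baseline
#'   volumes of dynamics.
#' @return a [dce_series()].
#' @export
truncate_first_pass <- function(series, n_volumes = 50) {
  stopifnot(inherits(series, "dce_series"))
  n_volumes <- as.integer(n_volumes)
  d <- dim(series$volumes)
  if (n_volumes > d[4])
    stop("`n_volumes` exceeds the series length", call. = FALSE)
  if (n_volumes < series$n_baseline + 2L)
    stop("`n_volumes` leaves no post-baseline dynamics", call. = FALSE)
  dce_series(series$volumes[, , , seq_len(n_volumes), drop = FALSE],
             dt = series$dt, n_baseline = series$n_baseline,
             concentration = series$concentration)
}

#' Extract the arterial input function from an aortic ROI
#'
#' Mean concentration-vs-time curve over all voxels of the mask (applied to
#' every slice).
#'
#' @param series a baseline-normalised [dce_series()].
#' @param aorta_mask logical matrix on the in-plane grid.
#' @return an [aif()].
#' @export
extract_aif <- function(series, aorta_mask) {
  stopifnot(inherits(series, "dce_series"))
  d <- dim(series$volumes)
  if (!identical(dim(aorta_mask), d[1:2]))
    stop("aorta mask shape does not match the series grid", call. = FALSE)
  if (!any(aorta_mask)) stop("aorta mask is empty", call. = FALSE)
  n_t <- d[4]
  conc <- vapply(seq_len(n_t), function(tix) {
    vol <- series$volumes[, , , tix, drop = FALSE]
    mean(apply(vol, 3, function(sl) mean(sl[aorta_mask])))
  }, numeric(1))
  times <- (seq_len(n_t) - 1) * series$dt
  aif(times, conc, source_roi = "aorta")
}

#' Truncated-SVD pseudo-inverse of the AIF convolution matrix
#'
#' Builds the lower-triangular Toeplitz matrix `A[i, j] = dt * ca[i - j + 1]`
#' of the discrete convolution and returns its pseudo-inverse with singular
#' values below `threshold_fraction * max(s)` zeroed.
#' @keywords internal
#' @noRd
deconvolution_operator <- function(ca, dt, threshold_fraction) {
  n <- length(ca)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) A[j:n, j] <- dt * ca[seq_len(n - j + 1)]
  sv <- svd(A)
  # numerically zero singular values are always dropped (pseudo-inverse
  # convention); threshold_fraction = 0 therefore means "unregularised", not
  # "divide by zero"
  tol_abs <- n * .Machine$double.eps * sv$d[1]
  keep <- sv$d >= max(threshold_fraction * sv$d[1], tol_abs)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  list(pinv = sv$v %*% (dinv * t(sv$u)), n_kept = sum(keep), A = A)
}

#' Deconvolve a tissue curve against the arterial input function
#'
#' Solves the discrete tracer-kinetic system `A h = c_T`, where `A` is the
#' lower-triangular Toeplitz matrix of the AIF scaled by `dt`, by truncated
#' SVD: singular values below `threshold_fraction` times the largest are
#' zeroed. The tissue impulse response is `h(t) = f * R(t)` (1/s before unit
#' conversion); renal perfusion is its maximum, `f = 6000 * max(h)` in
#' ml/100 g/min.
#'
#' @param ct tissue concentration curve (numeric vector or
#'   `aif`-style list with `$conc`).
#' @param ca arterial concentration curve, same length and spacing.
#' @param dt sample spacing, s (taken from the curves if they carry times).
#' @param threshold_fraction relative singular-value cutoff; 0 disables
#'   regularisation, 0.15 is the default for noisy data.
#' @return object of class `impulse_response`: `times`, `h` (1/s),
#'   `rbf` (= `6000 * max(h)`, ml/100 g/min) and `regularization_used`.
#' @export
deconvolve <- function(ct, ca, dt = NULL, threshold_fraction = 0.15) {
  get_curve <- function(x) if (is.list(x)) x$conc else as.numeric(x)
  ct_v <- get_curve(ct); ca_v <- get_curve(ca)
  if (length(ct_v) != length(ca_v))
    stop("tissue and arterial curves differ in length", call. = FALSE)
  if (is.null(dt)) {
    tms <- if (is.list(ca)) ca$times else NULL
    if (is.null(tms)) stop("`dt` required when curves carry no times", call. = FALSE)
    dt <- tms[2] - tms[1]
  }
  if (max(ca_v) <= 0) stop("arterial curve has no positive peak", call. = FALSE)
  if (threshold_fraction < 0) stop("`threshold_fraction` must be >= 0", call. = FALSE)
  op <- deconvolution_operator(ca_v, dt, threshold_fraction)
  h <- as.numeric(op$pinv %*% ct_v)
  structure(list(
    times = (seq_along(h) - 1) * dt, h = h, rbf = 6000 * max(h),
    regularization_used = list(method = "truncated SVD",
                               threshold_fraction = threshold_fraction,
                               singular_values_kept = op$n_kept)
  ), class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("<impulse_response> %d samples, max h = %.4g 1/s -> RBF %.1f ml/100 g/min (tSVD cutoff %g, %d sv kept)\n",
              length(x$h), max(x$h), x$rbf,
              x$regularization_used$threshold_fraction,
              x$regularization_used$singular_values_kept))
  invisible(x)
}

#' Pixel-by-pixel renal blood flow map from a DCE series
#'
#' Deconvolves every masked pixel's concentration curve against the AIF and
#' maps `f = 6000 * max(h)`. The truncated-SVD pseudo-inverse is computed
#' once and applied to all pixel curves. Pixels whose curves are not finite
#' are masked out (count reported via a warning).
#'
#' @param series a baseline-normalised, first-pass-truncated [dce_series()].
#' @param aif the arterial input function ([aif()]), same length as the
#'   series.
#' @param mask logical in-plane matrix of pixels to quantify.
#' @param threshold_fraction relative singular-value cutoff (see
#'   [deconvolve()]).
#' @return list of [perfusion_map()] objects, one per slice,
#'   provenance `"DCE"`.
#' @export
rbf_map <- function(series, aif, mask, threshold_fraction = 0.15) {
  stopifnot(inherits(series, "dce_series"), inherits(aif, "aif"))
  if (!series$concentration)
    stop("series must be baseline-normalised first (see normalize_baseline())",
         call. = FALSE)
  d <- dim(series$volumes)
  if (length(aif$conc) != d[4])
    stop("AIF length does not match the series", call. = FALSE)
  if (!identical(dim(mask), d[1:2]))
    stop("mask shape does not match the series grid", call. = FALSE)
  if (!any(mask)) stop("quantification mask is empty", call. = FALSE)

  op <- deconvolution_operator(aif$conc, series$dt, threshold_fraction)
  idx <- which(mask)
  n_bad <- 0L
  maps <- vector("list", d[3])
  for (s in seq_len(d[3])) {
    curves <- matrix(aperm(series$volumes[, , s, , drop = FALSE],
                           c(1, 2, 4, 3)), nrow = d[1] * d[2], ncol = d[4])[idx, , drop = FALSE]
    ok <- apply(is.finite(curves), 1, all)
    n_bad <- n_bad + sum(!ok)
    H <- op$pinv %*% t(curves[ok, , drop = FALSE])
    f <- 6000 * apply(H, 2, max)
    vals <- matrix(NA_real_, d[1], d[2])
    vals[idx[ok]] <- f
    msk <- matrix(FALSE, d[1], d[2]); msk[idx[ok]] <- TRUE
    maps[[s]] <- perfusion_map(vals, msk, "DCE")
  }
  if (n_bad > 0L)
    warning(sprintf("%d pixel curve(s) were non-finite and were masked out", n_bad))
  maps
}

#' ROI mean across the slices of a multislice RBF map
#'
#' Per-slice ROI means averaged over the slices. A slice with an empty
#' ROI/mask intersection is skipped with a warning; all slices empty is an
#' error.
#'
#' @param maps list of [perfusion_map()] objects (one per slice).
#' @param roi logical in-plane matrix.
#' @return scalar mean, ml/100 g/min.
#' @export
multislice_roi_mean <- function(maps, roi) {
  stopifnot(is.list(maps), length(maps) >= 1)
  per_slice <- vapply(seq_along(maps), function(s) {
    m <- maps[[s]]
    if (!any(roi & m$mask)) {
      warning(sprintf("slice %d: ROI does not intersect the mask; skipped", s))
      return(NA_real_)
    }
    roi_mean(m, roi)
  }, numeric(1))
  if (all(is.na(per_slice)))
    stop("ROI empty on every slice", call. = FALSE)
  mean(per_slice, na.rm = TRUE)
}

#' Full DCE quantification chain
#'
#' Baseline normalisation, first-pass truncation, aortic AIF extraction and
#' pixelwise truncated-SVD deconvolution.
#'
#' @param series a raw [dce_series()].
#' @param aorta_mask logical matrix locating the aorta.
#' @param mask logical matrix of tissue pixels to quantify.
#' @param first_pass_volumes volumes retained for the first pass.
#' @param threshold_fraction relative singular-value cutoff.
#' @return list with `maps` (per-slice [perfusion_map()]s) and `aif`.
#' @export
dce_quantify <- function(series, aorta_mask, mask, first_pass_volumes = 50,
                         threshold_fraction = 0.15) {
  conc <- normalize_baseline(series)
  conc <- truncate_first_pass(conc, first_pass_volumes)
  aif <- extract_aif(conc, aorta_mask)
  maps <- rbf_map(conc, aif, mask, threshold_fraction)
  list(maps = maps, aif = aif)
}

#' ROI-averaged concentration curve
#'
#' Mean concentration over the ROI's voxels (all slices) per time point.
#'
#' @param series a [dce_series()].
#' @param roi logical in-plane matrix.
#' @return numeric vector, one value per volume.
#' @export
roi_concentration_curve <- function(series, roi) {
  stopifnot(inherits(series, "dce_series"))
  d <- dim(series$volumes)
  if (!identical(dim(roi), d[1:2]))
    stop("ROI shape does not match the series grid", call. = FALSE)
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  vapply(seq_len(d[4]), function(tix) {
    vol <- series$volumes[, , , tix, drop = FALSE]
    mean(apply(vol, 3, function(sl) mean(sl[roi])))
  }, numeric(1))
}

#' ROI-based DCE perfusion estimate
#'
#' Deconvolves the ROI-averaged tissue concentration curve against the
#' aortic AIF and returns `6000 * max(h)`. Deconvolution is linear, so this
#' equals the ROI mean of the per-pixel impulse responses; taking the
#' maximum after averaging, however, avoids the upward bias that per-pixel
#' maxima of noisy responses incur, which makes this the preferred ROI
#' summary for noisy series (pixelwise [rbf_map()] remains the mapping
#' tool).
#'
#' @param series a raw [dce_series()].
#' @param roi logical matrix of the tissue ROI.
#' @param aorta_mask logical matrix locating the aorta.
#' @param first_pass_volumes volumes retained for the first pass.
#' @param threshold_fraction relative singular-value cutoff; weak by default
#'   since the ROI averaging already suppresses noise.
#' @return scalar RBF, ml/100 g/min.
#' @export
dce_roi_rbf <- function(series, roi, aorta_mask, first_pass_volumes = 50,
                        threshold_fraction = 1e-3) {
  conc <- normalize_baseline(series)
  conc <- truncate_first_pass(conc, first_pass_volumes)
  ct <- roi_concentration_curve(conc, roi)
  aifc <- extract_aif(conc, aorta_mask)
  deconvolve(ct, aifc, dt = series$dt,
             threshold_fraction = threshold_fraction)$rbf
}
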