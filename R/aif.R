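#' Gamma-variate arterial input function model
#'
#' Standard first-pass bolus shape for the arterial contrast concentration:
#' `c(t) = amplitude * ((t - t0)/beta)^alpha * exp(-(t - t0)/beta)` for
#' `t >= t0`, zero before bolus arrival. The curve peaks at
#' `t0 + alpha * beta` with value `amplitude * alpha^alpha * exp(-alpha)`.
#'
#' @param t0 bolus-arrival time, s.
#' @param alpha shape parameter (dimensionless, > 0).
#' @param beta scale parameter, s (> 0).
#' @param amplitude concentration scale, arbitrary units. The default
#'   normalises the peak to 1.
#' @return object of class `aif_model`.
#' @export
aif_model <- function(t0 = 13.5, alpha = 3, beta = 2,
                      amplitude = exp(alpha) / alpha^alpha) {
  stopifnot_scalar_pos(alpha, "alpha")
  stopifnot_scalar_pos(beta, "beta")
  stopifnot_scalar_pos(amplitude, "amplitude")
  if (!is.finite(t0) || t0 < 0) stop("`t0` must be >= 0", call. = FALSE)
  structure(list(t0 = t0, alpha = alpha, beta = beta, amplitude = amplitude),
            class = "aif_model")
}

#' Evaluate a gamma-variate AIF on a time grid
#'
#' @param model an [aif_model()].
#' @param times ascending vector of sample times, s.
#' @return object of class `aif`: list with `times`, `conc` and `source_roi`
#'   (here `"model"`).
#' @export
gamma_variate_aif <- function(model, times) {
  stopifnot(inherits(model, "aif_model"))
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly ascending", call. = FALSE)
  s <- pmax(times - model$t0, 0)
  conc <- model$amplitude * (s / model$beta)^model$alpha * exp(-s / model$beta)
  conc[times < model$t0] <- 0
  aif(times, conc, source_roi = "model", allow_zero = TRUE)
}

#' Arterial input function container
#'
#' @param times sample times, s (uniformly spaced, ascending).
#' @param conc concentration values, arbitrary units.
#' @param source_roi identifier of the ROI the curve came from.
#' @param allow_zero permit an all-zero curve (model evaluation before bolus
#'   arrival); measured AIFs must carry a positive peak.
#' @return object of class `aif`.
#' @export
aif <- function(times, conc, source_roi = "aorta", allow_zero = FALSE) {
  if (length(times) != length(conc))
    stop("`times` and `conc` lengths differ", call. = FALSE)
  if (length(times) > 1) {
    dts <- diff(times)
    if (any(dts <= 0) || diff(range(dts)) > 1e-8 * mean(dts))
      stop("`times` must be uniformly spaced and ascending", call. = FALSE)
  }
  if (!allow_zero && max(conc) <= 0)
    stop("no bolus detected: AIF has no positive peak", call. = FALSE)
  structure(list(times = as.numeric(times), conc = as.numeric(conc),
                 source_roi = source_roi), class = "aif")
}

#' @export
print.aif <- function(x, ...) {
  cat(sprintf("<aif> %d samples from '%s', peak %.3g at t = %.2f s\n",
              length(x$times), x$source_roi, max(x$conc),
              x$times[which.max(x$conc)]))
  invisible(x)
}
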