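#' Constants of the FAIR perfusion model
#'
#' @param lambda_bt blood-tissue water partition coefficient, ml/g.
#' @param t1 longitudinal relaxation time of tissue, s.
#' @param unit_factor 6000 converts ml/g/s to ml/100 g/min (x60 s to min,
#'   x100 per-g to per-100 g); 1 leaves the output in ml/g/s.
#' @return object of class `quant_constants`.
#' @export
quant_constants <- function(lambda_bt = 0.8, t1 = 1.14, unit_factor = 6000) {
  stopifnot_scalar_pos(lambda_bt, "lambda_bt")
  stopifnot_scalar_pos(t1, "t1")
  stopifnot_scalar_pos(unit_factor, "unit_factor")
  structure(list(lambda_bt = lambda_bt, t1 = t1, unit_factor = unit_factor),
            class = "quant_constants")
}

#' Construct a labelled ASL frame series
#'
#' A FAIR series interleaves three magnetic preparations: unprepared
#' equilibrium frames (`M0`), slice-selective inversion (`ssIR`, control)
#' and non-selective global inversion (`nsIR`, tag).
#'
#' @param frames numeric array (rows, cols, n_frames), arbitrary signal units.
#' @param labels character vector, one of `"M0"`, `"ssIR"`, `"nsIR"` per frame.
#' @param ti inflow (inversion) time, s.
#' @param inter_image_time time between consecutive frames, s.
#' @return object of class `asl_series`.
#' @export
asl_series <- function(frames, labels, ti = 1.2, inter_image_time = 6) {
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a 3-d array (rows, cols, n_frames)", call. = FALSE)
  labels <- as.character(labels)
  if (dim(frames)[3] != length(labels))
    stop("one label per frame required", call. = FALSE)
  bad <- setdiff(unique(labels), c("M0", "ssIR", "nsIR"))
  if (length(bad))
    stop("unknown preparation label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  missing <- setdiff(c("M0", "ssIR", "nsIR"), labels)
  if (length(missing))
    stop("series lacks preparation(s): ", paste(missing, collapse = ", "), call. = FALSE)
  stopifnot_scalar_pos(ti, "ti")
  structure(list(frames = frames, labels = labels, ti = ti,
                 inter_image_time = inter_image_time),
            class = "asl_series")
}

#' @export
print.asl_series <- function(x, ...) {
  cat(sprintf("<asl_series> %dx%d, %d frames (%s), TI = %g s\n",
              dim(x$frames)[1], dim(x$frames)[2], dim(x$frames)[3],
              paste(sprintf("%d %s", table(x$labels)[c("M0", "ssIR", "nsIR")],
                            c("M0", "ssIR", "nsIR")), collapse = ", "),
              x$ti))
  invisible(x)
}

#' Average frames by magnetic preparation
#'
#' @param series an [asl_series()].
#' @return list of three matrices: `m0`, `ssir`, `nsir`, each the pixelwise
#'   mean over all frames carrying that label.
#' @export
average_by_preparation <- function(series) {
  stopifnot(inherits(series, "asl_series"))
  avg <- function(lab) {
    idx <- which(series$labels == lab)
    if (!length(idx)) stop("no frames labelled '", lab, "'", call. = FALSE)
    m <- series$frames[, , idx, drop = FALSE]
    apply(m, c(1, 2), mean)
  }
  list(m0 = avg("M0"), ssir = avg("ssIR"), nsir = avg("nsIR"))
}

#' Perfusion-weighted difference image
#'
#' Subtracts the averaged tag (non-selective inversion) image from the
#' averaged control (slice-selective inversion) image; positive in perfused
#' tissue under the FAIR sign convention.
#'
#' @param ssir_mean,nsir_mean matrices of equal shape.
#' @return matrix `ssir_mean - nsir_mean`.
#' @export
delta_m <- function(ssir_mean, nsir_mean) {
  if (!identical(dim(ssir_mean), dim(nsir_mean)))
    stop("shape mismatch between ss-IR and ns-IR means", call. = FALSE)
  ssir_mean - nsir_mean
}

#' Forward FAIR difference signal at a given perfusion
#'
#' The algebraic inverse of [quantify_fair()]: the tag/control difference a
#' single-compartment FAIR experiment produces at perfusion `f`,
#' `dM = 2 * (f / unit_factor) * M0 * TI / lambda * exp(-TI / T1)`.
#' Used by the simulator so that quantification recovers the ground truth
#' exactly in the noise-free case.
#'
#' @param f perfusion, ml/100 g/min (matrix or scalar).
#' @param m0 equilibrium signal (same shape as `f` or scalar).
#' @param consts [quant_constants()].
#' @param ti inflow time, s.
#' @return difference signal dM in the units of `m0`.
#' @export
fair_forward_delta_m <- function(f, m0, consts = quant_constants(), ti = 1.2) {
  stopifnot_scalar_pos(ti, "ti")
  2 * (f / consts$unit_factor) * m0 * ti / consts$lambda_bt * exp(-ti / consts$t1)
}

#' Pixelwise FAIR perfusion quantification
#'
#' Single-compartment pulsed-ASL model with immediate blood-tissue exchange
#' and transit effects neglected:
#' `f = unit_factor * lambda * dM * exp(TI / T1) / (2 * M0 * TI)`.
#' Pixels whose equilibrium signal falls at or below `m0_floor` (background
#' air, where the ratio diverges) are excluded from the validity mask;
#' negative perfusion values on the mask are retained, not clipped.
#'
#' @param delta_m_map difference image from [delta_m()].
#' @param m0_map averaged equilibrium image, same shape.
#' @param consts [quant_constants()].
#' @param ti inflow time, s.
#' @param m0_floor signal threshold for the validity mask; default 5% of the
#'   99th percentile of `m0_map` (robust maximum).
#' @return object of class `perfusion_map`: list with `values` (matrix,
#'   ml/100 g/min, `NA` off-mask), logical `mask`, and `provenance = "ASL"`.
#' @export
quantify_fair <- function(delta_m_map, m0_map, consts = quant_constants(),
                          ti = 1.2, m0_floor = NULL) {
  if (!identical(dim(delta_m_map), dim(m0_map)))
    stop("shape mismatch between dM and M0 maps", call. = FALSE)
  stopifnot_scalar_pos(ti, "ti")
  if (is.null(m0_floor))
    m0_floor <- 0.05 * stats::quantile(m0_map, 0.99, names = FALSE)
  mask <- is.finite(m0_map) & m0_map > m0_floor
  vals <- matrix(NA_real_, nrow(m0_map), ncol(m0_map))
  vals[mask] <- consts$unit_factor * consts$lambda_bt * delta_m_map[mask] *
    exp(ti / consts$t1) / (2 * m0_map[mask] * ti)
  perfusion_map(vals, mask, "ASL")
}

#' Perfusion map container
#'
#' @param values matrix of perfusion values, ml/100 g/min (`NA` off-mask).
#' @param mask logical validity matrix, same shape.
#' @param provenance `"ASL"` or `"DCE"`.
#' @return object of class `perfusion_map`.
#' @export
perfusion_map <- function(values, mask, provenance = c("ASL", "DCE")) {
  provenance <- match.arg(provenance)
  stopifnot(identical(dim(values), dim(mask)))
  if (any(!is.finite(values[mask])))
    stop("perfusion values must be finite on the mask", call. = FALSE)
  structure(list(values = values, mask = mask, provenance = provenance),
            class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<perfusion_map> %s, %dx%d, %d masked px, range %.1f..%.1f ml/100 g/min\n",
              x$provenance, nrow(x$values), ncol(x$values), sum(x$mask),
              min(v), max(v)))
  invisible(x)
}

#' Mean perfusion over a region of interest
#'
#' Arithmetic mean of map values over the intersection of the ROI with the
#' map's validity mask; all masked pixels contribute (no clipping of
#' negative values).
#'
#' @param map a [perfusion_map()].
#' @param roi logical matrix, same shape as the map.
#' @return scalar mean, ml/100 g/min.
#' @export
roi_mean <- function(map, roi) {
  stopifnot(inherits(map, "perfusion_map"))
  if (!identical(dim(roi), dim(map$values)))
    stop("ROI shape does not match map", call. = FALSE)
  sel <- roi & map$mask
  if (!any(sel)) stop("ROI does not intersect the map's validity mask", call. = FALSE)
  mean(map$values[sel])
}

#' Full ASL quantification chain
#'
#' Convenience wrapper: preparation-wise averaging, tag/control subtraction,
#' and pixelwise FAIR quantification.
#'
#' @inheritParams average_by_preparation
#' @inheritParams quantify_fair
#' @return a [perfusion_map()].
#' @export
asl_quantify <- function(series, consts = quant_constants(), m0_floor = NULL) {
  means <- average_by_preparation(series)
  dm <- delta_m(means$ssir, means$nsir)
  quantify_fair(dm, means$m0, consts, ti = series$ti, m0_floor = m0_floor)
}
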