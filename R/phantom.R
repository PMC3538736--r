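#' Specification of a two-kidney digital perfusion phantom
#'
#' Describes a single axial slice through a rat abdomen containing both
#' kidneys: each kidney is an ellipse whose outer ring is renal cortex and
#' whose interior is medulla, plus a small circular aorta cross-section used
#' as the arterial input region in dynamic contrast-enhanced simulations.
#' Ground-truth perfusion is assigned per compartment in ml/100 g/min.
#'
#' @param grid_shape integer pair, image matrix size in pixels (rows, cols).
#' @param pixel_size in-plane pixel size in mm (isotropic).
#' @param kidney_geometries list of two ellipse descriptors (`left`, `right`),
#'   each a list with `centre` (row, col in pixels), `axes` (semi-axes in
#'   pixels) and `cortex_thickness` (ring width in pixels, strictly less than
#'   both semi-axes).
#' @param f_cortex_left,f_cortex_right,f_medulla ground-truth perfusion of
#'   each compartment, ml/100 g/min. A unilateral injury is emulated by
#'   setting one cortical value below the other.
#' @param m0_tissue equilibrium (unprepared) signal level, arbitrary units.
#' @param t1_tissue longitudinal relaxation time of tissue, s.
#' @param noise_sigma standard deviation of additive Gaussian frame noise,
#'   arbitrary units; 0 gives noise-free series.
#' @param aorta_centre,aorta_radius circular aorta ROI (pixels).
#' @param seed integer seed for all randomness in simulations from this spec.
#'
#' @details Defaults emulate the study conditions of a unilateral
#'   ischaemia-reperfusion injury: cortical perfusion 316 ml/100 g/min on the
#'   diseased (left) side versus 416 ml/100 g/min on the healthy (right)
#'   side, on a 128x128 grid.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L),
                         pixel_size = 0.5,
                         kidney_geometries = default_kidney_geometries(grid_shape),
                         f_cortex_left = 316,
                         f_cortex_right = 416,
                         f_medulla = 150,
                         m0_tissue = 100,
                         t1_tissue = 1.14,
                         noise_sigma = 0,
                         aorta_centre = NULL,
                         aorta_radius = 3,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape <= 0L))
    stop("`grid_shape` must be two positive integers", call. = FALSE)
  for (f in c(f_cortex_left, f_cortex_right, f_medulla))
    if (!is.finite(f) || f < 0) stop("perfusion values must be >= 0", call. = FALSE)
  stopifnot_scalar_pos(m0_tissue, "m0_tissue")
  stopifnot_scalar_pos(t1_tissue, "t1_tissue")
  stopifnot_scalar_pos(noise_sigma, "noise_sigma", strict = FALSE)
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  for (side in c("left", "right")) {
    g <- kidney_geometries[[side]]
    if (is.null(g)) stop("`kidney_geometries` needs elements 'left' and 'right'", call. = FALSE)
    if (g$cortex_thickness <= 0 || any(g$axes - g$cortex_thickness <= 0))
      stop("cortex ring must lie strictly inside the kidney ellipse", call. = FALSE)
  }
  if (is.null(aorta_centre))
    aorta_centre <- c(round(grid_shape[1] * 0.30), round(grid_shape[2] / 2))
  structure(list(
    grid_shape = grid_shape, pixel_size = pixel_size,
    kidney_geometries = kidney_geometries,
    f_cortex_left = f_cortex_left, f_cortex_right = f_cortex_right,
    f_medulla = f_medulla, m0_tissue = m0_tissue, t1_tissue = t1_tissue,
    noise_sigma = noise_sigma,
    aorta_centre = aorta_centre, aorta_radius = aorta_radius,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_kidney_geometries <- function(grid_shape = c(128L, 128L)) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  ax <- c(round(nr * 0.20), round(nc * 0.13))
  th <- max(2L, round(min(ax) * 0.35))
  list(
    left  = list(centre = c(round(nr * 0.60), round(nc * 0.28)),
                 axes = ax, cortex_thickness = th),
    right = list(centre = c(round(nr * 0.60), round(nc * 0.72)),
                 axes = ax, cortex_thickness = th)
  )
}

ellipse_mask <- function(grid_shape, centre, axes) {
  r <- matrix(seq_len(grid_shape[1]), grid_shape[1], grid_shape[2])
  c_ <- matrix(seq_len(grid_shape[2]), grid_shape[1], grid_shape[2], byrow = TRUE)
  ((r - centre[1]) / axes[1])^2 + ((c_ - centre[2]) / axes[2])^2 <= 1
}

disc_mask <- function(grid_shape, centre, radius) {
  ellipse_mask(grid_shape, centre, c(radius, radius))
}

#' Rasterise a phantom specification into ground-truth maps
#'
#' Builds the ground-truth perfusion map and the compartment masks (left and
#' right cortex and medulla, aorta) on the phantom grid. Perfusion equals the
#' spec's cortical value on each cortex ring, the medullary value inside, and
#' zero elsewhere (including the aorta, which carries tracer but no tissue
#' perfusion).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `ground_truth`: list with `perfusion_map`
#'   (matrix, ml/100 g/min), logical masks `cortex_left`, `cortex_right`,
#'   `medulla_left`, `medulla_right`, `aorta`, and the originating `spec`.
#'   All masks are pairwise disjoint.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  outer_l <- ellipse_mask(gs, spec$kidney_geometries$left$centre,
                          spec$kidney_geometries$left$axes)
  outer_r <- ellipse_mask(gs, spec$kidney_geometries$right$centre,
                          spec$kidney_geometries$right$axes)
  if (any(outer_l & outer_r))
    stop("kidney ellipses overlap; adjust `kidney_geometries`", call. = FALSE)
  inner_l <- ellipse_mask(gs, spec$kidney_geometries$left$centre,
                          spec$kidney_geometries$left$axes -
                            spec$kidney_geometries$left$cortex_thickness)
  inner_r <- ellipse_mask(gs, spec$kidney_geometries$right$centre,
                          spec$kidney_geometries$right$axes -
                            spec$kidney_geometries$right$cortex_thickness)
  aorta <- disc_mask(gs, spec$aorta_centre, spec$aorta_radius)
  if (any(aorta & (outer_l | outer_r)))
    stop("aorta ROI overlaps a kidney; adjust `aorta_centre`", call. = FALSE)

  cortex_l <- outer_l & !inner_l
  cortex_r <- outer_r & !inner_r
  f <- matrix(0, gs[1], gs[2])
  f[cortex_l] <- spec$f_cortex_left
  f[cortex_r] <- spec$f_cortex_right
  f[inner_l | inner_r] <- spec$f_medulla

  structure(list(
    perfusion_map = f,
    cortex_left = cortex_l, cortex_right = cortex_r,
    medulla_left = inner_l, medulla_right = inner_r,
    aorta = aorta, spec = spec
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  gs <- dim(x$perfusion_map)
  cat(sprintf("<ground_truth> %dx%d phantom\n", gs[1], gs[2]))
  cat(sprintf("  cortex L/R: %g / %g ml/100 g/min (%d / %d px), medulla %g\n",
              x$spec$f_cortex_left, x$spec$f_cortex_right,
              sum(x$cortex_left), sum(x$cortex_right), x$spec$f_medulla))
  invisible(x)
}

#' Encode phantom masks as an integer label map
#'
#' Label codes: 0 background, 1 left cortex, 2 right cortex, 3 left medulla,
#' 4 right medulla, 5 aorta.
#' @param truth a [make_phantom()] result.
#' @return integer matrix of labels.
#' @export
mask_labels <- function(truth) {
  lab <- matrix(0L, nrow(truth$perfusion_map), ncol(truth$perfusion_map))
  lab[truth$cortex_left] <- 1L
  lab[truth$cortex_right] <- 2L
  lab[truth$medulla_left] <- 3L
  lab[truth$medulla_right] <- 4L
  lab[truth$aorta] <- 5L
  lab
}
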