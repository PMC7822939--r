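#' Tissue class specification
#'
#' Describes the generative relaxation parameters of one tissue class:
#' per-voxel T1 and T2* are drawn from normal distributions truncated at the
#' class min/max, and the equilibrium magnetization M0 from an untruncated
#' normal (floored at zero).
#'
#' @param name Class label, one of `"fibrous"`, `"lipid"`, `"inflammation"`,
#'   `"hemorrhage"`, `"background"` (free labels are allowed for custom
#'   phantoms).
#' @param t1_mean,t1_sd,t1_min,t1_max Longitudinal relaxation time T1
#'   parameters (ms).
#' @param t2s_mean,t2s_sd,t2s_min,t2s_max Effective transverse relaxation time
#'   T2* parameters (ms).
#' @param m0_mean,m0_sd Equilibrium magnetization (arbitrary units).
#' @return An object of class `tissue_class_spec`.
#' @export
#' @examples
#' tissue_class_spec("lipid", 994.98, 338.93, 241.03, 2290.56,
#'                   11.38, 5.17, 3.59, 31.00)
tissue_class_spec <- function(name,
                              t1_mean, t1_sd, t1_min, t1_max,
                              t2s_mean, t2s_sd, t2s_min, t2s_max,
                              m0_mean = 1, m0_sd = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", what), call. = FALSE)
    as.numeric(x)
  }
  spec <- list(
    name     = name,
    t1_mean  = num1(t1_mean, "t1_mean"),   t1_sd  = num1(t1_sd, "t1_sd"),
    t1_min   = num1(t1_min, "t1_min"),     t1_max = num1(t1_max, "t1_max"),
    t2s_mean = num1(t2s_mean, "t2s_mean"), t2s_sd = num1(t2s_sd, "t2s_sd"),
    t2s_min  = num1(t2s_min, "t2s_min"),   t2s_max = num1(t2s_max, "t2s_max"),
    m0_mean  = num1(m0_mean, "m0_mean"),   m0_sd  = num1(m0_sd, "m0_sd")
  )
  with(spec, {
    if (!(t1_min <= t1_mean && t1_mean <= t1_max))
      stop("require t1_min <= t1_mean <= t1_max for class '", name, "'",
           call. = FALSE)
    if (!(t2s_min <= t2s_mean && t2s_mean <= t2s_max))
      stop("require t2s_min <= t2s_mean <= t2s_max for class '", name, "'",
           call. = FALSE)
    if (t1_sd < 0 || t2s_sd < 0 || m0_sd < 0)
      stop("standard deviations must be >= 0 for class '", name, "'",
           call. = FALSE)
    if (t1_min <= 0 || t2s_min <= 0)
      stop("relaxation times must be > 0 for class '", name, "'",
           call. = FALSE)
  })
  structure(spec, class = "tissue_class_spec")
}

#' @export
print.tissue_class_spec <- function(x, ...) {
  cat(sprintf("<tissue_class_spec> %s\n", x$name))
  cat(sprintf("  T1  (ms): mean %.2f sd %.2f  [%.2f, %.2f]\n",
              x$t1_mean, x$t1_sd, x$t1_min, x$t1_max))
  cat(sprintf("  T2* (ms): mean %.2f sd %.2f  [%.2f, %.2f]\n",
              x$t2s_mean, x$t2s_sd, x$t2s_min, x$t2s_max))
  cat(sprintf("  M0 (a.u.): mean %.3f sd %.3f\n", x$m0_mean, x$m0_sd))
  invisible(x)
}

#' Default tissue classes for carotid plaque phantoms
#'
#' The four plaque components (fibrous tissue, lipids, inflammation,
#' hemorrhage) parameterized by published ex vivo 11.7 T ROI statistics
#' (per-class mean, standard deviation, minimum and maximum of ROI-mean T1 and
#' T2*), plus a low-signal `background` class standing in for the fixative
#' bath (T1 = 2000 ms, T2* = 40 ms, M0 = 0.05).
#'
#' @return Named list of [tissue_class_spec()] objects in canonical order
#'   `background`, `fibrous`, `lipid`, `inflammation`, `hemorrhage`.
#' @export
#' @examples
#' names(default_tissue_classes())
default_tissue_classes <- function() {
  list(
    background = tissue_class_spec("background",
      t1_mean = 2000, t1_sd = 0, t1_min = 2000, t1_max = 2000,
      t2s_mean = 40, t2s_sd = 0, t2s_min = 40, t2s_max = 40,
      m0_mean = 0.05, m0_sd = 0),
    fibrous = tissue_class_spec("fibrous",
      t1_mean = 836.18, t1_sd = 322.36, t1_min = 239.36, t1_max = 1970.11,
      t2s_mean = 13.23, t2s_sd = 7.14, t2s_min = 2.04, t2s_max = 71.64,
      m0_mean = 1, m0_sd = 0.05),
    lipid = tissue_class_spec("lipid",
      t1_mean = 994.98, t1_sd = 338.93, t1_min = 241.03, t1_max = 2290.56,
      t2s_mean = 11.38, t2s_sd = 5.17, t2s_min = 3.59, t2s_max = 31.00,
      m0_mean = 1, m0_sd = 0.05),
    inflammation = tissue_class_spec("inflammation",
      t1_mean = 1317.74, t1_sd = 555.95, t1_min = 317.14, t1_max = 2670.81,
      t2s_mean = 11.35, t2s_sd = 11.26, t2s_min = 1.14, t2s_max = 68.15,
      m0_mean = 1, m0_sd = 0.05),
    hemorrhage = tissue_class_spec("hemorrhage",
      t1_mean = 1393.45, t1_sd = 774.46, t1_min = 406.08, t1_max = 3560.94,
      t2s_mean = 8.10, t2s_sd = 3.77, t2s_min = 1.55, t2s_max = 28.98,
      m0_mean = 1, m0_sd = 0.05)
  )
}

#' Region primitives for phantom construction
#'
#' Regions are painted into the label volume in list order (painter's order:
#' later regions overwrite earlier ones). Coordinates are 1-based voxel
#' indices in `(slice, row, col)` order.
#'
#' @param label Tissue class label of the region.
#' @param from,to Inclusive 1-based corner voxels `(slice, row, col)` of a box.
#' @return A `phantom_region` list.
#' @export
#' @examples
#' region_box("fibrous", c(1, 1, 1), c(4, 8, 8))
region_box <- function(label, from, to) {
  stopifnot(length(from) == 3L, length(to) == 3L, all(from >= 1),
            all(to >= from))
  structure(list(shape = "box", label = label,
                 from = as.integer(from), to = as.integer(to)),
            class = "phantom_region")
}

#' @param center Ellipsoid center `(slice, row, col)` in voxel units (may be
#'   fractional).
#' @param radii Ellipsoid semi-axes in voxels along `(slice, row, col)`.
#' @rdname region_box
#' @export
region_ellipsoid <- function(label, center, radii) {
  stopifnot(length(center) == 3L, length(radii) == 3L, all(radii > 0))
  structure(list(shape = "ellipsoid", label = label,
                 center = as.numeric(center), radii = as.numeric(radii)),
            class = "phantom_region")
}

#' Phantom specification
#'
#' Geometry of a digital plaque phantom: grid shape, voxel size, an ordered
#' list of painted regions and the background class.
#'
#' @param grid_shape Integer triple `(slices, rows, cols)`.
#' @param regions List of [region_box()] / [region_ellipsoid()] primitives,
#'   painted in order.
#' @param voxel_size_um Voxel edge lengths in micrometers; the acquisitions
#'   emulated here use 120 um isotropic voxels.
#' @param background_class Label filling unpainted voxels.
#' @param plaque_id Identifier carried through to ROIs and reports.
#' @param seed Integer seed making the per-voxel parameter draw deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, regions = list(),
                         voxel_size_um = c(120, 120, 120),
                         background_class = "background",
                         plaque_id = "plaque01", seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(voxel_size_um) == 3L, all(voxel_size_um > 0),
            is.list(regions))
  for (r in regions) {
    if (!inherits(r, "phantom_region"))
      stop("each region must be created by region_box()/region_ellipsoid()",
           call. = FALSE)
    if (r$shape == "box" && any(r$to > grid_shape))
      stop("region '", r$label, "' extends outside the grid", call. = FALSE)
    if (r$shape == "ellipsoid" &&
        (any(r$center - r$radii < 0.5) || any(r$center + r$radii > grid_shape + 0.5)))
      stop("region '", r$label, "' extends outside the grid", call. = FALSE)
  }
  structure(list(grid_shape = grid_shape,
                 voxel_size_um = as.numeric(voxel_size_um),
                 regions = regions,
                 background_class = background_class,
                 plaque_id = plaque_id,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Acquisition protocol for a spoiled gradient-echo series
#'
#' Describes either a variable-flip-angle (VFA) series used for T1 mapping or
#' a multi-echo series used for T2* mapping, plus the noise model applied to
#' the simulated magnitude images.
#'
#' @param mode `"vfa"` or `"multiecho"`.
#' @param tr Repetition time (ms).
#' @param flip_angles Flip angles in degrees (VFA mode; >= 2 distinct values).
#' @param echo_times Echo times in ms (multiecho mode; >= 2 distinct values).
#' @param te_fixed Echo time (ms) of the VFA acquisition; enters the forward
#'   model through the factor `A = exp(-TE/T2*)`.
#' @param flip_angle Flip angle (deg) of the multi-echo acquisition, used to
#'   compute the steady-state amplitude `S0`.
#' @param noise_model `"none"`, `"gaussian"` or `"rician"`.
#' @param noise_sigma Noise standard deviation as a fraction of the maximum
#'   noiseless signal in the stack.
#' @param zero_fill_factor Fourier zero-filling (interpolation) factor >= 1.
#' @param seed Integer seed for the noise draw.
#' @return An object of class `acquisition_protocol`.
#' @export
#' @examples
#' vfa_protocol()        # TR 10 ms, FA 5/10/20/30/40 deg, TE 2 ms
#' multiecho_protocol()  # TR 22 ms, TE 4/8/12/16/20 ms, FA 10 deg
acquisition_protocol <- function(mode = c("vfa", "multiecho"),
                                 tr,
                                 flip_angles = NULL,
                                 echo_times = NULL,
                                 te_fixed = 2,
                                 flip_angle = 10,
                                 noise_model = c("rician", "none", "gaussian"),
                                 noise_sigma = 0,
                                 zero_fill_factor = 1L,
                                 seed = 1L) {
  mode <- match.arg(mode)
  noise_model <- match.arg(noise_model)
  stopifnot(is.numeric(tr), tr > 0, noise_sigma >= 0, zero_fill_factor >= 1)
  if (mode == "vfa") {
    if (length(unique(flip_angles)) < 2L)
      stop("vfa mode requires >= 2 distinct flip angles", call. = FALSE)
    stopifnot(all(flip_angles >= 0), all(flip_angles < 180), te_fixed >= 0)
  } else {
    if (length(unique(echo_times)) < 2L)
      stop("multiecho mode requires >= 2 distinct echo times", call. = FALSE)
    stopifnot(all(echo_times >= 0), flip_angle > 0, flip_angle < 180)
  }
  structure(list(mode = mode, tr = as.numeric(tr),
                 flip_angles = as.numeric(flip_angles),
                 echo_times = as.numeric(echo_times),
                 te_fixed = as.numeric(te_fixed),
                 flip_angle = as.numeric(flip_angle),
                 noise_model = noise_model,
                 noise_sigma = as.numeric(noise_sigma),
                 zero_fill_factor = as.integer(zero_fill_factor),
                 seed = as.integer(seed)),
            class = "acquisition_protocol")
}

#' @param ... Passed on to [acquisition_protocol()] (noise options, seed, ...).
#' @rdname acquisition_protocol
#' @export
vfa_protocol <- function(tr = 10, flip_angles = c(5, 10, 20, 30, 40),
                         te_fixed = 2, ...) {
  acquisition_protocol("vfa", tr = tr, flip_angles = flip_angles,
                       te_fixed = te_fixed, ...)
}

#' @rdname acquisition_protocol
#' @export
multiecho_protocol <- function(tr = 22, echo_times = c(4, 8, 12, 16, 20),
                               flip_angle = 10, ...) {
  acquisition_protocol("multiecho", tr = tr, echo_times = echo_times,
                       flip_angle = flip_angle, ...)
}

# number of frames a protocol produces
n_frames <- function(protocol) {
  if (protocol$mode == "vfa") length(protocol$flip_angles)
  else length(protocol$echo_times)
}
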