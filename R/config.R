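#' Pipeline run configuration
#'
#' A run configuration bundles everything one end-to-end run needs: the
#' phantom geometry of each synthetic plaque, the tissue class parameters,
#' both acquisition protocols, the ROI sampling plan, the QDA options and a
#' master seed from which all per-stage seeds are derived. Configurations
#' round-trip through YAML.
#'
#' `default_run_config()` encodes a 12-plaque synthetic cohort mirroring the
#' composition pattern of the ex vivo study it emulates: fibrous tissue in
#' all 12 plaques, lipids in 10, inflammation in 9, hemorrhage in 5, and two
#' plaques of predominantly fibrous tissue on which QDA is not applicable.
#'
#' @param seed Master seed.
#' @param grid_shape Per-plaque grid `(slices, rows, cols)`.
#' @param noise_sigma Rician noise level as a fraction of the maximum
#'   noiseless signal (default 0.005, i.e. 0.5%).
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 20210121L, grid_shape = c(8L, 36L, 36L),
                               noise_sigma = 0.005) {
  # composition pattern: which classes each plaque contains
  comp <- list(
    c("fibrous", "lipid", "inflammation", "hemorrhage"),  # plaques 01-05
    c("fibrous", "lipid", "inflammation", "hemorrhage"),
    c("fibrous", "lipid", "inflammation", "hemorrhage"),
    c("fibrous", "lipid", "inflammation", "hemorrhage"),
    c("fibrous", "lipid", "inflammation", "hemorrhage"),
    c("fibrous", "lipid", "inflammation"),                 # 06-09
    c("fibrous", "lipid", "inflammation"),
    c("fibrous", "lipid", "inflammation"),
    c("fibrous", "lipid", "inflammation"),
    c("fibrous", "lipid"),                                 # 10
    c("fibrous"),                                          # 11-12: fibrous only
    c("fibrous"))
  g <- grid_shape
  ctr <- (g + 1) / 2
  plaques <- lapply(seq_along(comp), function(i) {
    classes <- comp[[i]]
    regions <- list(
      # outer fibrous body
      list(shape = "ellipsoid", label = "fibrous", center = ctr,
           radii = c(g[1] / 2 - 0.5, g[2] / 2 - 1.5, g[3] / 2 - 1.5)))
    inner <- setdiff(classes, "fibrous")
    # inner component pockets, side by side along the column axis
    if (length(inner)) {
      w <- (g[3] - 6) / length(inner)
      for (j in seq_along(inner)) {
        cc <- 3 + w * (j - 0.5)
        regions[[length(regions) + 1L]] <-
          list(shape = "ellipsoid", label = inner[j],
               center = c(ctr[1], ctr[2], cc),
               radii = c(g[1] / 2 - 1.5, g[2] / 4, w / 2 - 0.5))
      }
    }
    list(plaque_id = sprintf("plaque%02d", i), grid_shape = g,
         voxel_size_um = c(120, 120, 120), regions = regions,
         background_class = "background")
  })
  cfg <- list(
    seed = as.integer(seed),
    classes = "default",
    plaques = plaques,
    protocols = list(
      vfa = list(tr = 10, flip_angles = c(5, 10, 20, 30, 40), te_fixed = 2,
                 noise_model = "rician", noise_sigma = noise_sigma),
      multiecho = list(tr = 22, echo_times = c(4, 8, 12, 16, 20),
                       flip_angle = 10, noise_model = "rician",
                       noise_sigma = noise_sigma)),
    roi_plan = list(size_range = c(4L, 9L),
                    n_per_class = list(fibrous = 12L, lipid = 8L,
                                       inflammation = 6L, hemorrhage = 5L)),
    qda = list(scope = "per_plaque", shrinkage = 0.1, priors = "empirical"))
  structure(cfg, class = "run_config")
}

#' @param config A `run_config`.
#' @param path YAML file path.
#' @rdname default_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need <- c("seed", "classes", "plaques", "protocols", "roi_plan", "qda")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("run config lacks field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cls <- config_classes(cfg)
  cls_names <- vapply(cls, `[[`, character(1), "name")
  for (p in cfg$plaques) {
    for (fld in c("plaque_id", "grid_shape", "regions"))
      if (is.null(p[[fld]]))
        stop("plaque entry lacks field '", fld, "'", call. = FALSE)
    for (r in p$regions)
      if (!r$label %in% cls_names)
        stop("plaque '", p$plaque_id, "': region label '", r$label,
             "' has no class spec", call. = FALSE)
  }
  for (cl in names(cfg$roi_plan$n_per_class))
    if (!cl %in% cls_names)
      stop("roi plan names unknown class '", cl, "'", call. = FALSE)
  structure(cfg, class = "run_config")
}

# materialize the tissue class list of a config
config_classes <- function(cfg) {
  if (identical(cfg$classes, "default")) return(default_tissue_classes())
  lapply(cfg$classes, function(c)
    do.call(tissue_class_spec, c[names(c) != "shape"]))
}

# materialize one plaque entry into a phantom_spec
config_phantom_spec <- function(p, seed) {
  regions <- lapply(p$regions, function(r) {
    if (r$shape == "box") region_box(r$label, unlist(r$from), unlist(r$to))
    else region_ellipsoid(r$label, unlist(r$center), unlist(r$radii))
  })
  phantom_spec(unlist(p$grid_shape), regions,
               voxel_size_um = if (!is.null(p$voxel_size_um))
                 unlist(p$voxel_size_um) else c(120, 120, 120),
               background_class = p$background_class %||% "background",
               plaque_id = p$plaque_id, seed = seed)
}

config_protocol <- function(pr, mode, seed) {
  if (mode == "vfa")
    vfa_protocol(tr = pr$tr, flip_angles = unlist(pr$flip_angles),
                 te_fixed = pr$te_fixed %||% 2,
                 noise_model = pr$noise_model %||% "rician",
                 noise_sigma = pr$noise_sigma %||% 0, seed = seed)
  else
    multiecho_protocol(tr = pr$tr, echo_times = unlist(pr$echo_times),
                       flip_angle = pr$flip_angle %||% 10,
                       noise_model = pr$noise_model %||% "rician",
                       noise_sigma = pr$noise_sigma %||% 0, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stage seed derivation from the master seed; stays within
# 32-bit integer range
derive_seed <- function(master, stage, index = 0L) {
  stage_codes <- c(simulate = 11L, noise_vfa = 13L, noise_me = 17L,
                   roi = 19L, qda = 23L)
  code <- stage_codes[[stage]]
  as.integer((as.numeric(master) * 1009 + code * 9973 + index * 271) %%
             2147483647)
}
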