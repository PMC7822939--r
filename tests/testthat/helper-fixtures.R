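# shared fixtures: phantoms with prescribed ground-truth fields, synthetic
# feature frames for the classifier, and a small pipeline config

# phantom with explicit ground-truth arrays (single "tissue" class id 1,
# background id 0 unused); t1/t2s/m0 are recycled into `dims`
make_phantom_fields <- function(t1, t2s, m0 = 1, dims = c(2, 4, 4),
                                plaque_id = "fix01") {
  structure(list(
    labels = array(1L, dim = dims),
    t1_true = array(t1, dim = dims),
    t2s_true = array(t2s, dim = dims),
    m0_true = array(m0, dim = dims),
    class_table = data.frame(id = 0:1, name = c("background", "tissue"),
                             stringsAsFactors = FALSE),
    voxel_size_um = c(120, 120, 120),
    plaque_id = plaque_id), class = "phantom")
}

# single-class phantom drawn from one tissue_class_spec
uniform_class_phantom <- function(class_name, dims = c(4, 20, 20), seed = 1L,
                                  classes = default_tissue_classes(),
                                  plaque_id = "fix01") {
  spec <- phantom_spec(dims,
                       regions = list(region_box(class_name, c(1, 1, 1), dims)),
                       plaque_id = plaque_id, seed = seed)
  generate_phantom(spec, classes)
}

# feature frame with the 7 predictors; per-class multivariate-normal draws
# around well-separated or overlapping means
synth_features <- function(n_per_class, class_means, sds = 1, seed = 1L,
                           plaque_id = "pl01") {
  stopifnot(length(n_per_class) == length(class_means))
  preds <- qda_predictors()
  withr::with_seed(seed, {
    rows <- lapply(seq_along(class_means), function(k) {
      n <- n_per_class[k]
      mu <- class_means[[k]]
      stopifnot(length(mu) == 7L)
      x <- matrix(stats::rnorm(n * 7, mean = rep(mu, each = n), sd = sds),
                  nrow = n)
      colnames(x) <- preds
      cbind(data.frame(roi_id = sprintf("%s_c%d_%03d", plaque_id, k, seq_len(n)),
                       plaque_id = plaque_id,
                       tissue_label = names(class_means)[k],
                       stringsAsFactors = FALSE),
            as.data.frame(x))
    })
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("roi_features", "data.frame")
  res
}

# feature frame with exact, hand-chosen predictor values (one row per ROI)
exact_features <- function(tissue_label, mean_t1, mean_t2s = 10, sd_t1 = 1,
                           sd_t2s = 1, max_t1 = NULL, min_t1 = NULL,
                           n_pixels = 6, plaque_id = "pl01") {
  n <- max(length(tissue_label), length(mean_t1))
  df <- data.frame(
    roi_id = sprintf("%s_r%03d", plaque_id, seq_len(n)),
    plaque_id = plaque_id,
    tissue_label = rep_len(tissue_label, n),
    mean_t1 = rep_len(mean_t1, n),
    mean_t2s = rep_len(mean_t2s, n),
    sd_t1 = rep_len(sd_t1, n),
    sd_t2s = rep_len(sd_t2s, n),
    max_t1 = rep_len(if (is.null(max_t1)) mean_t1 + 1 else max_t1, n),
    min_t1 = rep_len(if (is.null(min_t1)) mean_t1 - 1 else min_t1, n),
    n_pixels = rep_len(n_pixels, n),
    stringsAsFactors = FALSE)
  class(df) <- c("roi_features", "data.frame")
  df
}

# small 3-plaque run config (two mixed plaques + one fibrous-only) for
# pipeline tests; noiseless by default so no ROI is ever dropped
small_run_config <- function(seed = 42L, noise_sigma = 0) {
  cfg <- default_run_config(seed = seed, grid_shape = c(6L, 24L, 24L),
                            noise_sigma = noise_sigma)
  keep <- c(1L, 6L, 11L)  # 4-class, 3-class, fibrous-only
  cfg$plaques <- cfg$plaques[keep]
  cfg$roi_plan$n_per_class <- list(fibrous = 8L, lipid = 6L,
                                   inflammation = 5L, hemorrhage = 4L)
  cfg
}
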