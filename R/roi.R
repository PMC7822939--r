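#' Sample homogeneous in-slice ROIs from a labeled phantom
#'
#' Draws, for each requested tissue class, random 4-connected blobs of 4-9
#' voxels lying within a single axial slice and composed entirely of voxels
#' of that class — the synthetic stand-in for an expert drawing small ROIs on
#' histology-matched map slices. Sampling is deterministic given `seed`.
#'
#' @param phantom A [generate_phantom()] result.
#' @param n_per_class Named integer vector or list, class name -> number of
#'   ROIs. An empty request returns an empty ROI set.
#' @param size_range Inclusive ROI size bounds in voxels; default `c(4, 9)`.
#' @param seed Integer seed.
#' @param max_tries Attempts per ROI before declaring the class unsampleable.
#' @return A data.frame of class `roi_set` in long form, one row per voxel,
#'   with columns `roi_id`, `plaque_id`, `tissue_label`, `slice`, `row`,
#'   `col` (1-based indices).
#' @export
sample_rois <- function(phantom, n_per_class, size_range = c(4, 9),
                        seed = 1L, max_tries = 200L) {
  stopifnot(inherits(phantom, "phantom"))
  n_per_class <- unlist(n_per_class)
  empty <- data.frame(roi_id = character(), plaque_id = character(),
                      tissue_label = character(), slice = integer(),
                      row = integer(), col = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("roi_set", "data.frame")
  if (!length(n_per_class)) return(empty)
  stopifnot(!is.null(names(n_per_class)), all(n_per_class >= 0))
  dims <- dim(phantom$labels)
  ct <- phantom$class_table
  out <- vector("list", sum(n_per_class))
  k <- 0L
  withr::with_seed(seed, {
    for (cls in names(n_per_class)) {
      id <- ct$id[match(cls, ct$name)]
      if (is.na(id))
        stop("class '", cls, "' not present in the phantom class table",
             call. = FALSE)
      cand <- which(phantom$labels == id, arr.ind = TRUE)
      if (nrow(cand) < size_range[1])
        stop("class '", cls, "' has too few voxels to sample ROIs",
             call. = FALSE)
      for (j in seq_len(n_per_class[[cls]])) {
        size <- sample(size_range[1]:size_range[2], 1L)
        blob <- NULL
        for (try in seq_len(max_tries)) {
          blob <- grow_blob(phantom$labels, id,
                            cand[sample.int(nrow(cand), 1L), ], size, dims)
          if (!is.null(blob)) break
        }
        if (is.null(blob))
          stop("could not sample a ", size,
               "-voxel homogeneous ROI for class '", cls, "'", call. = FALSE)
        k <- k + 1L
        out[[k]] <- data.frame(
          roi_id = sprintf("%s_%s_%04d", phantom$plaque_id, cls, j),
          plaque_id = phantom$plaque_id, tissue_label = cls,
          slice = blob[, 1], row = blob[, 2], col = blob[, 3],
          stringsAsFactors = FALSE)
      }
    }
  })
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  class(res) <- c("roi_set", "data.frame")
  res
}

# grow a 4-connected in-slice blob of `size` voxels of class `id` starting
# from `start` (slice, row, col); NULL if growth gets stuck
grow_blob <- function(labels, id, start, size, dims) {
  blob <- matrix(as.integer(start), nrow = 1)
  sl <- start[1]
  key <- function(m) (m[, 2] - 1L) * dims[3] + m[, 3]
  taken <- key(blob)
  while (nrow(blob) < size) {
    # frontier: 4-neighbors (within the slice) of current blob voxels
    nb <- rbind(cbind(sl, blob[, 2] - 1L, blob[, 3]),
                cbind(sl, blob[, 2] + 1L, blob[, 3]),
                cbind(sl, blob[, 2], blob[, 3] - 1L),
                cbind(sl, blob[, 2], blob[, 3] + 1L))
    okb <- nb[, 2] >= 1 & nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[okb, , drop = FALSE]
    nb <- nb[!key(nb) %in% taken, , drop = FALSE]
    if (nrow(nb))
      nb <- nb[labels[nb] == id, , drop = FALSE]
    if (!nrow(nb)) return(NULL)
    pick <- nb[sample.int(nrow(nb), 1L), , drop = FALSE]
    blob <- rbind(blob, pick)
    taken <- c(taken, key(pick))
  }
  colnames(blob) <- c("slice", "row", "col")
  blob
}

#' Extract ROI feature vectors from registered relaxation maps
#'
#' Computes the seven classification predictors per ROI — mean T1, mean T2*,
#' sample standard deviations of T1 and T2*, maximal and minimal T1, and ROI
#' size in pixels — over the ROI's *valid* voxels (both maps' validity masks
#' must hold). An ROI retaining fewer than `min_valid` valid voxels is
#' dropped with a warning and listed in the `rejects` attribute.
#'
#' @param maps A [relaxation_maps()] bundle (must be registered).
#' @param rois An `roi_set` from [sample_rois()] / [read_roi_csv()].
#' @param min_valid Minimum valid voxels for an ROI to be kept (default 4,
#'   the lower ROI-size bound).
#' @return A data.frame of class `roi_features` with columns `roi_id`,
#'   `plaque_id`, `tissue_label`, `mean_t1`, `mean_t2s`, `sd_t1`, `sd_t2s`,
#'   `max_t1`, `min_t1`, `n_pixels`; attribute `rejects` holds dropped ROI
#'   ids with reasons.
#' @export
extract_features <- function(maps, rois, min_valid = 4L) {
  stopifnot(inherits(maps, "relaxation_maps"), is.data.frame(rois))
  if (!maps$registered) stop("maps must be registered", call. = FALSE)
  dims <- dim(maps$t1$t1_map)
  need <- c("roi_id", "plaque_id", "tissue_label", "slice", "row", "col")
  if (!all(need %in% names(rois)))
    stop("roi set must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(rois) &&
      (any(rois$slice < 1 | rois$slice > dims[1]) ||
       any(rois$row < 1 | rois$row > dims[2]) ||
       any(rois$col < 1 | rois$col > dims[3])))
    stop("ROI voxel outside the map grid", call. = FALSE)
  ids <- unique(rois$roi_id)
  rows <- vector("list", length(ids))
  rejects <- list()
  for (i in seq_along(ids)) {
    sub <- rois[rois$roi_id == ids[i], , drop = FALSE]
    vox <- cbind(sub$slice, sub$row, sub$col)
    ok <- maps$t1$valid_mask[vox] & maps$t2s$valid_mask[vox]
    if (sum(ok) < min_valid) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        roi_id = ids[i], n_valid = sum(ok),
        reason = "fewer than min_valid valid voxels",
        stringsAsFactors = FALSE)
      next
    }
    t1v <- maps$t1$t1_map[vox[ok, , drop = FALSE]]
    t2v <- maps$t2s$t2s_map[vox[ok, , drop = FALSE]]
    rows[[i]] <- data.frame(
      roi_id = ids[i], plaque_id = sub$plaque_id[1],
      tissue_label = sub$tissue_label[1],
      mean_t1 = mean(t1v), mean_t2s = mean(t2v),
      sd_t1 = stats::sd(t1v), sd_t2s = stats::sd(t2v),
      max_t1 = max(t1v), min_t1 = min(t1v),
      n_pixels = length(t1v), stringsAsFactors = FALSE)
  }
  if (length(rejects))
    warning(length(rejects), " ROI(s) dropped: insufficient valid voxels",
            call. = FALSE)
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) res <- utils::head(
    data.frame(roi_id = character(), plaque_id = character(),
               tissue_label = character(), mean_t1 = numeric(),
               mean_t2s = numeric(), sd_t1 = numeric(), sd_t2s = numeric(),
               max_t1 = numeric(), min_t1 = numeric(), n_pixels = integer(),
               stringsAsFactors = FALSE), 0L)
  rownames(res) <- NULL
  attr(res, "rejects") <- if (length(rejects)) do.call(rbind, rejects) else NULL
  class(res) <- c("roi_features", "data.frame")
  res
}

#' Per-class summary of ROI-mean relaxation times
#'
#' Produces the classical ROI-statistics table: for every tissue class and
#' each of the two parameters (ROI-mean T1, ROI-mean T2*) the number of
#' ROIs, minimum, maximum, mean, sample standard deviation and range
#' (max - min) over the ROI-level means. Classes with a single ROI report
#' sd = 0 by convention.
#'
#' @param features An `roi_features` data.frame from [extract_features()].
#' @return Data.frame with columns `parameter`, `tissue_label`, `n_roi`,
#'   `min`, `max`, `mean`, `sd`, `range` (ms).
#' @export
summarize_classes <- function(features) {
  stopifnot(is.data.frame(features))
  if (!nrow(features)) stop("empty feature set", call. = FALSE)
  out <- list()
  for (param in c("mean_t1", "mean_t2s")) {
    for (cls in unique(features$tissue_label)) {
      v <- features[[param]][features$tissue_label == cls]
      out[[length(out) + 1L]] <- data.frame(
        parameter = if (param == "mean_t1") "mean T1" else "mean T2*",
        tissue_label = cls, n_roi = length(v),
        min = min(v), max = max(v), mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else 0,
        range = max(v) - min(v), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read and write ROI definitions
#'
#' ROI sets are exchanged as CSV (one row per voxel, columns `roi_id`,
#' `plaque_id`, `tissue_label`, `slice`, `row`, `col`) or an equivalent JSON
#' form (one record per ROI with a voxel list). On disk coordinates are
#' 0-based `(slice, row, col)`; in R they are 1-based, and these functions
#' convert.
#'
#' @param rois An `roi_set` data.frame.
#' @param path File path.
#' @return `read_roi_csv()` / `read_roi_json()` return an `roi_set`;
#'   the writers return `path` invisibly.
#' @export
write_roi_csv <- function(rois, path) {
  df <- as.data.frame(rois)
  df$slice <- df$slice - 1L; df$row <- df$row - 1L; df$col <- df$col - 1L
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "plaque_id", "tissue_label", "slice", "row", "col")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ROI file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$slice <- as.integer(df$slice) + 1L
  df$row <- as.integer(df$row) + 1L
  df$col <- as.integer(df$col) + 1L
  class(df) <- c("roi_set", "data.frame")
  df
}

#' @rdname write_roi_csv
#' @export
write_roi_json <- function(rois, path) {
  recs <- lapply(split(as.data.frame(rois), rois$roi_id), function(sub) {
    list(roi_id = sub$roi_id[1], plaque_id = sub$plaque_id[1],
         tissue_label = sub$tissue_label[1],
         voxels = unname(as.matrix(sub[, c("slice", "row", "col")]) - 1L))
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- lapply(seq_len(nrow(recs)), function(i) {
    vox <- matrix(unlist(recs$voxels[[i]]), ncol = 3) + 1L
    data.frame(roi_id = recs$roi_id[i], plaque_id = recs$plaque_id[i],
               tissue_label = recs$tissue_label[i],
               slice = vox[, 1], row = vox[, 2], col = vox[, 3],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$roi_id), ]
  rownames(df) <- NULL
  class(df) <- c("roi_set", "data.frame")
  df
}
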