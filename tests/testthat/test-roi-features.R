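# phantom + noiseless maps shared by the extraction tests
quadrant_phantom <- function(dims = c(4, 20, 20), seed = 21) {
  g <- dims
  regions <- list(
    region_box("fibrous", c(1, 1, 1), c(g[1], g[2] / 2, g[3] / 2)),
    region_box("lipid", c(1, 1, g[3] / 2 + 1), c(g[1], g[2] / 2, g[3])),
    region_box("inflammation", c(1, g[2] / 2 + 1, 1), c(g[1], g[2], g[3] / 2)),
    region_box("hemorrhage", c(1, g[2] / 2 + 1, g[3] / 2 + 1),
               c(g[1], g[2], g[3])))
  generate_phantom(phantom_spec(g, regions, seed = seed))
}

noiseless_maps <- function(ph) {
  relaxation_maps(
    fit_t1_vfa(simulate_acquisition(ph, vfa_protocol(noise_model = "none"))),
    fit_t2star(simulate_acquisition(ph, multiecho_protocol(noise_model = "none"))))
}

test_that("sample_rois honors counts, labels, size and 4-connectivity", {
  ph <- quadrant_phantom()
  plan <- list(fibrous = 10, lipid = 7, inflammation = 5, hemorrhage = 3)
  rois <- sample_rois(ph, plan, seed = 3)
  ids <- unique(rois$roi_id)
  expect_length(ids, 25L)
  counts <- table(vapply(split(rois$tissue_label, rois$roi_id), `[`, "", 1))
  expect_equal(as.vector(counts[names(plan)]), unlist(plan, use.names = FALSE))
  ct <- ph$class_table
  for (id in ids) {
    sub <- rois[rois$roi_id == id, ]
    # homogeneous label
    lab <- ct$id[match(sub$tissue_label[1], ct$name)]
    expect_true(all(ph$labels[cbind(sub$slice, sub$row, sub$col)] == lab))
    # in one slice, 4-9 voxels, distinct
    expect_length(unique(sub$slice), 1L)
    expect_gte(nrow(sub), 4L); expect_lte(nrow(sub), 9L)
    expect_false(any(duplicated(sub[, c("slice", "row", "col")])))
    # 4-connected: breadth-first flood from the first voxel reaches all
    vox <- as.matrix(sub[, c("row", "col")])
    reached <- 1L
    repeat {
      adj <- outer(seq_len(nrow(vox)), reached, function(i, j)
        abs(vox[i, 1] - vox[j, 1]) + abs(vox[i, 2] - vox[j, 2]) == 1)
      new <- setdiff(which(apply(adj, 1, any)), reached)
      if (!length(new)) break
      reached <- c(reached, new)
    }
    expect_length(reached, nrow(vox))
  }
})

test_that("sample_rois: empty plan, determinism, and failure naming the class", {
  ph <- quadrant_phantom()
  expect_identical(nrow(sample_rois(ph, list())), 0L)
  r1 <- sample_rois(ph, list(lipid = 5), seed = 9)
  r2 <- sample_rois(ph, list(lipid = 5), seed = 9)
  expect_identical(r1, r2)
  expect_error(sample_rois(ph, list(background = 3), seed = 1), "background")
})

test_that("extract_features computes the seven predictors correctly", {
  ph <- quadrant_phantom()
  maps <- noiseless_maps(ph)
  rois <- sample_rois(ph, list(fibrous = 6, lipid = 6), seed = 5)
  feats <- extract_features(maps, rois)
  expect_setequal(setdiff(names(feats), c("roi_id", "plaque_id", "tissue_label")),
                  qda_predictors())  # exactly the 7 predictors
  expect_identical(nrow(feats), 12L)
  expect_true(all(feats$min_t1 <= feats$mean_t1 & feats$mean_t1 <= feats$max_t1))
  expect_true(all(feats$sd_t1 >= 0 & feats$sd_t2s >= 0))
  expect_true(all(feats$n_pixels >= 4 & feats$n_pixels <= 9))
  # brute-force recomputation oracle on one ROI
  id <- feats$roi_id[1]
  sub <- rois[rois$roi_id == id, ]
  t1v <- maps$t1$t1_map[cbind(sub$slice, sub$row, sub$col)]
  expect_equal(feats$mean_t1[1], mean(t1v), tolerance = 1e-12)
  expect_equal(feats$sd_t1[1], sd(t1v), tolerance = 1e-12)
  expect_equal(feats$max_t1[1], max(t1v), tolerance = 1e-12)
})

test_that("feature statistics: constant ROI and the hand-computed sample sd", {
  # maps built directly so values are exact
  t1f <- structure(list(t1_map = array(1000, c(1, 2, 2)),
                        m0_map = array(1, c(1, 2, 2)),
                        valid_mask = array(TRUE, c(1, 2, 2)), tr = 10),
                   class = "t1_fit")
  t2f <- structure(list(t2s_map = array(10, c(1, 2, 2)),
                        s0_map = array(1, c(1, 2, 2)),
                        valid_mask = array(TRUE, c(1, 2, 2))),
                   class = "t2s_fit")
  maps <- relaxation_maps(t1f, t2f)
  rois <- data.frame(roi_id = "r1", plaque_id = "p", tissue_label = "fibrous",
                     slice = 1, row = c(1, 1, 2, 2), col = c(1, 2, 1, 2))
  f <- extract_features(maps, rois)
  expect_equal(f$mean_t1, 1000); expect_equal(f$sd_t1, 0)
  expect_equal(f$min_t1, 1000); expect_equal(f$max_t1, 1000)

  # T1 values {2, 4, 6, 8}: mean 5, sd = sqrt(20/3)
  t1f$t1_map[] <- c(2, 4, 6, 8)   # column-major fill over the 4 voxels
  maps2 <- relaxation_maps(t1f, t2f)
  f2 <- extract_features(maps2, rois)
  expect_equal(f2$mean_t1, 5)
  expect_equal(f2$min_t1, 2); expect_equal(f2$max_t1, 8)
  expect_equal(f2$sd_t1, sqrt(20 / 3), tolerance = 1e-9)
  expect_equal(f2$sd_t1, 2.5819889, tolerance = 1e-6)
})

test_that("ROIs with too few valid voxels are dropped and reported", {
  t1f <- structure(list(t1_map = array(1000, c(1, 3, 3)),
                        m0_map = array(1, c(1, 3, 3)),
                        valid_mask = array(TRUE, c(1, 3, 3)), tr = 10),
                   class = "t1_fit")
  t1f$valid_mask[1, 1, 1:2] <- FALSE
  t2f <- structure(list(t2s_map = array(10, c(1, 3, 3)),
                        s0_map = array(1, c(1, 3, 3)),
                        valid_mask = array(TRUE, c(1, 3, 3))),
                   class = "t2s_fit")
  maps <- relaxation_maps(t1f, t2f)
  rois <- data.frame(roi_id = rep(c("bad", "good"), each = 4),
                     plaque_id = "p", tissue_label = "fibrous",
                     slice = 1,
                     row = c(1, 1, 2, 2, 3, 3, 2, 2),
                     col = c(1, 2, 1, 2, 1, 2, 1, 2))
  expect_warning(f <- extract_features(maps, rois), "dropped")
  expect_identical(f$roi_id, "good")
  expect_identical(attr(f, "rejects")$roi_id, "bad")
  # out-of-grid voxel is an input error
  rois_bad <- transform(rois, col = col + 5)
  expect_error(extract_features(maps, rois_bad), "outside")
})

test_that("summarize_classes reproduces Table-style rows", {
  f <- exact_features(rep(c("fibrous", "lipid"), c(3, 2)),
                      mean_t1 = c(400, 700, 1000, 500, 900),
                      mean_t2s = c(5, 10, 15, 8, 12))
  s <- summarize_classes(f)
  expect_identical(nrow(s), 4L)   # 2 classes x 2 parameters
  fib_t1 <- s[s$parameter == "mean T1" & s$tissue_label == "fibrous", ]
  expect_equal(fib_t1$n_roi, 3)
  expect_equal(fib_t1$min, 400); expect_equal(fib_t1$max, 1000)
  expect_equal(fib_t1$mean, 700)
  expect_equal(fib_t1$sd, sd(c(400, 700, 1000)))
  expect_true(all(s$range == s$max - s$min))
  # singleton class: min = max = mean, sd 0, range 0
  s1 <- summarize_classes(exact_features("hemorrhage", 1200))
  expect_true(all(s1$sd == 0) && all(s1$range == 0))
  expect_error(summarize_classes(exact_features("x", 1)[0, ]), "empty")
})

test_that("ROI definitions round-trip through CSV and JSON with 0-based files", {
  ph <- quadrant_phantom()
  rois <- sample_rois(ph, list(fibrous = 3, hemorrhage = 3), seed = 12)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_roi_csv(rois, csv)
  write_roi_json(rois, js)
  # files are 0-based
  raw <- utils::read.csv(csv)
  expect_identical(min(raw$slice), min(rois$slice) - 1L)
  back_csv <- read_roi_csv(csv)
  expect_equal(as.data.frame(back_csv), as.data.frame(rois))
  back_js <- read_roi_json(js)
  ord <- order(rois$roi_id)
  expect_equal(back_js[, c("roi_id", "slice", "row", "col")],
               as.data.frame(rois[ord, c("roi_id", "slice", "row", "col")]),
               ignore_attr = TRUE)
  expect_error(read_roi_csv(withr::local_tempfile(lines = "a,b\n1,2",
                                                  fileext = ".csv")),
               "lacks column")
})

test_that("noiseless zero-sd phantom: ROI means equal class means exactly", {
  cls <- default_tissue_classes()
  for (nm in names(cls)) {
    cls[[nm]]$t1_sd <- 0; cls[[nm]]$t2s_sd <- 0; cls[[nm]]$m0_sd <- 0
  }
  g <- c(2, 12, 12)
  regions <- list(region_box("fibrous", c(1, 1, 1), c(2, 12, 6)),
                  region_box("lipid", c(1, 1, 7), c(2, 12, 12)))
  ph <- generate_phantom(phantom_spec(g, regions, seed = 2), cls)
  maps <- noiseless_maps(ph)
  rois <- sample_rois(ph, list(fibrous = 4, lipid = 4), seed = 6)
  feats <- extract_features(maps, rois)
  for (nm in c("fibrous", "lipid")) {
    v <- feats$mean_t1[feats$tissue_label == nm]
    expect_equal(v, rep(cls[[nm]]$t1_mean, 4), tolerance = 1e-9)
  }
  s <- summarize_classes(feats)
  expect_true(all(abs(s$range) < 1e-9))
})
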