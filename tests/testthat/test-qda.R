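test_that("fit_qda means/covariances equal brute-force per-class recomputation", {
  feats <- synth_features(c(a = 15, b = 12),
                          list(a = c(800, 12, 40, 2, 900, 700, 6),
                               b = c(1200, 8, 60, 3, 1300, 1100, 6)),
                          sds = 10, seed = 2)
  fit <- fit_qda(feats, scope = "pooled", shrinkage = 0)
  m <- fit$models$pooled
  x <- as.matrix(feats[, qda_predictors()])
  for (cl in c("a", "b")) {
    xc <- x[feats$tissue_label == cl, ]
    expect_equal(unname(m$means[[cl]]), unname(colMeans(xc)), tolerance = 1e-12)
    expect_equal(unname(m$covariances[[cl]]), unname(cov(xc)),
                 tolerance = 1e-12)
  }
  expect_equal(unname(m$priors), c(15, 12) / 27, tolerance = 1e-12)
  # uniform priors flag
  fit_u <- fit_qda(feats, scope = "pooled", shrinkage = 0, priors = "uniform")
  expect_equal(unname(fit_u$models$pooled$priors), c(0.5, 0.5))
})

test_that("translation equivariance: shifted classes share the covariance", {
  base <- synth_features(c(a = 10), list(a = rep(0, 7)), sds = 1, seed = 7)
  shifted <- base
  shifted$tissue_label <- "b"
  shifted$roi_id <- paste0(shifted$roi_id, "_b")
  delta <- c(5, 4, 3, 2, 1, 6, 7)
  shifted[, qda_predictors()] <- sweep(as.matrix(shifted[, qda_predictors()]),
                                       2, delta, `+`)
  both <- rbind(base, shifted)
  class(both) <- c("roi_features", "data.frame")
  m <- fit_qda(both, scope = "pooled", shrinkage = 0)$models$pooled
  expect_equal(unname(m$means$b - m$means$a), delta, tolerance = 1e-10)
  expect_equal(m$covariances$a, m$covariances$b, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("scopes with fewer than two usable classes become not-applicable", {
  feats <- rbind(
    synth_features(c(fibrous = 10), list(fibrous = rep(1, 7)), seed = 1,
                   plaque_id = "pl_fib"),
    synth_features(c(fibrous = 8, lipid = 8),
                   list(fibrous = rep(0, 7), lipid = rep(10, 7)), seed = 2,
                   plaque_id = "pl_mix"))
  class(feats) <- c("roi_features", "data.frame")
  fit <- fit_qda(feats, scope = "per_plaque", shrinkage = 0.1)
  expect_named(fit$models, "pl_mix")
  expect_identical(fit$not_applicable$scope, "pl_fib")
  expect_match(fit$not_applicable$reason, "not applicable")
  # classes with a single ROI are dropped from the scope's model
  one <- synth_features(c(a = 6, b = 6), list(a = rep(0, 7), b = rep(5, 7)),
                        seed = 3)
  extra <- synth_features(c(hem = 1), list(hem = rep(9, 7)), seed = 4)
  feats2 <- rbind(one, extra)
  class(feats2) <- c("roi_features", "data.frame")
  m2 <- fit_qda(feats2, scope = "pooled")$models$pooled
  expect_setequal(m2$classes, c("a", "b"))
  expect_identical(m2$dropped_classes, "hem")
})

test_that("classify_rois: 1-D boundary, class-mean point, and tie-breaking", {
  # 1-D instructive case: other six predictors constant; class means 0 and 2
  # along mean_t1 with unit sample variance and equal priors -> boundary at 1
  s <- sqrt(1 / 2)
  f <- exact_features(rep(c("a", "b"), each = 2),
                      mean_t1 = c(-s, s, 2 - s, 2 + s),
                      mean_t2s = 10, sd_t1 = 1, sd_t2s = 1,
                      max_t1 = 5, min_t1 = -5, n_pixels = 6)
  m <- fit_qda(f, scope = "pooled", shrinkage = 1)$models$pooled
  probe <- exact_features("a", mean_t1 = 0.9, mean_t2s = 10, sd_t1 = 1,
                          sd_t2s = 1, max_t1 = 5, min_t1 = -5, n_pixels = 6)
  pred <- classify_rois(m, probe)
  expect_identical(pred$predicted_label, "a")
  probe$mean_t1 <- 1.1
  expect_identical(classify_rois(m, probe)$predicted_label, "b")

  # a point exactly at a class mean with equal covariances and priors
  feats <- synth_features(c(a = 20, b = 20),
                          list(a = rep(0, 7), b = rep(3, 7)), sds = 1,
                          seed = 5)
  fit <- fit_qda(feats, scope = "pooled", shrinkage = 0.2, priors = "uniform")
  mm <- fit$models$pooled
  mm$covariances$b <- mm$covariances$a     # force equal shapes
  at_mean <- exact_features("b", mean_t1 = 0)
  at_mean[, qda_predictors()] <- rep(mm$means$b, each = 1)
  expect_identical(classify_rois(mm, at_mean)$predicted_label, "b")
  expect_true(classify_rois(mm, at_mean)$misclassified == FALSE)

  # exact tie -> first class in declared order
  tie <- at_mean
  tie[, qda_predictors()] <- rep((mm$means$a + mm$means$b) / 2, each = 1)
  expect_identical(classify_rois(mm, tie)$predicted_label, "a")

  expect_error(classify_rois(mm, at_mean[, -4]), "lack")
})

test_that("well-separated classes give zero resubstitution misclassification", {
  # means 10 sd apart on every predictor
  feats <- synth_features(c(fibrous = 25, lipid = 25),
                          list(fibrous = rep(0, 7), lipid = rep(10, 7)),
                          sds = 1, seed = 8)
  fit <- fit_qda(feats, scope = "pooled", shrinkage = 0.1)
  preds <- classify_rois(fit$models$pooled, feats)
  expect_identical(sum(preds$misclassified), 0L)
})

test_that("scores equal exhaustive multivariate-normal log-densities plus log priors", {
  skip_if_not_installed("mvtnorm")
  withr::with_seed(17, {
    for (k in 2:4) {
      means <- lapply(seq_len(k), function(i) rnorm(7, mean = 3 * i, sd = 1))
      names(means) <- paste0("c", seq_len(k))
      n <- sample(8:20, k, replace = TRUE)
      names(n) <- names(means)
      feats <- synth_features(n, means, sds = 1.5,
                              seed = sample.int(1e6, 1))
      expect_lte(nrow(feats), 200)
      fit <- fit_qda(feats, scope = "pooled", shrinkage = 0.1)
      m <- fit$models$pooled
      preds <- classify_rois(m, feats)
      x <- as.matrix(feats[, m$predictors])
      oracle_scores <- sapply(m$classes, function(cl)
        mvtnorm::dmvnorm(x, mean = m$means[[cl]],
                         sigma = m$covariances[[cl]], log = TRUE) +
          log(m$priors[[cl]]))
      oracle_pred <- m$classes[apply(oracle_scores, 1, which.max)]
      expect_identical(preds$predicted_label, oracle_pred)
      # scores differ from the log density only by the constant -7/2 log(2*pi)
      ours <- as.matrix(preds[, paste0("score_", m$classes)])
      expect_equal(unname(ours - oracle_scores),
                   matrix(3.5 * log(2 * pi), nrow(x), k), tolerance = 1e-8)
    }
  })
})

test_that("predicted labels agree with MASS::qda on a shared fit (lambda 0)", {
  skip_if_not_installed("MASS")
  feats <- synth_features(c(a = 30, b = 30, c = 30),
                          list(a = rep(0, 7), b = rep(2, 7), c = rep(4, 7)),
                          sds = 2, seed = 23)
  fit <- fit_qda(feats, scope = "pooled", shrinkage = 0)
  ours <- classify_rois(fit$models$pooled, feats)$predicted_label
  x <- as.data.frame(as.matrix(feats[, qda_predictors()]))
  mq <- MASS::qda(x, grouping = factor(feats$tissue_label))
  theirs <- as.character(predict(mq, x)$class)
  expect_identical(ours, theirs)
})

test_that("resubstitution rate is invariant to affine feature rescaling (lambda 0)", {
  feats <- synth_features(c(a = 20, b = 20, c = 20),
                          list(a = rep(0, 7), b = rep(1.5, 7), c = rep(3, 7)),
                          sds = 1.2, seed = 31)
  run <- function(f) {
    fit <- fit_qda(f, scope = "pooled", shrinkage = 0)
    mean(classify_rois(fit$models$pooled, f)$misclassified)
  }
  base_rate <- run(feats)
  scaled <- feats
  a <- c(2, 0.5, 10, 0.1, 3, 7, 0.25); b <- c(100, -5, 0, 2, -40, 8, 1)
  scaled[, qda_predictors()] <-
    sweep(sweep(as.matrix(feats[, qda_predictors()]), 2, a, `*`), 2, b, `+`)
  expect_equal(run(scaled), base_rate, tolerance = 1e-12)
  expect_gt(base_rate, 0)   # overlapping classes: the check is not vacuous
})

test_that("shrinkage lambda = 1 never yields a singular model", {
  # constant predictors (zero variance) and tiny classes
  f <- exact_features(rep(c("a", "b"), each = 2),
                      mean_t1 = c(0, 0, 5, 5), n_pixels = 4)
  fit <- fit_qda(f, scope = "pooled", shrinkage = 1)
  for (cl in fit$models$pooled$classes) {
    ev <- eigen(fit$models$pooled$covariances[[cl]], symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  # and classification still works on the degenerate geometry
  preds <- classify_rois(fit$models$pooled, f)
  expect_identical(sum(preds$misclassified), 0L)
  # lambda = 0 on the same degenerate input is singular -> informative error
  expect_error(fit_qda(f, scope = "pooled", shrinkage = 0), "singular")
})

test_that("separation property: misclassification vanishes as means diverge", {
  rates <- vapply(c(0.5, 2, 10), function(d) {
    feats <- synth_features(c(a = 20, b = 20),
                            list(a = rep(0, 7), b = rep(d, 7)), sds = 1,
                            seed = 40)
    fit <- fit_qda(feats, scope = "pooled", shrinkage = 0.1)
    mean(classify_rois(fit$models$pooled, feats)$misclassified)
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_identical(rates[3], 0)
})

test_that("misclassification_report: rates, t-interval and degenerate cases", {
  mk_preds <- function(plaque, n, n_mis) {
    data.frame(roi_id = sprintf("%s_%02d", plaque, 1:n), plaque_id = plaque,
               true_label = "a",
               predicted_label = rep(c("b", "a"), c(n_mis, n - n_mis)),
               misclassified = rep(c(TRUE, FALSE), c(n_mis, n - n_mis)),
               stringsAsFactors = FALSE)
  }
  # 8 predictions, 1 misclassified -> 12.5%
  rep1 <- misclassification_report(mk_preds("p1", 8, 1))
  expect_equal(rep1$per_plaque$rate, 12.5)
  expect_equal(rep1$mean_rate, 12.5)
  expect_equal(c(rep1$ci_low, rep1$ci_high), c(12.5, 12.5))  # single plaque

  # all correct -> zero mean, degenerate CI [0, 0]
  rep0 <- misclassification_report(rbind(mk_preds("p1", 5, 0),
                                         mk_preds("p2", 7, 0)))
  expect_equal(rep0$mean_rate, 0)
  expect_equal(c(rep0$ci_low, rep0$ci_high), c(0, 0))

  # rates {10, 15, 20}: closed-form t(2) interval oracle
  preds <- rbind(mk_preds("p1", 10, 1), mk_preds("p2", 20, 3),
                 mk_preds("p3", 10, 2))
  rep3 <- misclassification_report(preds)
  expect_equal(sort(rep3$per_plaque$rate), c(10, 15, 20))
  expect_equal(rep3$mean_rate, 15)
  half <- qt(0.975, df = 2) * sd(c(10, 15, 20)) / sqrt(3)
  expect_equal(rep3$ci_low, 15 - half, tolerance = 1e-9)
  expect_equal(rep3$ci_high, 15 + half, tolerance = 1e-9)
  expect_equal(rep3$ci_low, 2.5793114, tolerance = 1e-6)
  expect_equal(rep3$ci_high, 27.4206886, tolerance = 1e-6)

  # zero eligible plaques: empty report with a warning
  expect_warning(repe <- misclassification_report(mk_preds("p", 5, 0)[0, ]),
                 "empty")
  expect_true(is.na(repe$mean_rate))
})

test_that("QDA model sets round-trip through JSON", {
  feats <- rbind(
    synth_features(c(a = 8, b = 8), list(a = rep(0, 7), b = rep(4, 7)),
                   seed = 3, plaque_id = "p1"),
    synth_features(c(fibrous = 9), list(fibrous = rep(1, 7)), seed = 4,
                   plaque_id = "p2"))
  class(feats) <- c("roi_features", "data.frame")
  fit <- fit_qda(feats, scope = "per_plaque", shrinkage = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_qda_json(fit, path)
  back <- read_qda_json(path)
  expect_identical(names(back$models), names(fit$models))
  m0 <- fit$models$p1; m1 <- back$models$p1
  expect_equal(m1$means, m0$means, tolerance = 1e-12)
  expect_equal(m1$covariances, m0$covariances, tolerance = 1e-12)
  expect_equal(m1$priors, m0$priors, tolerance = 1e-12)
  expect_identical(m1$training_scope, "p1")
  expect_identical(back$not_applicable$scope, fit$not_applicable$scope)
  # restored models classify identically
  sub <- feats[feats$plaque_id == "p1", ]
  expect_identical(classify_rois(m1, sub)$predicted_label,
                   classify_rois(m0, sub)$predicted_label)
})
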