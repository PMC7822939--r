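#' Fit quadratic discriminant models to ROI feature vectors
#'
#' Fits, per training scope (one model per plaque, or one pooled model), a
#' Gaussian class-conditional model: class mean vector, class sample
#' covariance matrix shrunk toward its diagonal as
#' `(1 - lambda) * Sigma + lambda * diag(Sigma)`, and class priors
#' (empirical frequencies or uniform). Scopes that do not contain at least
#' two classes with at least two ROIs each are recorded as not applicable
#' rather than raising an error — mirroring plaques dominated by a single
#' tissue on which discriminant analysis cannot be trained.
#'
#' Zero-variance predictors (e.g. every ROI in a class having the same pixel
#' count) would make even the diagonal shrinkage target singular; their
#' diagonal entries are floored at a small positive value so that
#' `shrinkage = 1` always yields a proper model.
#'
#' @param features An `roi_features` data.frame ([extract_features()]).
#' @param scope `"per_plaque"` (default) or `"pooled"`.
#' @param shrinkage Shrinkage weight lambda in `[0, 1]`; default 0.1.
#' @param priors `"empirical"` (class frequencies, default) or `"uniform"`.
#' @return A list of class `qda_model_set`: element `models` is a named list
#'   of `qda_model` objects (one per applicable scope), element
#'   `not_applicable` a data.frame of skipped scopes with reasons.
#' @export
fit_qda <- function(features, scope = c("per_plaque", "pooled"),
                    shrinkage = 0.1, priors = c("empirical", "uniform")) {
  scope <- match.arg(scope)
  priors <- match.arg(priors)
  stopifnot(is.data.frame(features), shrinkage >= 0, shrinkage <= 1)
  groups <- if (scope == "per_plaque")
    split(features, features$plaque_id) else list(pooled = features)
  models <- list()
  na_rows <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    counts <- table(g$tissue_label)
    usable <- names(counts)[counts >= 2L]
    if (length(usable) < 2L) {
      na_rows[[length(na_rows) + 1L]] <- data.frame(
        scope = gname,
        reason = sprintf("QDA not applicable: %d class(es) with >= 2 ROIs",
                         length(usable)),
        stringsAsFactors = FALSE)
      next
    }
    dropped <- setdiff(names(counts), usable)
    g <- g[g$tissue_label %in% usable, , drop = FALSE]
    x <- as.matrix(g[, qda_predictors()])
    cls <- sort(usable)
    means <- covs <- list()
    for (cl in cls) {
      xc <- x[g$tissue_label == cl, , drop = FALSE]
      means[[cl]] <- colMeans(xc)
      sig <- stats::cov(xc)
      target <- diag(diag(sig), ncol(sig))
      # floor zero-variance entries of the shrinkage target
      dmax <- max(diag(sig))
      floorv <- if (dmax > 0) 1e-6 * dmax else 1e-12
      diag(target) <- pmax(diag(target), floorv)
      covs[[cl]] <- (1 - shrinkage) * sig + shrinkage * target
    }
    pri <- if (priors == "empirical")
      as.numeric(counts[cls] / sum(counts[cls])) else rep(1 / length(cls), length(cls))
    names(pri) <- cls
    model <- structure(list(classes = cls, means = means, covariances = covs,
                            priors = pri, shrinkage = shrinkage,
                            prior_mode = priors, training_scope = gname,
                            dropped_classes = dropped,
                            predictors = qda_predictors()),
                       class = "qda_model")
    validate_qda_model(model)
    models[[gname]] <- model
  }
  structure(list(models = models,
                 not_applicable = if (length(na_rows)) do.call(rbind, na_rows)
                                  else NULL,
                 scope = scope),
            class = "qda_model_set")
}

#' The seven QDA predictor names
#'
#' Mean T1, mean T2*, the two standard deviations, maximal and minimal T1,
#' and ROI size in pixels.
#' @return Character vector of length 7.
#' @export
qda_predictors <- function() {
  c("mean_t1", "mean_t2s", "sd_t1", "sd_t2s", "max_t1", "min_t1", "n_pixels")
}

validate_qda_model <- function(model) {
  stopifnot(length(model$classes) >= 2L,
            abs(sum(model$priors) - 1) < 1e-8)
  for (cl in model$classes) {
    ev <- eigen(model$covariances[[cl]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("covariance for class '", cl, "' in scope '",
           model$training_scope,
           "' is singular after shrinkage; increase 'shrinkage'",
           call. = FALSE)
  }
  invisible(model)
}

#' Classify ROI feature vectors with a fitted QDA model
#'
#' Scores each ROI against every class with the quadratic discriminant
#' \deqn{\delta_k(x) = -\tfrac12 \ln|\Sigma_k|
#'   - \tfrac12 (x - \mu_k)^\top \Sigma_k^{-1} (x - \mu_k) + \ln \pi_k}
#' and predicts the class with the maximal score (ties broken by class
#' order). An ROI whose predicted class differs from its label is flagged
#' misclassified.
#'
#' @param model A `qda_model`.
#' @param features `roi_features` rows to classify (must carry the seven
#'   predictors).
#' @return Data.frame of class `qda_predictions` with `roi_id`, `plaque_id`,
#'   `true_label`, `predicted_label`, `misclassified`, plus one
#'   `score_<class>` column per class.
#' @export
classify_rois <- function(model, features) {
  stopifnot(inherits(model, "qda_model"), is.data.frame(features))
  miss <- setdiff(model$predictors, names(features))
  if (length(miss))
    stop("features lack predictor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(features[, model$predictors])
  if (ncol(x) != length(model$predictors))
    stop("predictor dimension mismatch", call. = FALSE)
  scores <- sapply(model$classes, function(cl) {
    mu <- model$means[[cl]]
    sig <- model$covariances[[cl]]
    ch <- chol(sig)
    logdet <- 2 * sum(log(diag(ch)))
    z <- backsolve(ch, t(x) - mu, transpose = TRUE)   # ch' z = (x - mu)'
    maha <- colSums(z * z)
    -0.5 * logdet - 0.5 * maha + log(model$priors[[cl]])
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  pred <- model$classes[apply(scores, 1, which.max)]  # which.max: first wins
  res <- data.frame(roi_id = features$roi_id, plaque_id = features$plaque_id,
                    true_label = features$tissue_label,
                    predicted_label = pred,
                    misclassified = pred != features$tissue_label,
                    stringsAsFactors = FALSE)
  colnames(scores) <- paste0("score_", model$classes)
  res <- cbind(res, as.data.frame(scores))
  rownames(res) <- NULL
  class(res) <- c("qda_predictions", "data.frame")
  res
}

#' Classify with every model of a fitted set
#'
#' Applies each per-scope model to its own ROIs (resubstitution for
#' `per_plaque` scope) or the pooled model to all ROIs.
#'
#' @param model_set A `qda_model_set` from [fit_qda()].
#' @param features The `roi_features` the set was trained on.
#' @return A `qda_predictions` data.frame covering all applicable scopes.
#' @export
classify_all <- function(model_set, features) {
  stopifnot(inherits(model_set, "qda_model_set"))
  if (!length(model_set$models)) {
    res <- data.frame(roi_id = character(), plaque_id = character(),
                      true_label = character(), predicted_label = character(),
                      misclassified = logical(), stringsAsFactors = FALSE)
    class(res) <- c("qda_predictions", "data.frame")
    attr(res, "not_applicable") <- model_set$not_applicable
    return(res)
  }
  preds <- lapply(names(model_set$models), function(gname) {
    m <- model_set$models[[gname]]
    sub <- if (model_set$scope == "per_plaque")
      features[features$plaque_id == gname &
               features$tissue_label %in% m$classes, , drop = FALSE]
    else features[features$tissue_label %in% m$classes, , drop = FALSE]
    classify_rois(m, sub)
  })
  # score columns differ between scopes; keep the common core + scores by union
  core <- c("roi_id", "plaque_id", "true_label", "predicted_label",
            "misclassified")
  all_cols <- unique(unlist(lapply(preds, names)))
  preds <- lapply(preds, function(p) {
    for (cn in setdiff(all_cols, names(p))) p[[cn]] <- NA_real_
    p[, all_cols]
  })
  res <- do.call(rbind, preds)
  rownames(res) <- NULL
  class(res) <- c("qda_predictions", "data.frame")
  attr(res, "not_applicable") <- model_set$not_applicable
  res
}

#' Per-plaque misclassification report
#'
#' Summarizes resubstitution predictions into per-plaque misclassification
#' rates (percent), their unweighted mean over eligible plaques, and a
#' Student-t confidence interval on that mean. Plaques on which QDA was not
#' applicable are listed with reasons and excluded from the mean.
#'
#' @param predictions A `qda_predictions` data.frame (typically from
#'   [classify_all()], which attaches the not-applicable scopes).
#' @param ci_level Confidence level, default 0.95.
#' @param not_applicable Optional data.frame of excluded scopes (overrides
#'   the attribute on `predictions`).
#' @return List of class `misclassification_report`: `per_plaque`
#'   (data.frame plaque_id, n_roi, n_misclassified, rate), `mean_rate`,
#'   `ci_low`, `ci_high` (percent), `ci_method`, `excluded_plaques`.
#' @export
misclassification_report <- function(predictions, ci_level = 0.95,
                                     not_applicable = NULL) {
  stopifnot(is.data.frame(predictions), ci_level > 0, ci_level < 1)
  if (is.null(not_applicable))
    not_applicable <- attr(predictions, "not_applicable")
  if (!nrow(predictions)) {
    warning("no eligible plaques: empty report", call. = FALSE)
    return(structure(list(per_plaque = data.frame(), mean_rate = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          ci_method = "student-t",
                          excluded_plaques = not_applicable),
                     class = "misclassification_report"))
  }
  per <- do.call(rbind, lapply(split(predictions, predictions$plaque_id),
    function(p) data.frame(plaque_id = p$plaque_id[1], n_roi = nrow(p),
                           n_misclassified = sum(p$misclassified),
                           rate = 100 * mean(p$misclassified),
                           stringsAsFactors = FALSE)))
  per <- per[order(per$plaque_id), ]
  rownames(per) <- NULL
  rates <- per$rate
  m <- mean(rates)
  if (length(rates) > 1L && stats::sd(rates) > 0) {
    half <- stats::qt(1 - (1 - ci_level) / 2, df = length(rates) - 1L) *
      stats::sd(rates) / sqrt(length(rates))
    ci <- c(m - half, m + half)
  } else {
    ci <- c(m, m)   # degenerate: single plaque or zero variance
  }
  structure(list(per_plaque = per, mean_rate = m,
                 ci_low = ci[1], ci_high = ci[2],
                 ci_method = sprintf("student-t %.0f%% on per-plaque rates",
                                     100 * ci_level),
                 excluded_plaques = not_applicable),
            class = "misclassification_report")
}

#' @export
print.misclassification_report <- function(x, ...) {
  cat("<misclassification_report>\n")
  if (nrow(x$per_plaque)) {
    print(x$per_plaque, row.names = FALSE)
    cat(sprintf("mean rate %.1f%%  (CI %.1f-%.1f, %s)\n",
                x$mean_rate, x$ci_low, x$ci_high, x$ci_method))
  } else cat("  (empty)\n")
  if (!is.null(x$excluded_plaques) && nrow(x$excluded_plaques)) {
    cat("excluded:\n")
    print(x$excluded_plaques, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize / restore fitted QDA models
#'
#' Models are stored as JSON (class means, covariances, priors, shrinkage,
#' scope) so that pipeline stages can be re-run from saved intermediates.
#'
#' @param model_set A `qda_model_set`.
#' @param path JSON file path.
#' @return `read_qda_json()` returns a `qda_model_set`; the writer returns
#'   `path` invisibly.
#' @export
write_qda_json <- function(model_set, path) {
  stopifnot(inherits(model_set, "qda_model_set"))
  ser <- list(
    scope = model_set$scope,
    models = lapply(model_set$models, function(m) list(
      classes = m$classes,
      means = m$means,
      covariances = lapply(m$covariances, function(s) unclass(as.matrix(s))),
      priors = as.list(m$priors),
      shrinkage = m$shrinkage, prior_mode = m$prior_mode,
      training_scope = m$training_scope, predictors = m$predictors)),
    not_applicable = model_set$not_applicable)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qda_json
#' @export
read_qda_json <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(seq_along(ser$models), function(i) {
    m <- ser$models[[i]]
    covs <- lapply(m$covariances, function(s) {
      s <- as.matrix(s)
      dimnames(s) <- list(m$predictors, m$predictors)
      s
    })
    means <- lapply(m$means, function(v) {
      v <- unlist(v); names(v) <- m$predictors; v
    })
    structure(list(classes = m$classes, means = means, covariances = covs,
                   priors = unlist(m$priors), shrinkage = m$shrinkage,
                   prior_mode = m$prior_mode,
                   training_scope = m$training_scope,
                   dropped_classes = character(),
                   predictors = m$predictors),
              class = "qda_model")
  })
  names(models) <- names(ser$models)
  na_df <- ser$not_applicable
  if (!is.data.frame(na_df) || !nrow(na_df)) na_df <- NULL
  structure(list(models = models, not_applicable = na_df, scope = ser$scope),
            class = "qda_model_set")
}
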