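check_features <- function(features) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (is.null(colnames(features))) stop("feature matrix must have column names")
  storage.mode(features) <- "double"
  features
}

new_model <- function(task, forest, schema, n_trees, seed, oob, extra = list()) {
  structure(c(list(task = task, forest = forest, schema = schema,
                   schema_version = FEATURE_SCHEMA_VERSION,
                   n_trees = n_trees, seed = seed, oob_error = oob),
              extra),
            class = "guidekit_model")
}

#' @export
print.guidekit_model <- function(x, ...) {
  cat(sprintf("<guidekit_model> %s: %d trees, %d features, OOB %s = %.4g\n",
              x$task, x$n_trees, length(x$schema),
              if (x$task == "regression") "MSE" else "misclassification rate",
              x$oob_error))
  invisible(x)
}

#' Train a Random Forest guide-efficiency regressor
#'
#' All hyperparameters except the number of trees stay at library
#' defaults; 450 trees is the tuned default. Training is deterministic
#' given the seed, and the out-of-bag MSE is stored on the model.
#'
#' @param features Numeric matrix (rows = guides) with schema column
#'   names, e.g. from [featurize_sequences()].
#' @param labels Efficiency labels in percent (\[0, 100\]), one per row.
#' @param n_trees Number of trees (default 450).
#' @param seed Integer RNG seed.
#' @return A `guidekit_model` (task `"regression"`).
#' @export
train_regressor <- function(features, labels, n_trees = 450L, seed = 1L) {
  features <- check_features(features)
  stopifnot(nrow(features) == length(labels), nrow(features) >= 10L,
            n_trees >= 1L)
  if (any(labels < 0 | labels > 100)) stop("labels must lie in [0, 100]")
  fams <- attr(features, "families", exact = TRUE)
  enc <- attr(features, "encoding", exact = TRUE)
  set.seed(seed)
  forest <- randomForest::randomForest(x = features, y = as.numeric(labels),
                                       ntree = n_trees)
  new_model("regression", forest, colnames(features), n_trees, seed,
            oob = forest$mse[n_trees],
            extra = list(families = fams, encoding = enc))
}

#' Train a Random Forest SNV-outcome classifier
#'
#' Multiclass classifier of the substituted base at a hotspot position,
#' trained on tokenized analysis windows (39 nt by default upstream).
#' For any target the outcome can only be one of the 3 non-reference
#' bases, so chance accuracy is 1/3; rows whose label equals the
#' reference base are rejected. The out-of-bag misclassification rate
#' is stored on the model.
#'
#' @param features Numeric feature matrix with column names.
#' @param labels Outcome base per row (`A`/`C`/`G`/`T`).
#' @param ref_base Reference base at the hotspot (single base, or one
#'   per row); labels equal to it are invalid.
#' @param n_trees Number of trees (default 450).
#' @param seed Integer RNG seed.
#' @return A `guidekit_model` (task `"classification"`) with
#'   `chance_accuracy = 1/3`.
#' @export
train_snv_classifier <- function(features, labels, ref_base = NULL,
                                 n_trees = 450L, seed = 1L) {
  features <- check_features(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (!all(labels %in% BASES)) stop("labels must be A/C/G/T")
  if (!is.null(ref_base)) {
    bad <- labels == rep_len(toupper(ref_base), length(labels))
    if (any(bad)) stop(sum(bad), " row(s) rejected: outcome equals the ",
                       "reference base at the hotspot")
  }
  fams <- attr(features, "families", exact = TRUE)
  enc <- attr(features, "encoding", exact = TRUE)
  set.seed(seed)
  forest <- randomForest::randomForest(x = features, y = factor(labels),
                                       ntree = n_trees)
  oob <- forest$err.rate[n_trees, "OOB"]
  new_model("classification", forest, colnames(features), n_trees, seed,
            oob = unname(oob),
            extra = list(chance_accuracy = 1 / 3, families = fams,
                         encoding = enc))
}

#' Predict from a trained model
#'
#' The feature schema must equal the training schema (names and order).
#' Regression predictions are clipped to \[0, 100\]; classification
#' returns the predicted class, or a class-probability matrix with
#' `type = "prob"`.
#'
#' @param object A `guidekit_model`.
#' @param features Feature matrix with the training schema.
#' @param type `"response"` (default) or, for classification, `"prob"`.
#' @param ... Unused.
#' @return Numeric vector, factor, or probability matrix.
#' @export
predict.guidekit_model <- function(object, features, type = "response", ...) {
  features <- check_features(features)
  if (!identical(colnames(features), object$schema)) {
    stop("feature schema mismatch between model and input")
  }
  if (object$task == "regression") {
    p <- stats::predict(object$forest, features)
    return(unname(pmin(100, pmax(0, p))))
  }
  if (type == "prob") {
    stats::predict(object$forest, features, type = "prob")
  } else {
    stats::predict(object$forest, features)
  }
}

#' Deterministic k-fold assignment
#'
#' Unstratified folds are a seeded random shuffle split into k nearly
#' equal groups. Stratified folds (classification) shuffle within each
#' class and deal members round-robin, preserving class proportions
#' within one sample per class per fold.
#'
#' @param n Number of samples (unstratified) — or omit and give `y`.
#' @param k Number of folds.
#' @param seed Integer RNG seed.
#' @param y Optional class labels for stratification.
#' @return Integer vector of fold ids (1..k), length n.
#' @export
make_folds <- function(n, k = 5L, seed = 1L, y = NULL) {
  if (!is.null(y)) {
    n <- length(y)
    tab <- table(y)
    small <- names(tab)[tab < k]
    if (length(small)) {
      stop("class '", small[1L], "' has fewer members (", tab[small[1L]],
           ") than folds (", k, ")")
    }
    set.seed(seed)
    folds <- integer(n)
    offset <- 0L
    for (cl in names(tab)) {
      idx <- sample(which(y == cl))
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)  # rotate so remainders spread over folds
    }
    return(folds)
  }
  stopifnot(n >= k)
  set.seed(seed)
  folds <- integer(n)
  folds[sample.int(n)] <- rep_len(seq_len(k), n)
  folds
}

#' k-fold cross-validation of a Random Forest model
#'
#' Data are partitioned across samples into k groups (default 5); each
#' group is held out once while a model is trained on the rest.
#' Regression uses unstratified folds; classification uses stratified
#' folds that preserve class proportions within one sample per class.
#' Mean metrics are arithmetic means over folds.
#'
#' @param features Feature matrix with column names.
#' @param labels Numeric labels (regression) or class labels
#'   (classification).
#' @param task `"regression"` or `"classification"`.
#' @param folds Number of folds (default 5).
#' @param n_trees Trees per fold model (default 450).
#' @param seed Integer RNG seed (drives both fold assignment and fold
#'   models).
#' @return List with `fold_id` (per-sample assignment), `per_fold`
#'   (data.frame of per-fold metrics: mse/pearson_r/spearman_rho or
#'   accuracy), `mean` (named means over folds), and `predictions`
#'   (data.frame `index`, `truth`, `pred` of pooled out-of-fold
#'   predictions).
#' @export
cross_validate <- function(features, labels, task = c("regression",
                                                      "classification"),
                           folds = 5L, n_trees = 450L, seed = 1L) {
  task <- match.arg(task)
  features <- check_features(features)
  n <- nrow(features)
  stopifnot(n == length(labels), n >= folds)
  fold_id <- if (task == "classification") {
    make_folds(k = folds, seed = seed, y = as.character(labels))
  } else {
    make_folds(n, k = folds, seed = seed)
  }
  per_fold <- list()
  pred_all <- if (task == "regression") numeric(n) else character(n)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (task == "regression") {
      m <- train_regressor(features[!test, , drop = FALSE], labels[!test],
                           n_trees = n_trees, seed = seed + f)
      p <- predict(m, features[test, , drop = FALSE])
      pred_all[test] <- p
      truth <- labels[test]
      per_fold[[f]] <- data.frame(
        fold = f, n_test = sum(test),
        mse = mean((p - truth)^2),
        pearson_r = if (stats::sd(p) > 0 && stats::sd(truth) > 0)
          stats::cor(p, truth) else NA_real_,
        spearman_rho = if (stats::sd(p) > 0 && stats::sd(truth) > 0)
          stats::cor(p, truth, method = "spearman") else NA_real_)
    } else {
      m <- train_snv_classifier(features[!test, , drop = FALSE],
                                labels[!test], n_trees = n_trees,
                                seed = seed + f)
      p <- as.character(predict(m, features[test, , drop = FALSE]))
      pred_all[test] <- p
      per_fold[[f]] <- data.frame(
        fold = f, n_test = sum(test),
        accuracy = mean(p == labels[test]))
    }
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- setdiff(names(per_fold), c("fold", "n_test"))
  list(fold_id = fold_id, per_fold = per_fold,
       mean = colMeans(per_fold[, metric_cols, drop = FALSE], na.rm = TRUE),
       predictions = data.frame(index = seq_len(n), truth = labels,
                                pred = pred_all, stringsAsFactors = FALSE))
}

#' Validation report: predictions against truths
#'
#' Regression: MSE, Pearson and Spearman correlations with two-sided p,
#' and percentile ranks of both lists. Classification: confusion matrix
#' (rows = truth, columns = prediction) and per-class accuracy; pass
#' class probabilities to [roc_one_vs_all()] for ROC/AUC.
#'
#' @param predictions,truths Equal-length vectors (n >= 3).
#' @param task `"regression"` or `"classification"`.
#' @return For regression a list with `mse`, `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p` (correlations `NA` when either list
#'   has zero variance), `percentile_ranks` (data.frame `truth_rank`,
#'   `pred_rank`); for classification a list with `confusion`,
#'   `per_class_accuracy`, `accuracy`.
#' @export
validate <- function(predictions, truths, task = c("regression",
                                                   "classification")) {
  task <- match.arg(task)
  stopifnot(length(predictions) == length(truths), length(truths) >= 3L)
  if (task == "classification") {
    lev <- sort(unique(c(as.character(truths), as.character(predictions))))
    confusion <- table(truth = factor(truths, lev),
                       prediction = factor(predictions, lev))
    per_class <- diag(confusion) / rowSums(confusion)
    return(list(confusion = confusion, per_class_accuracy = per_class,
                accuracy = sum(diag(confusion)) / sum(confusion)))
  }
  mse <- mean((predictions - truths)^2)
  if (stats::sd(predictions) == 0 || stats::sd(truths) == 0) {
    message("zero variance; correlations undefined")
    pe <- list(estimate = NA_real_, p.value = NA_real_)
    sp <- pe
  } else {
    pe <- stats::cor.test(predictions, truths)
    sp <- suppressWarnings(
      stats::cor.test(predictions, truths, method = "spearman"))
  }
  list(mse = mse,
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       percentile_ranks = data.frame(
         truth_rank = percentile_ranks(truths),
         pred_rank = percentile_ranks(predictions)))
}

#' Ranked feature importances of a trained model
#'
#' Random-Forest impurity importances normalised to sum to 1, sorted in
#' decreasing order with ties broken by schema order. When every raw
#' importance is zero (pure-noise degenerate case) a uniform weighting
#' is returned.
#'
#' @param model A `guidekit_model`.
#' @return Data.frame with `feature`, `weight` (weights >= 0, sum 1).
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "guidekit_model") || is.null(model$forest)) {
    stop("model is not a trained guidekit_model")
  }
  imp <- randomForest::importance(model$forest)[, 1L]
  w <- if (sum(imp) > 0) imp / sum(imp) else
    rep(1 / length(imp), length(imp))
  ord <- order(-w, seq_along(w))
  data.frame(feature = model$schema[ord], weight = unname(w[ord]),
             stringsAsFactors = FALSE)
}

#' Percentile ranks of values within their own list
#'
#' Mean-of-strict-and-weak convention:
#' `100 * (#\{x < v\} + #\{x <= v\}) / (2n)`. Order-preserving; a list
#' of identical values ranks everything at 50.
#'
#' @param values Numeric vector (n >= 1).
#' @return Numeric vector of ranks in \[0, 100\].
#' @export
percentile_ranks <- function(values) {
  n <- length(values)
  stopifnot(n >= 1L)
  vapply(values, function(v)
    100 * (sum(values < v) + sum(values <= v)) / (2 * n), numeric(1))
}

#' Permutation test for a Pearson correlation
#'
#' Tests association between held-out predictions and truths by
#' shuffling one vector; two-sided p with the add-one correction
#' `(1 + #\{|r_perm| >= |r_obs|\}) / (n_perm + 1)`.
#'
#' @param predictions,truths Equal-length numeric vectors.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer RNG seed.
#' @return List with `r`, `p`, `n_perm`.
#' @export
permutation_cor_test <- function(predictions, truths, n_perm = 9999L,
                                 seed = 1L) {
  stopifnot(length(predictions) == length(truths))
  r_obs <- stats::cor(predictions, truths)
  set.seed(seed)
  r_perm <- replicate(n_perm, stats::cor(predictions, sample(truths)))
  list(r = r_obs,
       p = (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1),
       n_perm = n_perm)
}

#' One-vs-all ROC curves and AUCs
#'
#' For each class, the ROC of that class's predicted probability
#' against the binary indicator truth == class; AUC 0.5 indicates
#' random discrimination.
#'
#' @param truths Class labels.
#' @param prob Probability matrix with one named column per class.
#' @return List keyed by class: each entry has `auc` and `curve`
#'   (data.frame `fpr`, `tpr`).
#' @export
roc_one_vs_all <- function(truths, prob) {
  stopifnot(is.matrix(prob), !is.null(colnames(prob)),
            nrow(prob) == length(truths))
  out <- lapply(colnames(prob), function(cl) {
    resp <- as.integer(as.character(truths) == cl)
    r <- pROC::roc(resp, prob[, cl], quiet = TRUE, direction = "<",
                   levels = c(0, 1))
    list(auc = as.numeric(pROC::auc(r)),
         curve = data.frame(fpr = 1 - r$specificities,
                            tpr = r$sensitivities))
  })
  stats::setNames(out, colnames(prob))
}

#' Save / load a trained model
#'
#' The model is serialised to a single binary artifact with a JSON
#' sidecar (`<path>.json`) recording task, tree count, feature-schema
#' version and length, seed and OOB error.
#'
#' @param model A `guidekit_model`.
#' @param path Output path for the model artifact.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "guidekit_model"))
  saveRDS(model, path)
  meta <- list(task = model$task, n_trees = model$n_trees,
               schema_version = model$schema_version,
               n_features = length(model$schema),
               seed = model$seed, oob_error = model$oob_error)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "guidekit_model")) stop("not a guidekit model file")
  if (!identical(model$schema_version, FEATURE_SCHEMA_VERSION)) {
    stop("model was trained under feature schema '", model$schema_version,
         "'; this build uses '", FEATURE_SCHEMA_VERSION, "'")
  }
  model
}
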