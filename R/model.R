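# Random-forest modeling: train/test split, similarity-constrained CV with
# BEDROC-driven hyperparameter selection, final-model training, evaluation.

#' Random shuffled train/test split
#'
#' Test size is `floor(test_fraction * n)`; the remainder goes to training
#' (a 4:1 ratio at the default). Reproducible under the seed.
#'
#' @param records data.frame (or anything with rows).
#' @param test_fraction fraction held out.
#' @param seed integer seed.
#' @return list with `train` and `test` row indices.
#' @export
split_train_test <- function(records, test_fraction = 0.2, seed = 42) {
  n <- if (is.data.frame(records) || is.matrix(records)) nrow(records)
       else length(records)
  stopifnot(n >= 10)
  n_test <- floor(test_fraction * n)
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n - n_test)]),
       test = sort(perm[seq(n - n_test + 1L, n)]))
}

# ---- RF engine --------------------------------------------------------------

# Resolve a max_features specification against the full panel width d_total
# and the width d_kept that remains after dropping constant columns. mtry is
# rescaled as round(m * d_kept / d_total) so that candidate-split sampling
# matches full-panel semantics in expectation ("all" maps exactly to d_kept).
resolve_mtry <- function(max_features, d_total, d_kept) {
  m <- if (identical(max_features, "all") || is.null(max_features)) {
    d_total
  } else if (identical(max_features, "sqrt")) {
    floor(sqrt(d_total))
  } else if (is.numeric(max_features) && max_features > 0 && max_features <= 1) {
    floor(max_features * d_total)
  } else {
    stop("max_features must be 'all', 'sqrt', or a fraction in (0, 1]")
  }
  max(1L, min(d_kept, as.integer(round(m * d_kept / d_total))))
}

# Fit a 1000-tree classification forest; probability of activity is defined
# as the fraction of trees voting active. Constant feature columns carry no
# split information and are dropped before fitting (see resolve_mtry).
fit_rf <- function(x, y, max_features = 0.2, n_trees = 1000, seed = 42,
                   min_node_size = 1) {
  x <- unclass(x)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- factor(as.character(y), levels = c("inactive", "active"))
  if (any(is.na(y))) stop("labels must be 'active'/'inactive'")
  keep <- which(apply(x, 2L, function(col) any(col != col[1L])))
  if (length(keep) == 0L) stop("all feature columns are constant")
  mtry <- resolve_mtry(max_features, ncol(x), length(keep))
  xk <- x[, keep, drop = FALSE]
  colnames(xk) <- paste0("f", keep)
  fit <- ranger::ranger(x = xk, y = y, num.trees = n_trees, mtry = mtry,
                        min.node.size = min_node_size, num.threads = 1L,
                        seed = seed)
  list(fit = fit, keep = keep, d_total = ncol(x), mtry = mtry,
       max_features = max_features, n_trees = n_trees, seed = seed)
}

predict_rf <- function(model, x) {
  x <- unclass(x)
  stopifnot(is.matrix(x), ncol(x) == model$d_total)
  xk <- x[, model$keep, drop = FALSE]
  colnames(xk) <- paste0("f", model$keep)
  pred <- stats::predict(model$fit, data = xk, num.threads = 1L,
                         predict.all = TRUE)
  votes <- pred$predictions
  active_level <- which(model$fit$forest$levels == "active")
  rowMeans(votes == active_level)
}

# ---- cross-validation and model selection -----------------------------------

#' Similarity-constrained cross-validation with BEDROC model selection
#'
#' Builds one fold plan (Butina clusters at `similarity_floor` assigned to
#' `k` folds, shared across the whole hyperparameter grid), then for every
#' `max_features` value trains on the k-1 oversampled training folds and
#' scores the held-out fold. The grid value with the highest mean fold
#' BEDROC wins (ties: first in grid order). Oversampling happens strictly
#' inside the training folds; held-out folds are never touched.
#'
#' @param x feature matrix (rows match `labels`).
#' @param labels `"active"`/`"inactive"` vector.
#' @param fingerprints ECFP4 matrix used for clustering (may equal `x`).
#' @param grid list/vector of max_features values
#'   (`"all"`, `"sqrt"`, or fractions).
#' @param k folds.
#' @param alpha BEDROC alpha.
#' @param seed integer seed (fold shuffle, oversampler, forests).
#' @param similarity_floor Butina threshold for the fold plan.
#' @param oversample_mode passed to [smote_balance()].
#' @param n_trees forest size.
#' @return a `screen_cv` object: per-setting fold BEDROC table, the chosen
#'   `max_features`, the shared `fold_plan`, and out-of-fold scores of the
#'   chosen setting.
#' @export
cv_select <- function(x, labels, fingerprints,
                      grid = list("all", "sqrt", 0.2, 0.4, 0.8),
                      k = 5, alpha = 20.0, seed = 42,
                      similarity_floor = 0.3,
                      oversample_mode = "continuous",
                      n_trees = 1000) {
  x <- unclass(x)
  stopifnot(length(grid) >= 1, nrow(x) == length(labels))
  act <- as_active(labels)
  clusters <- butina_cluster(fingerprints, similarity_floor)
  plan <- assign_folds(clusters, k = k, seed = seed)

  grid_names <- vapply(grid, function(g) {
    if (is.character(g)) g else format(g)
  }, "")
  fold_bedroc <- matrix(NA_real_, length(grid), k,
                        dimnames = list(grid_names, paste0("fold", 1:k)))
  oof <- matrix(NA_real_, length(grid), nrow(x))

  for (gi in seq_along(grid)) {
    for (fold in seq_len(k)) {
      hold <- plan$fold_id == fold
      if (!any(hold)) next
      if (length(unique(act[!hold])) < 2L) {
        stop("training folds must contain both classes; ",
             "reduce k or rebalance the dataset")
      }
      bal <- smote_balance(x[!hold, , drop = FALSE],
                           ifelse(act[!hold], "active", "inactive"),
                           mode = oversample_mode, seed = seed + fold)
      model <- fit_rf(bal$x, bal$y, max_features = grid[[gi]],
                      n_trees = n_trees, seed = seed)
      p <- predict_rf(model, x[hold, , drop = FALSE])
      oof[gi, hold] <- p
      if (any(act[hold]) && any(!act[hold])) {
        fold_bedroc[gi, fold] <- bedroc(p, act[hold], alpha = alpha)
      }
    }
  }
  mean_bedroc <- rowMeans(fold_bedroc, na.rm = TRUE)
  best <- which.max(mean_bedroc)  # ties: first in grid order
  res <- list(table = data.frame(max_features = grid_names,
                                 fold_bedroc,
                                 mean_bedroc = mean_bedroc,
                                 row.names = NULL),
              best_max_features = grid[[best]],
              best_mean_bedroc = mean_bedroc[[best]],
              oof_scores = oof[best, ],
              fold_plan = plan,
              alpha = alpha, seed = seed, k = k,
              oversample_mode = oversample_mode)
  class(res) <- "screen_cv"
  res
}

#' @export
print.screen_cv <- function(x, ...) {
  cat(sprintf("%d-fold similarity-constrained CV, BEDROC alpha = %g\n",
              x$k, x$alpha))
  print(x$table, digits = 3)
  cat(sprintf("selected max_features: %s (mean BEDROC %.3f)\n",
              format(x$best_max_features), x$best_mean_bedroc))
  invisible(x)
}

# ---- final model ------------------------------------------------------------

#' Train a final screening model on a full dataset
#'
#' Oversamples the whole dataset to class balance and trains the
#' 1000-tree random forest with the chosen `max_features`. The returned
#' bundle carries a training manifest (panel, hyperparameters, seeds,
#' dataset hash) sufficient to retrain identically.
#'
#' @param x feature matrix.
#' @param labels `"active"`/`"inactive"` vector.
#' @param max_features chosen hyperparameter (from [cv_select()]).
#' @param panel feature panel tag (e.g. `"ecfp4_2048"`).
#' @param n_trees forest size.
#' @param seed integer seed.
#' @param oversample_mode passed to [smote_balance()].
#' @return a `screen_model`.
#' @export
train_final <- function(x, labels, max_features, panel = attr(x, "panel"),
                        n_trees = 1000, seed = 42,
                        oversample_mode = "continuous") {
  x <- unclass(x)
  act <- as_active(labels)
  bal <- smote_balance(x, ifelse(act, "active", "inactive"),
                       mode = oversample_mode, seed = seed)
  model <- fit_rf(bal$x, bal$y, max_features = max_features,
                  n_trees = n_trees, seed = seed)
  manifest <- list(panel = panel %||% "unknown",
                   n_trees = n_trees,
                   min_samples_split = 2,
                   max_features = max_features,
                   seed = seed,
                   oversampler = paste0("smote_", oversample_mode),
                   n_compounds = nrow(x),
                   n_active = sum(act),
                   n_inactive = sum(!act),
                   d = ncol(x),
                   dataset_hash = dataset_hash(x, act),
                   trained_at = format(Sys.time(), tz = "UTC"))
  structure(list(model = model, manifest = manifest), class = "screen_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dataset_hash <- function(x, y) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(list(round(unname(x), 12), unname(y)), con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' @export
print.screen_model <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("screen_model: %s panel, %d trees, max_features=%s\n",
              m$panel, m$n_trees, format(m$max_features)))
  cat(sprintf("  trained on %d compounds (%d active / %d inactive), seed %d\n",
              m$n_compounds, m$n_active, m$n_inactive, m$seed))
  invisible(x)
}

#' @export
summary.screen_model <- function(object, ...) {
  utils::str(object$manifest, give.attr = FALSE)
  invisible(object$manifest)
}

#' Predict activity probabilities from a screening model
#'
#' @param object a `screen_model`.
#' @param newdata feature matrix matching the model's panel, or a character
#'   vector of standardized SMILES (featurized according to the panel).
#' @param ... unused.
#' @return numeric vector of probabilities (fraction of trees voting
#'   active).
#' @export
predict.screen_model <- function(object, newdata, ...) {
  if (is.character(newdata)) {
    newdata <- switch(object$manifest$panel,
      ecfp4_2048 = ecfp4(newdata),
      physchem_2d = physchem_panel(newdata),
      pca_panel_13 = pca_panel_13(newdata),
      stop("cannot featurize SMILES for panel ", object$manifest$panel))
  }
  predict_rf(object$model, newdata)
}

#' Evaluate a model on a foreign (cross-source) dataset
#'
#' @param object a `screen_model`.
#' @param x feature matrix of the foreign dataset (same panel).
#' @param labels labels of the foreign dataset.
#' @param alpha BEDROC alpha.
#' @return list with `roc_auc`, `bedroc`, `n_active`, `n_inactive`.
#' @export
cross_source_evaluate <- function(object, x, labels, alpha = 20.0) {
  act <- as_active(labels)
  if (!any(act) || all(act)) {
    stop("foreign dataset must contain both classes")
  }
  p <- predict(object, x)
  list(roc_auc = roc_auc(p, act),
       bedroc = bedroc(p, act, alpha = alpha),
       n_active = sum(act),
       n_inactive = sum(!act))
}
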