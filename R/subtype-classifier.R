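# Subtype classification: predict the parent-image label (M0/M1/M2) from
# morphology-only, motility-only or combined per-cell features, with a
# radial-kernel SVM under shuffled stratified 5-fold cross-validation.
# Training folds are SMOTE-balanced (minority classes oversampled to the
# majority count by interpolation between same-class neighbours);
# z-scoring and SMOTE are fit on the training fold only, so test data
# never leak into balancing or scaling.

#' Feature columns of the three classifier variants
#'
#' Morphology uses `eccentricity`, `compactness`, `cell_size`; motility
#' uses `hull_area`, `speed`, `persistence`; combined is their union.
#'
#' @param name `"morphology"`, `"motility"` or `"combined"`.
#' @return Character vector of column names.
#' @export
feature_set_columns <- function(name = c("combined", "morphology", "motility")) {
  name <- match.arg(name)
  morph <- c("eccentricity", "compactness", "cell_size")
  mot <- c("hull_area", "speed", "persistence")
  switch(name, morphology = morph, motility = mot, combined = c(morph, mot))
}

#' SMOTE oversampling of minority classes
#'
#' Each minority class is upsampled to the majority-class count: a new
#' point is placed at a uniform random fraction of the segment between a
#' randomly chosen class member and one of its `k_neighbors` nearest
#' same-class neighbours (Euclidean). The majority class is untouched.
#' Classes smaller than `k_neighbors + 1` use all available neighbours,
#' with a warning. Randomness comes from the current RNG stream.
#'
#' @param x numeric feature matrix.
#' @param y class labels.
#' @param k_neighbors number of nearest neighbours to interpolate with.
#' @return List with `x`, `y` (originals first, synthetic points
#'   appended) and `n_synthetic` per class.
#' @export
smote_balance <- function(x, y, k_neighbors = 5L) {
  x <- as.matrix(x)
  y <- factor(y)
  counts <- table(y)
  target <- max(counts)
  added_x <- list(); added_y <- list()
  n_syn <- setNames(integer(nlevels(y)), levels(y))
  for (cl in levels(y)) {
    deficit <- target - counts[[cl]]
    if (deficit == 0L) next
    xi <- x[y == cl, , drop = FALSE]
    if (nrow(xi) < 2L)
      stop_macmot("class ", cl, " has fewer than 2 members; cannot SMOTE")
    k <- k_neighbors
    if (nrow(xi) <= k) {
      k <- nrow(xi) - 1L
      warning("class ", cl, " smaller than k_neighbors + 1; using k = ", k)
    }
    d <- as.matrix(dist(xi))
    diag(d) <- Inf
    nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
    base <- sample.int(nrow(xi), deficit, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, deficit, replace = TRUE))]
    u <- runif(deficit)
    syn <- xi[base, , drop = FALSE] +
      u * (xi[pick, , drop = FALSE] - xi[base, , drop = FALSE])
    added_x[[cl]] <- syn
    added_y[[cl]] <- rep(cl, deficit)
    n_syn[cl] <- deficit
  }
  list(x = rbind(x, do.call(rbind, added_x)),
       y = factor(c(as.character(y), unlist(added_y, use.names = FALSE)),
                  levels = levels(y)),
       n_synthetic = n_syn)
}

#' Train an RBF-kernel SVM and predict
#'
#' Multiclass (one-vs-one) soft-margin SVM with radial basis kernel,
#' `cost = 1` and kernel bandwidth `gamma = 1/p` -- with z-scored
#' features (unit variance) this is the usual `1/(p * var)` convention.
#' Features must already be scaled; no further scaling is applied.
#'
#' @param x_train,y_train training features and labels.
#' @param x_test test features.
#' @param cost soft-margin cost C.
#' @param gamma kernel bandwidth; `NULL` for `1/ncol(x_train)`.
#' @param kernel e1071 kernel name.
#' @return Factor of predicted labels for `x_test`.
#' @export
train_predict_svm <- function(x_train, y_train, x_test, cost = 1,
                              gamma = NULL, kernel = "radial") {
  y_train <- factor(y_train)
  if (nlevels(droplevels(y_train)) < 2L)
    stop_macmot("training fold contains a single class")
  fit <- e1071::svm(as.matrix(x_train), y_train, kernel = kernel,
                    cost = cost, gamma = gamma %||% (1 / ncol(x_train)),
                    scale = FALSE)
  predict(fit, as.matrix(x_test))
}

#' Cross-validated subtype classification experiment
#'
#' Shuffles the cohort, builds stratified folds, and per fold: z-scores
#' by training-fold statistics, SMOTE-balances the training fold, fits
#' the RBF SVM and predicts the held-out fold. Confusion counts are
#' pooled over folds; the row-normalized matrix (rows = actual, columns =
#' predicted, rows summing to 100%) carries the per-class accuracies on
#' its diagonal.
#'
#' @param table feature table with `parent_label` and the feature columns
#'   of the chosen set.
#' @param feature_set see [feature_set_columns()].
#' @param n_folds number of folds.
#' @param seed integer seed controlling shuffling, folds and SMOTE.
#' @param smote_k SMOTE neighbour count.
#' @param svm_cost SVM cost parameter.
#' @return Object of class `subtype_cv_report`: `confusion_counts`,
#'   `confusion_pct`, `per_class_accuracy`, `overall_accuracy`,
#'   `fold_confusions`, `train_class_counts` (post-SMOTE, per fold),
#'   `config`.
#' @export
run_cv_experiment <- function(table, feature_set = "combined", n_folds = 5L,
                              seed = 0L, smote_k = 5L, svm_cost = 1) {
  cols <- feature_set_columns(feature_set)
  miss <- setdiff(c(cols, "parent_label"), names(table))
  if (length(miss))
    stop_macmot("feature table lacks columns: ", paste(miss, collapse = ", "))
  x <- as.matrix(table[, cols])
  y <- factor(table$parent_label)
  if (any(table(y) < n_folds)) stop_macmot("every class needs >= n_folds cells")
  local_seed(seed, {
    perm <- sample.int(nrow(x))
    x <- x[perm, , drop = FALSE]; y <- y[perm]
    folds <- stratified_folds(y, n_folds)
    conf <- matrix(0L, nlevels(y), nlevels(y),
                   dimnames = list(actual = levels(y), predicted = levels(y)))
    fold_conf <- vector("list", n_folds)
    train_counts <- matrix(0L, n_folds, nlevels(y),
                           dimnames = list(NULL, levels(y)))
    for (f in seq_len(n_folds)) {
      te <- folds == f
      mu <- colMeans(x[!te, , drop = FALSE])
      sg <- apply(x[!te, , drop = FALSE], 2L, sd)
      sg[sg == 0] <- 1
      ztr <- scale(x[!te, , drop = FALSE], mu, sg)
      zte <- scale(x[te, , drop = FALSE], mu, sg)
      bal <- smote_balance(ztr, y[!te], k_neighbors = smote_k)
      train_counts[f, ] <- as.integer(table(bal$y))
      pr <- train_predict_svm(bal$x, bal$y, zte, cost = svm_cost)
      fc <- table(factor(y[te], levels(y)), factor(pr, levels(y)))
      fold_conf[[f]] <- fc
      conf <- conf + fc
    }
    pct <- sweep(conf, 1L, pmax(rowSums(conf), 1L), "/") * 100
    structure(list(
      confusion_counts = conf,
      confusion_pct = pct,
      per_class_accuracy = diag(pct),
      overall_accuracy = sum(diag(conf)) / sum(conf),
      fold_confusions = fold_conf,
      train_class_counts = train_counts,
      config = list(feature_set = feature_set, n_folds = n_folds,
                    seed = seed, smote_k = smote_k, svm_cost = svm_cost,
                    kernel = "radial")
    ), class = "subtype_cv_report")
  })
}

#' @export
print.subtype_cv_report <- function(x, ...) {
  cat(sprintf("subtype_cv_report [%s]: overall accuracy %.1f%%\n",
              x$config$feature_set, 100 * x$overall_accuracy))
  cat("row-normalized confusion (%):\n")
  print(round(x$confusion_pct, 1))
  invisible(x)
}

#' Compare morphology-only, motility-only and combined classifiers
#'
#' Runs [run_cv_experiment()] for the three feature sets over a list of
#' seeds and summarizes overall and per-class accuracy, flagging whether
#' the combined model beats both single-modality models.
#'
#' @param table feature table.
#' @param seeds integer vector of CV seeds.
#' @param ... passed to [run_cv_experiment()].
#' @return List with `results` (one row per seed x feature set),
#'   `summary` (mean and SD of overall accuracy per set),
#'   `n_combined_best` (seeds where combined strictly beats both single
#'   modalities on overall accuracy) and `n_seeds`.
#' @export
compare_feature_sets <- function(table, seeds = 0:9, ...) {
  sets <- c("morphology", "motility", "combined")
  rows <- list()
  for (s in seeds) for (fs in sets) {
    rep <- run_cv_experiment(table, feature_set = fs, seed = s, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s, feature_set = fs,
      overall_accuracy = rep$overall_accuracy,
      t(setNames(rep$per_class_accuracy,
                 paste0("acc_", names(rep$per_class_accuracy)))))
  }
  res <- do.call(rbind, rows)
  wide <- reshape(res[, c("seed", "feature_set", "overall_accuracy")],
                  direction = "wide", idvar = "seed", timevar = "feature_set")
  names(wide) <- sub("overall_accuracy\\.", "", names(wide))
  n_best <- sum(wide$combined > wide$morphology & wide$combined > wide$motility)
  summ <- aggregate(overall_accuracy ~ feature_set, data = res,
                    FUN = function(v) c(mean = mean(v), sd = sd(v)))
  list(results = res, summary = summ,
       n_combined_best = n_best, n_seeds = length(seeds))
}

#' @importFrom stats reshape
NULL
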