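# Quadratic discriminant analysis in (speed, persistence) space: per-class
# Gaussian fits with their own covariance, prediction by maximum
# posterior, evaluated by stratified 5-fold cross-validation. Used to
# quantify how well morphology groups (or parent labels) can be told
# apart from motility alone.

#' Fit a quadratic discriminant model
#'
#' Class-conditional Gaussians with maximum-likelihood mean and covariance
#' (denominator n) and empirical priors. A near-singular class covariance
#' is ridge-regularized by `1e-6 * mean(diag)` on the diagonal and
#' flagged.
#'
#' @param x numeric matrix (n x p) of features.
#' @param y class labels (2 or more classes, >= 3 samples each).
#' @return Object of class `qda_model` with `means`, `covariances`,
#'   `priors`, `classes`, `regularized`.
#' @export
qda_fit <- function(x, y) {
  x <- as.matrix(x)
  y <- factor(y)
  if (any(table(y) < 3L))
    stop_macmot("each class needs at least 3 samples")
  classes <- levels(y)
  reg <- FALSE
  fit1 <- function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xi)
    ctr <- sweep(xi, 2L, mu, "-")
    sig <- crossprod(ctr) / nrow(xi)
    if (rcond(sig) < 1e-10) {
      sig <- sig + diag(1e-6 * mean(diag(sig)) + 1e-12, ncol(sig))
      reg <<- TRUE
    }
    list(mean = mu, cov = sig)
  }
  fits <- lapply(classes, fit1)
  structure(list(
    classes = classes,
    means = lapply(fits, `[[`, "mean"),
    covariances = lapply(fits, `[[`, "cov"),
    priors = as.numeric(table(y) / length(y)),
    regularized = reg
  ), class = "qda_model")
}

#' @rdname qda_fit
#' @param object a `qda_model`.
#' @param newdata matrix of new observations.
#' @param type `"class"` or `"posterior"`.
#' @param ... unused.
#' @export
predict.qda_model <- function(object, newdata, type = c("class", "posterior"),
                              ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  lp <- vapply(seq_along(object$classes), function(i) {
    mu <- object$means[[i]]
    sig <- object$covariances[[i]]
    ch <- chol(sig)
    ctr <- sweep(x, 2L, mu, "-")
    z <- backsolve(ch, t(ctr), transpose = TRUE)
    log(object$priors[i]) - sum(log(diag(ch))) - colSums(z^2) / 2
  }, numeric(nrow(x)))
  lp <- matrix(lp, nrow = nrow(x))
  if (type == "posterior") {
    m <- apply(lp, 1L, max)
    p <- exp(lp - m)
    p <- p / rowSums(p)
    colnames(p) <- object$classes
    return(p)
  }
  factor(object$classes[max.col(lp)], levels = object$classes)
}

# stratified fold assignment: within each class, shuffled indices are
# dealt round-robin so fold class counts differ by at most one
stratified_folds <- function(y, n_folds) {
  y <- factor(y)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Cross-validated QDA accuracy
#'
#' @param x feature matrix.
#' @param y class labels.
#' @param n_folds number of folds (stratified).
#' @param seed integer seed for the fold assignment.
#' @return List with `fold_accuracies`, `mean_accuracy`, `confusion`
#'   (pooled counts, actual x predicted).
#' @export
qda_cv <- function(x, y, n_folds = 5L, seed = 0L) {
  x <- as.matrix(x); y <- factor(y)
  folds <- local_seed(seed, stratified_folds(y, n_folds))
  acc <- numeric(n_folds)
  conf <- matrix(0L, nlevels(y), nlevels(y),
                 dimnames = list(actual = levels(y), predicted = levels(y)))
  for (f in seq_len(n_folds)) {
    te <- folds == f
    fit <- qda_fit(x[!te, , drop = FALSE], y[!te])
    pr <- predict(fit, x[te, , drop = FALSE])
    acc[f] <- mean(pr == y[te])
    conf <- conf + table(factor(y[te], levels(y)), factor(pr, levels(y)))
  }
  list(fold_accuracies = acc, mean_accuracy = mean(acc), confusion = conf)
}

default_group_pairs <- function(groups) {
  g <- groups
  pairs <- list(
    list(a = g[2L], b = g[c(1L, 3L)]),
    list(a = g[1L], b = g[2L]),
    list(a = g[1L], b = g[3L]),
    list(a = g[2L], b = g[3L]),
    list(a = g[c(2L, 3L)], b = g[1L]),
    list(a = g[c(1L, 2L)], b = g[3L])
  )
  pairs
}

#' Pairwise QDA discrimination of cell groups in speed-persistence space
#'
#' For each requested pair of (possibly combined) groups, runs stratified
#' 5-fold cross-validated QDA on the per-cell `(speed, persistence)`
#' scalars and reports the mean accuracy. With `grouping =
#' "cluster_name"`, only the circular / protruded / elongated clusters
#' enter (mixed cells are excluded), and the default pairs are protruded
#' vs circular+elongated, the three single pairs, and the two remaining
#' one-vs-rest combinations.
#'
#' @param table feature table carrying `speed`, `persistence` and the
#'   grouping column.
#' @param grouping `"cluster_name"` or `"parent_label"`.
#' @param pairs list of `list(a = , b = )` character vectors of group
#'   names; `NULL` for the defaults.
#' @param n_folds,seed cross-validation controls.
#' @param min_cells pairs where either side has fewer cells are skipped
#'   with a warning.
#' @return Data frame: one row per pair with sizes, fold accuracies
#'   (list column) and `mean_accuracy`.
#' @export
run_pairwise_discrimination <- function(table,
                                        grouping = c("cluster_name", "parent_label"),
                                        pairs = NULL, n_folds = 5L, seed = 0L,
                                        min_cells = 10L) {
  grouping <- match.arg(grouping)
  need <- c("speed", "persistence", grouping)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop_macmot("missing columns: ", paste(miss, collapse = ", "))
  base_groups <- if (grouping == "cluster_name") {
    c("circular", "protruded", "elongated")
  } else c("M0", "M1", "M2")
  if (is.null(pairs)) pairs <- default_group_pairs(base_groups)
  rows <- list()
  for (i in seq_along(pairs)) {
    pa <- pairs[[i]]
    ia <- table[[grouping]] %in% pa$a
    ib <- table[[grouping]] %in% pa$b
    lab_a <- paste(pa$a, collapse = "+")
    lab_b <- paste(pa$b, collapse = "+")
    if (sum(ia) < min_cells || sum(ib) < min_cells) {
      warning("skipping ", lab_a, " vs ", lab_b, ": group below ",
              min_cells, " cells")
      next
    }
    x <- as.matrix(table[ia | ib, c("speed", "persistence")])
    y <- ifelse(ia[ia | ib], lab_a, lab_b)
    cv <- qda_cv(x, y, n_folds = n_folds, seed = seed + i)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(lab_a, "vs", lab_b),
      n_a = sum(ia), n_b = sum(ib),
      mean_accuracy = cv$mean_accuracy
    )
    rows[[length(rows)]]$fold_accuracies <- I(list(cv$fold_accuracies))
  }
  do.call(rbind, rows)
}
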