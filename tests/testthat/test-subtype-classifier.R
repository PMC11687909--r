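# SMOTE balancing, the RBF SVM and the cross-validated experiment.

test_that("SMOTE balances the reported class counts exactly", {
  set.seed(101)
  x <- matrix(rnorm((200 + 296 + 318) * 3L), ncol = 3L)
  y <- rep(c("M0", "M1", "M2"), c(200L, 296L, 318L))
  bal <- smote_balance(x, y)
  expect_equal(as.integer(table(bal$y)), c(318L, 318L, 318L))
  expect_equal(length(bal$y), 954L)
  expect_equal(nrow(bal$x), 954L)
  # originals preserved verbatim at the head
  expect_identical(bal$x[seq_len(nrow(x)), ], x)
})

test_that("already balanced input is returned unchanged", {
  x <- matrix(rnorm(60), ncol = 2L)
  y <- rep(c("a", "b"), each = 15L)
  bal <- smote_balance(x, y)
  expect_identical(bal$x, x)
  expect_equal(as.character(bal$y), y)
  expect_true(all(bal$n_synthetic == 0L))
})

test_that("every synthetic point lies on a segment between class members", {
  set.seed(102)
  x <- rbind(matrix(rnorm(60), ncol = 2L),              # 30 minority
             matrix(rnorm(160, mean = 5), ncol = 2L))   # 80 majority
  y <- rep(c("min", "maj"), c(30L, 80L))
  bal <- smote_balance(x, y, k_neighbors = 5L)
  syn <- bal$x[bal$y == "min", , drop = FALSE][-(1:30), , drop = FALSE]
  expect_equal(nrow(syn), 50L)
  minority <- x[y == "min", ]
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  for (i in seq_len(nrow(syn))) {
    dmin <- Inf
    for (j in 1:29) for (k in (j + 1):30) {
      dmin <- min(dmin, seg_dist(syn[i, ], minority[j, ], minority[k, ]))
      if (dmin < 1e-9) break
    }
    expect_lt(dmin, 1e-9)
  }
})

test_that("tiny classes reduce k with a warning", {
  x <- rbind(matrix(rnorm(8), ncol = 2L), matrix(rnorm(40), ncol = 2L))
  y <- rep(c("small", "big"), c(4L, 20L))
  set.seed(103)
  expect_warning(bal <- smote_balance(x, y, k_neighbors = 5L), "using k = 3")
  expect_equal(as.integer(table(bal$y)), c(20L, 20L))
})

test_that("the RBF kernel solves what a linear kernel cannot", {
  set.seed(104)
  # XOR pattern
  blk <- function(mx, my) cbind(rnorm(50, mx, 0.5), rnorm(50, my, 0.5))
  xr <- rbind(blk(2, 2), blk(-2, -2), blk(2, -2), blk(-2, 2))
  yr <- rep(c("same", "diff"), each = 100L)
  idx <- sample(length(yr))
  train <- idx[1:140]; test <- idx[141:200]
  pr_rbf <- train_predict_svm(xr[train, ], yr[train], xr[test, ])
  pr_lin <- train_predict_svm(xr[train, ], yr[train], xr[test, ],
                              kernel = "linear")
  expect_gte(mean(pr_rbf == yr[test]), 0.95)
  expect_lte(mean(pr_lin == yr[test]), 0.65)
  # linearly separable three-class toy data: perfect accuracy
  xs <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2L),
              matrix(rnorm(40, 5, 0.2), ncol = 2L),
              matrix(rnorm(40, 10, 0.2), ncol = 2L))
  ys <- rep(c("a", "b", "c"), each = 20L)
  expect_equal(mean(train_predict_svm(xs, ys, xs) == ys), 1)
  expect_error(train_predict_svm(xs[1:20, ], ys[1:20], xs), "single class")
})

test_that("cross-validated experiments are deterministic and bookkeeping is exact", {
  coh <- macrophage_cohort(n_cells = c(M0 = 60, M1 = 80, M2 = 90), seed = 4L)
  r1 <- run_cv_experiment(coh, "combined", seed = 7L)
  r2 <- run_cv_experiment(coh, "combined", seed = 7L)
  expect_identical(r1$confusion_counts, r2$confusion_counts)
  # confusion counts conserve the cohort
  expect_equal(sum(r1$confusion_counts), nrow(coh))
  # per-fold counts sum to fold test sizes, stratified within +-1
  for (f in seq_along(r1$fold_confusions)) {
    rs <- rowSums(r1$fold_confusions[[f]])
    expect_true(all(abs(rs - table(coh$parent_label) / 5) <= 1))
  }
  # rows of the percentage matrix sum to 100
  expect_equal(unname(rowSums(r1$confusion_pct)), rep(100, 3L),
               tolerance = 1e-9)
  # per-class accuracy is the diagonal
  expect_equal(r1$per_class_accuracy, diag(r1$confusion_pct))
  # training folds are balanced to the majority count
  expect_true(all(apply(r1$train_class_counts, 1L,
                        function(r) length(unique(r)) == 1L)))
  # permuted labels: accuracy near 1/3
  set.seed(105)
  perm <- coh
  perm$parent_label <- sample(perm$parent_label)
  rp <- run_cv_experiment(perm, "combined", seed = 7L)
  expect_lt(abs(rp$overall_accuracy - 1 / 3), 0.12)
  expect_error(run_cv_experiment(coh[, -7L], "combined"), "lacks columns")
})

test_that("no training leakage: test rows are never synthetic points", {
  # SMOTE only ever appends to the training matrix; the test fold is the
  # untouched original rows. Verify by checking that fold test sizes sum
  # to the cohort size (no synthetic row is ever scored).
  coh <- macrophage_cohort(n_cells = c(M0 = 40, M1 = 50, M2 = 60), seed = 5L)
  rep <- run_cv_experiment(coh, "motility", seed = 1L)
  expect_equal(sum(vapply(rep$fold_confusions, sum, 0)), nrow(coh))
})

test_that("feature-set comparison flags the combined gain pattern", {
  coh <- macrophage_cohort(n_cells = c(M0 = 120, M1 = 150, M2 = 160), seed = 6L)
  cmp <- compare_feature_sets(coh, seeds = 0:2)
  expect_equal(nrow(cmp$results), 9L)
  expect_true(all(c("morphology", "motility", "combined") %in%
                    cmp$results$feature_set))
  expect_true(cmp$n_combined_best >= 0 && cmp$n_combined_best <= 3L)
  # ablation: motility scrambled -> motility-only collapses toward chance,
  # combined stays near morphology-only
  abl <- coh
  set.seed(106)
  for (cc in c("speed", "persistence", "hull_area"))
    abl[[cc]] <- sample(abl[[cc]])
  r_mot <- run_cv_experiment(abl, "motility", seed = 0L)
  r_mor <- run_cv_experiment(abl, "morphology", seed = 0L)
  r_com <- run_cv_experiment(abl, "combined", seed = 0L)
  expect_lt(r_mot$overall_accuracy, 0.45)
  expect_gt(r_com$overall_accuracy, r_mot$overall_accuracy + 0.05)
  expect_lt(abs(r_com$overall_accuracy - r_mor$overall_accuracy), 0.08)
})

test_that("redundant modalities yield no combined gain", {
  set.seed(107)
  coh <- macrophage_cohort(n_cells = c(M0 = 80, M1 = 90, M2 = 100), seed = 8L)
  red <- coh
  # make motility a deterministic copy of morphology
  red$speed <- red$eccentricity
  red$persistence <- red$compactness
  red$hull_area <- red$cell_size
  r_mor <- run_cv_experiment(red, "morphology", seed = 0L)
  r_com <- run_cv_experiment(red, "combined", seed = 0L)
  expect_lt(abs(r_com$overall_accuracy - r_mor$overall_accuracy), 0.05)
})
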