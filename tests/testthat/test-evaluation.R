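test_that("confusion matrices count label pairs in fixed class order", {
  cm <- confusion_matrix(c("NOR", "GBM", "PCNSL"), c("NOR", "GBM", "PCNSL"))
  expect_identical(unname(diag(cm)), rep(1L, 3))
  expect_identical(sum(cm) - sum(diag(cm)), 0L)
  expect_equal(cm_accuracy(cm), 1)
  # hand-counted toy case
  true <- c("NOR", "NOR", "GBM", "GBM", "PCNSL", "PCNSL")
  pred <- c("NOR", "GBM", "GBM", "GBM", "PCNSL", "NOR")
  cm2 <- confusion_matrix(true, pred)
  expect_identical(sum(diag(cm2)), 4L)
  expect_equal(cm_accuracy(cm2), 0.667, tolerance = 1e-3)
  # partition identity on random labels
  set.seed(1)
  t3 <- sample(tissue_classes(), 100, replace = TRUE)
  p3 <- sample(tissue_classes(), 100, replace = TRUE)
  cm3 <- confusion_matrix(t3, p3)
  expect_identical(as.integer(rowSums(cm3)),
                   as.integer(table(factor(t3, tissue_classes()))))
  expect_identical(sum(cm3), 100L)
  expect_error(confusion_matrix(c("NOR", "XXX"), c("NOR", "NOR")),
               class = "octbrain_label_error")
})

test_that("one-vs-rest sensitivity and specificity collapse correctly", {
  perfect <- confusion_matrix(rep(tissue_classes(), 5),
                              rep(tissue_classes(), 5))
  ss <- sensitivity_specificity(perfect, "GBM")
  expect_equal(ss$sensitivity, 1)
  expect_equal(ss$specificity, 1)
  # hand computation from the collapsed 2x2 of the middle row
  cm <- confusion_matrix(
    rep(tissue_classes(), times = c(10, 10, 10)),
    c(rep("NOR", 8), "GBM", "PCNSL",
      rep("NOR", 2), rep("GBM", 6), rep("PCNSL", 2),
      "NOR", rep("GBM", 2), rep("PCNSL", 7)))
  # collapsed 2x2 for GBM: TP = 6, FN = 4, FP = 1 + 2 = 3, TN = 17
  ss2 <- sensitivity_specificity(cm, "GBM")
  expect_equal(ss2$sensitivity, 0.6)
  expect_equal(ss2$specificity, 17 / 20)
  # absent class: flagged undefined, not silent zero
  cm0 <- confusion_matrix(c("NOR", "GBM"), c("NOR", "GBM"))
  expect_warning(ss0 <- sensitivity_specificity(cm0, "PCNSL"), "undefined")
  expect_true(is.na(ss0$sensitivity))
})

test_that("ROC/AUC equals the pair-counting statistic, ties included", {
  # perfectly separated scores
  r <- roc_auc_ovr(c(0.9, 0.8, 0.2, 0.1), c("GBM", "GBM", "NOR", "NOR"),
                   "GBM")
  expect_equal(r$auc, 1)
  # endpoints always present
  expect_equal(r$sensitivity[1], 0); expect_equal(r$specificity[1], 1)
  expect_equal(r$sensitivity[length(r$sensitivity)], 1)
  expect_equal(r$specificity[length(r$specificity)], 0)
  # brute-force pair-counting oracle on random instances (with heavy ties)
  set.seed(2)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    labs <- sample(c("GBM", "NOR"), n, replace = TRUE,
                   prob = c(0.4, 0.6))
    if (length(unique(labs)) < 2) next
    scores <- round(runif(n), sample(c(1, 2), 1))  # quantized -> ties
    r <- roc_auc_ovr(scores, labs, "GBM")
    expect_equal(r$auc, auc_pair_count(scores, labs == "GBM"),
                 tolerance = 1e-12)
  }
  # curve monotonicity: sensitivity non-decreasing as specificity decreases
  expect_true(all(diff(r$sensitivity) >= 0))
  expect_true(all(diff(r$specificity) <= 0))
  expect_error(roc_auc_ovr(c(0.5, 0.6), c("GBM", "GBM"), "GBM"),
               class = "octbrain_undefined_auc_error")
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(3)
  n <- 2000
  labs <- sample(c("GBM", "NOR"), n, replace = TRUE)
  r <- roc_auc_ovr(runif(n), labs, "GBM")
  expect_equal(r$auc, 0.5, tolerance = 0.03)
})

test_that("our AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  for (rep in 1:5) {
    labs <- sample(c("GBM", "NOR"), 80, replace = TRUE)
    scores <- round(runif(80), 2)
    ours <- roc_auc_ovr(scores, labs, "GBM")$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labs == "GBM", scores,
                                          quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("fold-averaged ROC bands interpolate on the specificity grid", {
  r1 <- roc_auc_ovr(c(0.9, 0.7, 0.4, 0.2), c("GBM", "GBM", "NOR", "NOR"),
                    "GBM")
  single <- average_roc_over_folds(list(r1))
  expect_true(all(single$sd_sensitivity == 0))
  expect_equal(single$auc_mean, r1$auc)
  twin <- average_roc_over_folds(list(r1, r1))
  expect_equal(twin$mean_sensitivity, single$mean_sensitivity)
  expect_true(all(twin$sd_sensitivity == 0))
  # two curves with sensitivities 0.6 and 0.8 at a grid point:
  # mean 0.7, sample sd 0.1414
  ra <- r1; ra$sensitivity <- rep(0.6, length(ra$sensitivity))
  rb <- r1; rb$sensitivity <- rep(0.8, length(rb$sensitivity))
  ab <- average_roc_over_folds(list(ra, rb))
  mid <- which(ab$specificity == 0.5)
  expect_equal(ab$mean_sensitivity[mid], 0.7)
  expect_equal(ab$sd_sensitivity[mid], 0.141421, tolerance = 1e-5)
  expect_error(average_roc_over_folds(list()),
               class = "octbrain_invalid_parameter")
})

test_that("grad-CAM heatmaps are non-negative, normalized and input-sized", {
  m <- build_model(tiny_model_config(), seed = 20)
  set.seed(21)
  frame <- matrix(runif(32 * 48), 32, 48)
  cam <- grad_cam(m, frame, "GBM")
  expect_identical(dim(cam$heatmap), c(32L, 48L))
  expect_gte(min(cam$heatmap), 0)
  expect_lte(max(cam$heatmap), 1)
  expect_identical(dim(cam$overlay), c(32L, 48L, 3L))
  expect_error(grad_cam(m, frame, "XYZ"), class = "octbrain_label_error")
})

test_that("t-SNE preserves well-separated clusters deterministically", {
  set.seed(22)
  n <- 20L
  centers <- matrix(rnorm(3 * 64, sd = 10), 3, 64)
  X <- centers[rep(1:3, each = n), ] + matrix(rnorm(3 * n * 64), 3 * n, 64)
  labs <- rep(tissue_classes(), each = n)
  ep <- tsne_scatter(X, labs, labs, seed = 23, perplexity = 10)
  expect_identical(nrow(ep$coords), 3L * n)
  # same seed twice: identical coordinates
  ep2 <- tsne_scatter(X, labs, labs, seed = 23, perplexity = 10)
  expect_identical(ep$coords, ep2$coords)
  # cluster preservation: silhouette of the 2-d embedding
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(as.integer(factor(labs)), dist(ep$coords))
  expect_gte(mean(sil[, 3]), 0.5)
  expect_error(tsne_embed(X[1:4, ]),
               class = "octbrain_insufficient_points_error")
})

test_that("figure writers produce files", {
  tmp <- tempdir()
  cm <- confusion_matrix(rep(tissue_classes(), 4), rep(tissue_classes(), 4))
  f1 <- file.path(tmp, "cm.png")
  plot_confusion(cm, f1)
  r <- roc_auc_ovr(c(0.9, 0.7, 0.4, 0.2), c("GBM", "GBM", "NOR", "NOR"),
                   "GBM")
  f2 <- file.path(tmp, "roc.png")
  plot_roc_band(average_roc_over_folds(list(r)), "GBM", f2)
  expect_true(all(file.exists(f1, f2)))
  file.remove(f1, f2)
})

test_that("grad-CAM mass concentrates on inclusions versus random regions", {
  # paired comparison on frames of the shared end-to-end run: heatmap mass
  # inside the true inclusion mask vs inside an equal-area random shift of it
  run <- acceptance_pipeline()
  gbm_vols <- run$manifest[run$manifest$label == "GBM", ]
  set.seed(99)
  mass_true <- c(); mass_rand <- c()
  for (i in seq_len(nrow(gbm_vols))) {
    mask <- volume_inclusion_mask("GBM", gbm_vols$seed[i], run$acq,
                                  dilate_px = 0)
    if (!any(mask)) next
    fs <- if (gbm_vols$split_hint[i] == "test") run$test_fs else run$train_fs
    idx <- which(fs$volume_id == gbm_vols$volume_id[i])
    idx <- head(idx, 4)          # a few frames per volume, > 50 in total
    for (j in idx) {
      cam <- grad_cam(run$model, fs$x[, , j], "GBM")
      total <- sum(cam$heatmap)
      if (total == 0) next
      mass_true <- c(mass_true, sum(cam$heatmap[mask]) / total)
      rmask <- shift_frame(mask, sample.int(128, 1), sample.int(256, 1))
      mass_rand <- c(mass_rand, sum(cam$heatmap[rmask]) / total)
    }
  }
  expect_gte(length(mass_true), 50)
  expect_gt(mean(mass_true), mean(mass_rand))
})
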