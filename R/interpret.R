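# Interpretability: grad-CAM heatmaps from the deepest post-attention
# feature map, and t-SNE embeddings of the pooled penultimate features.

#' Grad-CAM heatmap for one frame
#'
#' Channel weights are the spatial means of the target-class logit's
#' gradient with respect to the deepest (64-filter, post-attention) feature
#' map; the heatmap is the ReLU of the weighted channel sum, bilinearly
#' upsampled to the input size and max-normalized to 1 (non-zero maps).
#'
#' @param model an `oct_model` (an untrained model is allowed but logged).
#' @param frame standardized frame (matrix or [bscan_frame()]).
#' @param target_class class whose logit is explained.
#' @return object of class `cam_map`: `heatmap` (input-sized, in `[0, 1]`),
#'   `target_class`, `overlay` (RGB array).
#' @export
grad_cam <- function(model, frame, target_class) {
  if (!isTRUE(model$env$trained))
    log_event("info", "explain", "grad-CAM on an untrained model")
  target_class <- as.character(target_class)
  if (!target_class %in% tissue_classes())
    oct_error("label_error", "unknown class %s", target_class)
  px <- as_pixels(frame)
  fw <- model_forward(model, px, training = FALSE, keep_cache = TRUE)
  dlogits <- matrix(0, 1, model$config$n_classes)
  dlogits[1, match(target_class, tissue_classes())] <- 1
  bw <- model_backward(model, fw$cache, dlogits, capture = "gcam")
  grad <- bw$captured$gcam            # (h, w, C, 1)
  act <- fw$stage_map
  d <- dim(grad)
  wts <- colSums(matrix(grad, d[1] * d[2], d[3])) / (d[1] * d[2])
  cam <- matrix(matrix(act, d[1] * d[2], d[3]) %*% wts, d[1], d[2])
  cam[cam < 0] <- 0
  heat <- resize_bilinear(cam, nrow(px), ncol(px))
  heat[heat < 0] <- 0
  if (max(heat) > 0) heat <- heat / max(heat)
  overlay <- array(0, c(nrow(px), ncol(px), 3))
  overlay[, , 1] <- pmin(1, px + 0.7 * heat)
  overlay[, , 2] <- px * (1 - 0.5 * heat)
  overlay[, , 3] <- px * (1 - 0.5 * heat)
  structure(list(heatmap = heat, target_class = target_class,
                 overlay = overlay), class = "cam_map")
}

# ---- t-SNE (exact, O(n^2); adequate for the few hundred frames used) ----

tsne_p_matrix <- function(X, perplexity) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  target <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:60) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s < 1e-300) { hi <- beta; beta <- (lo + hi) / 2; next }
      p <- p / s
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (hi == 1e20) beta * 2 else (lo + hi) / 2 }
      else { hi <- beta; beta <- (lo + hi) / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Exact t-SNE embedding
#'
#' Deterministic t-SNE: pairwise affinities at the requested perplexity
#' (binary-searched bandwidths), initialization from the first two
#' principal components (sign-fixed), gradient descent with momentum,
#' adaptive gains and early exaggeration.
#'
#' @param X numeric matrix, one row per point.
#' @param perplexity target perplexity (reduced automatically for tiny n).
#' @param seed integer seed (kept for interface stability; the embedding is
#'   deterministic).
#' @param max_iter gradient-descent iterations.
#' @return n x 2 coordinate matrix.
#' @export
tsne_embed <- function(X, perplexity = 30, seed = 1L, max_iter = 350L) {
  n <- nrow(X)
  if (n < 5) oct_error("insufficient_points_error",
                       "t-SNE needs at least 5 points, got %d", n)
  perplexity <- min(perplexity, (n - 1) / 3)
  P <- tsne_p_matrix(X, perplexity)
  pc <- prcomp(X, rank. = 2)$x
  if (ncol(pc) < 2) pc <- cbind(pc, 0)
  # fix PCA sign so the embedding is reproducible across BLAS builds
  for (j in 1:2) if (pc[which.max(abs(pc[, j])), j] < 0) pc[, j] <- -pc[, j]
  Y <- pc / max(stats::sd(pc[, 1]), 1e-12) * 1e-4
  vel <- Y * 0; gains <- Y * 0 + 1
  exag <- 4
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      Pe <- if (it <= 100) P * exag else P
      sq <- rowSums(Y^2)
      num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      G <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (it < 100) 0.5 else 0.8
      gains <- ifelse(sign(G) != sign(vel), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      vel <- mom * vel - 100 * gains * G
      Y <- Y + vel
      Y <- sweep(Y, 2, colMeans(Y))
    }
  })
  Y
}

#' t-SNE scatter of penultimate-layer embeddings
#'
#' @param embeddings n x d feature matrix (see [extract_features()]).
#' @param predicted predicted labels (point colors).
#' @param true true labels (misclassified points are marked).
#' @param split optional per-point `"train"`/`"test"` tags (light/dark
#'   shading).
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity.
#' @return object of class `embedding_plot`: `coords` (n x 2), `predicted`,
#'   `true`, `split`.
#' @export
tsne_scatter <- function(embeddings, predicted, true = predicted,
                         split = NULL, seed = 1L, perplexity = 30) {
  coords <- tsne_embed(as.matrix(embeddings), perplexity = perplexity,
                       seed = seed)
  n <- nrow(coords)
  stopifnot(length(predicted) == n, length(true) == n)
  structure(list(coords = coords,
                 predicted = as_tissue_label(predicted),
                 true = as_tissue_label(true),
                 split = split %||% rep("train", n)),
            class = "embedding_plot")
}

#' @export
print.embedding_plot <- function(x, ...) {
  cat(sprintf("<embedding_plot> %d points, %d misclassified\n",
              nrow(x$coords), sum(x$predicted != x$true)))
  invisible(x)
}

# ---- figure writers ----------------------------------------------------

#' Plot an embedding scatter
#'
#' Colors by predicted class, light (train) vs dark (test) shading, and
#' crosses on misclassified points.
#'
#' @param ep an `embedding_plot`.
#' @param file optional PNG path; when `NULL`, draws on the current device.
#' @return `ep`, invisibly.
#' @export
plot_embedding <- function(ep, file = NULL) {
  if (!is.null(file)) { png(file, 900, 700); on.exit(dev.off()) }
  base <- c(NOR = "#1b9e77", GBM = "#d95f02", PCNSL = "#7570b3")
  light <- c(NOR = "#a6dcc9", GBM = "#f4b183", PCNSL = "#c4c1e0")
  dark_pt <- ep$split == "test"
  col <- ifelse(dark_pt, base[as.character(ep$predicted)],
                light[as.character(ep$predicted)])
  plot(ep$coords, col = col, pch = 16, cex = 0.8,
       xlab = "t-SNE 1", ylab = "t-SNE 2",
       main = "Penultimate-layer features (t-SNE)")
  mis <- ep$predicted != ep$true
  if (any(mis)) points(ep$coords[mis, , drop = FALSE], pch = 4, cex = 1.1)
  legend("topright", bty = "n", pch = 16, col = base,
         legend = names(base))
  invisible(ep)
}

#' Plot a grad-CAM overlay
#' @param cam a `cam_map`.
#' @param file optional PNG path.
#' @return `cam`, invisibly.
#' @export
plot_cam <- function(cam, file = NULL) {
  if (!is.null(file)) { png(file, 800, 420); on.exit(dev.off()) }
  op <- par(mar = c(1, 1, 2, 1)); on.exit(par(op), add = TRUE)
  plot(NULL, xlim = c(0, 1), ylim = c(0, 1), axes = FALSE, xlab = "",
       ylab = "", main = sprintf("grad-CAM (%s)", cam$target_class))
  rasterImage(cam$overlay, 0, 0, 1, 1)
  invisible(cam)
}

#' Plot fold-averaged ROC curves
#' @param avg result of [average_roc_over_folds()].
#' @param label curve label.
#' @param file optional PNG path.
#' @return `avg`, invisibly.
#' @export
plot_roc_band <- function(avg, label = "", file = NULL) {
  if (!is.null(file)) { png(file, 700, 700); on.exit(dev.off()) }
  x <- 1 - avg$specificity
  o <- order(x)
  plot(x[o], avg$mean_sensitivity[o], type = "l", lwd = 2,
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("%s ROC: AUC %.3f +/- %.3f", label, avg$auc_mean,
                      avg$auc_sd))
  lo <- pmax(0, avg$mean_sensitivity - avg$sd_sensitivity)
  hi <- pmin(1, avg$mean_sensitivity + avg$sd_sensitivity)
  polygon(c(x[o], rev(x[o])), c(lo[o], rev(hi[o])), border = NA,
          col = grDevices::adjustcolor("steelblue", 0.3))
  lines(c(0, 1), c(0, 1), lty = 2)
  invisible(avg)
}

#' Plot a confusion matrix heatmap
#' @param cm a [confusion_matrix()].
#' @param file optional PNG path.
#' @return `cm`, invisibly.
#' @export
plot_confusion <- function(cm, file = NULL) {
  if (!is.null(file)) { png(file, 600, 600); on.exit(dev.off()) }
  k <- nrow(cm)
  image(1:k, 1:k, t(cm[k:1, ]), axes = FALSE, col = hcl.colors(32, "Blues 3",
                                                               rev = TRUE),
        xlab = "predicted", ylab = "true", main = "Confusion matrix")
  axis(1, 1:k, colnames(cm)); axis(2, 1:k, rev(rownames(cm)))
  for (i in 1:k) for (j in 1:k)
    text(j, k + 1 - i, cm[i, j],
         col = if (cm[i, j] > max(cm) / 2) "white" else "black")
  invisible(cm)
}
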