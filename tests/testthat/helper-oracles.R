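# Independent oracles used across tests.

# AUC by brute-force pair counting: P(score_pos > score_neg) + ties/2
auc_pair_count <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (s in sp) tot <- tot + sum(s > sn) + 0.5 * sum(s == sn)
  tot / (length(sp) * length(sn))
}

# naive O(n^2) discrete cross-correlation shift estimate (circular)
naive_best_shift <- function(ref, mov, max_shift = 4) {
  best <- c(0, 0); best_v <- -Inf
  for (dz in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    v <- sum(ref * shift_frame(mov, -dz, -dx))
    if (v > best_v) { best_v <- v; best <- c(dz, dx) }
  }
  best
}

small_acq <- function(...) {
  acquisition_spec(n_depth_pixels = 64L, n_lateral_pixels = 96L, ...)
}

small_phantom <- function(label = "NOR", seed = 1L, mu = 2, n_inc = 0L,
                          shape = c(64L, 96L)) {
  build_phantom(phantom_spec(label, mu_base = mu, n_inclusions = n_inc,
                             mu_lateral_variation = if (label == "GBM") 0.4 else 0,
                             inclusion_radius_range = c(0.05, 0.12),
                             seed = seed),
                shape)
}

tiny_model_config <- function(...) {
  model_config(input_shape = c(32L, 48L, 1L), stage_filters = c(3L, 5L, 7L, 9L),
               units_per_stage = c(1L, 2L, 2L, 1L),
               attention_stages = c(7L, 9L), ...)
}

# frame sets of separable random textures for trainer plumbing tests
toy_frame_set <- function(n_per_class, rows = 32L, cols = 48L, seed = 1L,
                          vol_prefix = "V") {
  set.seed(seed)
  n <- n_per_class * 3L
  x <- array(0, c(rows, cols, n))
  labels <- character(n); vols <- character(n)
  depth <- matrix(seq(0, 1, length.out = rows), rows, cols)
  for (i in seq_len(n)) {
    cl <- tissue_classes()[(i - 1) %% 3 + 1]
    base <- switch(cl, NOR = exp(-4 * depth), GBM = exp(-4 * depth) *
                     (1 + 0.5 * sin(seq_len(cols) / 4))[col(depth)] * 0.8,
                   PCNSL = exp(-1.2 * depth))
    img <- base * matrix(rgamma(rows * cols, 8, 8), rows, cols)
    img <- (img - min(img)) / (max(img) - min(img))
    x[, , i] <- img
    labels[i] <- cl
    vols[i] <- sprintf("%s_%s_%d", vol_prefix, cl, (i - 1) %/% 6 + 1)
  }
  frame_set(x, labels, vols, rep(1L, n))
}
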