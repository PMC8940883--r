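# The attention ResNet: a 14-layer pre-activation residual network
# (1 stem conv + 6 residual units x 2 convs + 1 dense = 14 weighted
# layers in the naming convention used here) with multiplicative
# attention gates trunk * (1 + alpha * M), M in [0, 1], on the two
# deepest stages. alpha is a learnable non-negative scalar per gate
# (projected SGD keeps alpha >= 0), so alpha = 0 is exactly a no-op and
# the gates can only rescale features upward.
#
# Forward/backward are written against the Rcpp im2col convolution
# kernels; tensors are R arrays dim (H, W, C, N).

#' Configure the attention ResNet
#'
#' @param input_shape `(rows, cols, channels)` of one standardized frame.
#' @param stage_filters strictly increasing filter counts of the four
#'   stages (default 8, 16, 32, 64).
#' @param units_per_stage residual units per stage, summing to 6
#'   (default 1, 2, 2, 1: depth concentrated at the attention-bearing
#'   stages).
#' @param attention_stages filter counts of the stages that receive an
#'   attention gate (default 32 and 64; empty builds the plain trunk).
#' @param alpha_init initial attention gain (>= 0, default 0).
#' @param n_classes number of classes (fixed at 3 for this problem).
#' @param l2_coefficient L2 penalty on conv and dense kernels.
#' @return an object of class `model_config`.
#' @export
model_config <- function(input_shape = c(128L, 256L, 1L),
                         stage_filters = c(8L, 16L, 32L, 64L),
                         units_per_stage = c(1L, 2L, 2L, 1L),
                         attention_stages = c(32L, 64L),
                         alpha_init = 0,
                         n_classes = 3L,
                         l2_coefficient = 1e-4) {
  if (any(diff(stage_filters) <= 0))
    oct_error("config_error", "stage_filters must be strictly increasing")
  if (length(units_per_stage) != length(stage_filters))
    oct_error("config_error",
              "units_per_stage must match stage_filters in length")
  if (sum(units_per_stage) != 6L)
    oct_error("config_error", "units_per_stage must sum to 6")
  if (!all(attention_stages %in% stage_filters))
    oct_error("config_error",
              "attention_stages must be a subset of stage_filters")
  if (alpha_init < 0)
    oct_error("config_error", "alpha_init must be >= 0")
  if (n_classes != 3L)
    oct_error("config_error", "n_classes is fixed at 3 for this classifier")
  if (l2_coefficient < 0)
    oct_error("config_error", "l2_coefficient must be >= 0")
  structure(list(input_shape = as.integer(input_shape),
                 stage_filters = as.integer(stage_filters),
                 units_per_stage = as.integer(units_per_stage),
                 attention_stages = as.integer(attention_stages),
                 alpha_init = alpha_init, n_classes = as.integer(n_classes),
                 l2_coefficient = l2_coefficient),
            class = "model_config")
}

build_plan <- function(config) {
  plan <- list(list(type = "conv0"))
  cin <- config$stage_filters[1]
  for (s in seq_along(config$stage_filters)) {
    f <- config$stage_filters[s]
    for (u in seq_len(config$units_per_stage[s])) {
      stride <- if (s > 1 && u == 1) 2L else 1L
      plan[[length(plan) + 1L]] <- list(
        type = "unit", pfx = sprintf("s%du%d", s, u), stride = stride,
        cin = cin, cout = f, proj = (stride > 1L || cin != f))
      cin <- f
    }
    if (f %in% config$attention_stages)
      plan[[length(plan) + 1L]] <- list(type = "att",
                                        pfx = sprintf("att%d", f),
                                        c = f, cmid = max(4L, f %/% 4L))
  }
  plan
}

he_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout) * sqrt(2 / (kh * kw * cin)),
        c(kh, kw, cin, cout))
}

#' Build an attention ResNet
#'
#' Initializes all weights deterministically from `seed`: He initialization
#' for convolutions, Glorot for the dense head, unit/zero batch-norm
#' parameters, attention alphas at `alpha_init`, and the *last* convolution
#' of every residual unit at zero, so each unit starts as its shortcut and
#' the network begins training from an identity-like state (the standard
#' zero-init-residual scheme, which markedly speeds early SGD progress at
#' small step budgets).
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `oct_model`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  plan <- build_plan(config)
  params <- list()
  state <- list()
  add_bn <- function(name, c) {
    params[[paste0(name, "_g")]] <<- rep(1, c)
    params[[paste0(name, "_b")]] <<- rep(0, c)
    state[[paste0(name, "_rm")]] <<- rep(0, c)
    state[[paste0(name, "_rv")]] <<- rep(1, c)
  }
  with_seed(seed, {
    for (b in plan) {
      if (b$type == "conv0") {
        params$conv0_w <- he_conv(3, 3, config$input_shape[3],
                                  config$stage_filters[1])
      } else if (b$type == "unit") {
        add_bn(paste0(b$pfx, "_bn1"), b$cin)
        params[[paste0(b$pfx, "_conv1_w")]] <- he_conv(3, 3, b$cin, b$cout)
        add_bn(paste0(b$pfx, "_bn2"), b$cout)
        # zero-init residual: the unit is exactly its shortcut at start
        params[[paste0(b$pfx, "_conv2_w")]] <-
          array(0, c(3, 3, b$cout, b$cout))
        if (b$proj)
          params[[paste0(b$pfx, "_proj_w")]] <- he_conv(1, 1, b$cin, b$cout)
      } else if (b$type == "att") {
        params[[paste0(b$pfx, "_w1")]] <- he_conv(1, 1, b$c, b$cmid)
        params[[paste0(b$pfx, "_w2")]] <- he_conv(1, 1, b$cmid, b$c)
        params[[paste0(b$pfx, "_alpha")]] <- config$alpha_init
      }
    }
    f4 <- config$stage_filters[length(config$stage_filters)]
    add_bn("bnf", f4)
    params$dense_w <- matrix(rnorm(config$n_classes * f4) *
                               sqrt(2 / (f4 + config$n_classes)),
                             config$n_classes, f4)
    params$dense_b <- rep(0, config$n_classes)
  })
  env <- new.env(parent = emptyenv())
  env$params <- params
  env$state <- state
  env$trained <- FALSE
  structure(list(config = config, plan = plan, env = env, seed = seed),
            class = "oct_model")
}

#' @export
print.oct_model <- function(x, ...) {
  cat(sprintf("<oct_model> %s input %s, filters %s, units %s, attention on {%s}, %d parameters%s\n",
              if (x$env$trained) "trained," else "untrained,",
              paste(x$config$input_shape, collapse = "x"),
              paste(x$config$stage_filters, collapse = "/"),
              paste(x$config$units_per_stage, collapse = "/"),
              paste(x$config$attention_stages, collapse = ","),
              model_parameter_count(x),
              sprintf(", alpha = %s",
                      paste(signif(attention_alphas(x), 3), collapse = "/"))))
  invisible(x)
}

#' Total trainable parameter count
#' @param model an `oct_model`.
#' @return integer.
#' @export
model_parameter_count <- function(model) {
  sum(vapply(model$env$params, length, 1L))
}

#' Layer table of the built network
#'
#' One row per weighted layer. The "14-layer" naming convention counts the
#' stem convolution, the two convolutions of each of the six residual
#' units, and the dense classifier; projection shortcuts and
#' attention-branch convolutions are not counted.
#'
#' @param model an `oct_model`.
#' @return data frame with columns layer, kind, shape, params, counted.
#' @export
model_layer_table <- function(model) {
  p <- model$env$params
  rows <- lapply(names(p), function(nm) {
    kind <- if (grepl("conv0_w$|conv[12]_w$", nm)) "conv"
            else if (grepl("proj_w$", nm)) "proj_conv"
            else if (grepl("att.*_w[12]$", nm)) "attention_conv"
            else if (grepl("_g$|_b$", nm) && !grepl("dense", nm)) "batch_norm"
            else if (grepl("alpha$", nm)) "attention_alpha"
            else if (grepl("dense", nm)) "dense"
            else "other"
    data.frame(layer = nm, kind = kind,
               shape = paste(dim(p[[nm]]) %||% length(p[[nm]]),
                             collapse = "x"),
               params = length(p[[nm]]),
               counted = kind %in% c("conv", "dense") &&
                 grepl("_w$", nm) || nm == "dense_w",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Current attention gains
#' @param model an `oct_model`.
#' @return named numeric vector of per-gate alpha values.
#' @export
attention_alphas <- function(model) {
  nm <- grep("_alpha$", names(model$env$params), value = TRUE)
  vapply(stats::setNames(nm, nm), function(n) model$env$params[[n]], 1)
}

#' Fix all attention gains
#' @param model an `oct_model`.
#' @param value non-negative alpha applied to every gate.
#' @return the model (modified by reference), invisibly.
#' @export
set_attention_alpha <- function(model, value) {
  if (value < 0) oct_error("invalid_parameter", "alpha must be >= 0")
  for (n in grep("_alpha$", names(model$env$params), value = TRUE))
    model$env$params[[n]] <- value
  invisible(model)
}

#' Drop the attention gates, keeping trunk weights
#'
#' Builds a plain pre-activation ResNet with no attention branches whose
#' trunk weights are identical to `model`'s (shared copies). Used to verify
#' that the gated model at alpha = 0 is exactly the plain trunk.
#'
#' @param model an `oct_model`.
#' @return an `oct_model` without attention gates.
#' @export
strip_attention <- function(model) {
  cfg <- model$config
  cfg$attention_stages <- integer(0)
  plain <- build_model(cfg, seed = model$seed)
  keep <- !grepl("^att", names(model$env$params))
  plain$env$params <- model$env$params[keep]
  plain$env$state <- model$env$state
  plain$env$trained <- model$env$trained
  plain
}

# ---- forward / backward ------------------------------------------------

# fused batch-norm + ReLU; returns the normalized tensor (for backward),
# the rectified output, and the statistics used
bn_relu <- function(model, name, x, training) {
  p <- model$env$params
  g <- p[[paste0(name, "_g")]]; b <- p[[paste0(name, "_b")]]
  if (training) {
    d <- dim(x); m <- d[1] * d[2] * d[4]
    st0 <- .chan_stats(x)
    mu <- st0$sum / m
    v <- pmax(st0$sumsq / m - mu^2, 0)
    st <- model$env$state
    st[[paste0(name, "_rm")]] <- 0.9 * st[[paste0(name, "_rm")]] + 0.1 * mu
    st[[paste0(name, "_rv")]] <- 0.9 * st[[paste0(name, "_rv")]] + 0.1 * v
    model$env$state <- st
  } else {
    mu <- model$env$state[[paste0(name, "_rm")]]
    v <- model$env$state[[paste0(name, "_rv")]]
  }
  istd <- 1 / sqrt(v + 1e-5)
  ba <- .bn_relu_fw(x, mu, istd, g, b)
  list(xhat = ba$xhat, h = ba$h, istd = istd, training = training)
}

#' Run the network forward
#'
#' @param model an `oct_model`.
#' @param x array `(H, W, N)` or `(H, W, 1, N)` of standardized frames, or a
#'   [frame_set()].
#' @param training if `TRUE`, batch statistics are used (and running
#'   statistics updated); otherwise running statistics.
#' @param keep_cache keep intermediate tensors for [model_backward()].
#' @return list with `logits` and `probs` (`N x 3`), `embedding`
#'   (`N x` last filter count), `stage_map` (the deepest post-attention
#'   feature map), and `cache` when requested.
#' @export
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  if (inherits(x, "frame_set")) x <- x$x
  d <- dim(x)
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3) dim(x) <- c(d[1], d[2], 1L, d[3])
  d <- dim(x)
  ish <- model$config$input_shape
  if (d[1] != ish[1] || d[2] != ish[2] || d[3] != ish[3])
    oct_error("shape_error", "input is %dx%dx%d but the model expects %dx%dx%d",
              d[1], d[2], d[3], ish[1], ish[2], ish[3])
  if (is.double(x)) x <- .to_f32(x)   # activations live in float32

  p <- model$env$params
  caches <- if (keep_cache) vector("list", length(model$plan))
  h <- NULL
  for (i in seq_along(model$plan)) {
    b <- model$plan[[i]]
    if (b$type == "conv0") {
      if (keep_cache) caches[[i]] <- list(x = x)
      h <- .conv2d_fw(x, p$conv0_w, 1L)
    } else if (b$type == "unit") {
      bn1 <- bn_relu(model, paste0(b$pfx, "_bn1"), h, training)
      h1 <- bn1$h
      sc <- if (b$proj) .conv2d_fw(h1, p[[paste0(b$pfx, "_proj_w")]], b$stride)
            else h
      c1 <- .conv2d_fw(h1, p[[paste0(b$pfx, "_conv1_w")]], b$stride)
      bn2 <- bn_relu(model, paste0(b$pfx, "_bn2"), c1, training)
      h2 <- bn2$h
      c2 <- .conv2d_fw(h2, p[[paste0(b$pfx, "_conv2_w")]], 1L)
      if (keep_cache) {
        bn1$h <- NULL; bn2$h <- NULL
        caches[[i]] <- list(bn1 = bn1, h1 = h1, bn2 = bn2, h2 = h2)
      }
      h <- .tensor_add(c2, sc)
    } else if (b$type == "att") {
      alpha <- p[[paste0(b$pfx, "_alpha")]]
      a1 <- .conv2d_fw(h, p[[paste0(b$pfx, "_w1")]], 1L)
      r1 <- .relu_fw(a1)
      a2 <- .conv2d_fw(r1, p[[paste0(b$pfx, "_w2")]], 1L)
      gate <- .att_gate_fw(h, a2, alpha)
      if (keep_cache) caches[[i]] <- list(t = h, r1 = r1, M = gate$M)
      h <- gate$y
    }
  }
  stage_map <- h
  bnf <- bn_relu(model, "bnf", h, training)
  hf <- bnf$h
  df <- dim(hf); hw <- df[1] * df[2]
  emb <- .gap_fw(hf)
  logits <- t(p$dense_w %*% emb + p$dense_b)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  colnames(probs) <- colnames(logits) <- tissue_classes()[seq_len(ncol(probs))]
  out <- list(logits = logits, probs = probs, embedding = t(emb),
              stage_map = .from_f32(stage_map))
  if (keep_cache)
    out$cache <- list(blocks = caches, bnf = bnf, hf = hf, emb = emb,
                      hw = hw, stage_dim = df)
  out
}

#' Backpropagate through the network
#'
#' @param model an `oct_model`.
#' @param cache the cache from [model_forward()] with `keep_cache = TRUE`.
#' @param dlogits `N x n_classes` gradient of the objective with respect to
#'   the logits.
#' @param capture character subset of `c("input", "stem", "gcam")`:
#'   additionally return the gradient at the network input, at the first
#'   residual unit's input, and at the deepest post-attention feature map.
#' @param need_input_grad compute `gx` through the stem convolution.
#' @return list with `grads` (named like the parameters) and `captured`.
#' @export
model_backward <- function(model, cache, dlogits, capture = character(),
                           need_input_grad = FALSE) {
  p <- model$env$params
  grads <- list()
  captured <- list()

  gemb <- t(p$dense_w) %*% t(dlogits)                  # (C, N)
  grads$dense_w <- t(dlogits) %*% t(cache$emb)
  grads$dense_b <- colSums(dlogits)
  hw <- cache$hw
  ghf <- .gap_expand(gemb / hw, cache$hf)
  bnf_bw <- .bn_relu_bw(ghf, cache$hf, cache$bnf$xhat, p$bnf_g,
                        cache$bnf$istd, cache$bnf$training)
  grads$bnf_g <- bnf_bw$ggamma; grads$bnf_b <- bnf_bw$gbeta
  gy <- bnf_bw$gx
  if ("gcam" %in% capture) captured$gcam <- .from_f32(gy)

  for (i in rev(seq_along(model$plan))) {
    b <- model$plan[[i]]
    cc <- cache$blocks[[i]]
    if (b$type == "att") {
      alpha <- p[[paste0(b$pfx, "_alpha")]]
      gb <- .att_gate_bw(gy, cc$t, cc$M, alpha)
      grads[[paste0(b$pfx, "_alpha")]] <- gb$galpha
      bw2 <- .conv2d_bw(cc$r1, p[[paste0(b$pfx, "_w2")]], gb$ga2, 1L)
      grads[[paste0(b$pfx, "_w2")]] <- bw2$gw
      ga1 <- .relu_bw(bw2$gx, cc$r1)
      bw1 <- .conv2d_bw(cc$t, p[[paste0(b$pfx, "_w1")]], ga1, 1L)
      grads[[paste0(b$pfx, "_w1")]] <- bw1$gw
      gy <- .tensor_add(gb$gt, bw1$gx)
    } else if (b$type == "unit") {
      gy_in <- gy                       # skip-path gradient
      bwc2 <- .conv2d_bw(cc$h2, p[[paste0(b$pfx, "_conv2_w")]], gy, 1L)
      grads[[paste0(b$pfx, "_conv2_w")]] <- bwc2$gw
      bn2_bw <- .bn_relu_bw(bwc2$gx, cc$h2, cc$bn2$xhat,
                            p[[paste0(b$pfx, "_bn2_g")]], cc$bn2$istd,
                            cc$bn2$training)
      grads[[paste0(b$pfx, "_bn2_g")]] <- bn2_bw$ggamma
      grads[[paste0(b$pfx, "_bn2_b")]] <- bn2_bw$gbeta
      bwc1 <- .conv2d_bw(cc$h1, p[[paste0(b$pfx, "_conv1_w")]], bn2_bw$gx,
                         b$stride)
      grads[[paste0(b$pfx, "_conv1_w")]] <- bwc1$gw
      gh1 <- bwc1$gx
      if (b$proj) {
        bwp <- .conv2d_bw(cc$h1, p[[paste0(b$pfx, "_proj_w")]], gy_in,
                          b$stride)
        grads[[paste0(b$pfx, "_proj_w")]] <- bwp$gw
        gh1 <- .tensor_add(gh1, bwp$gx)
      }
      bn1_bw <- .bn_relu_bw(gh1, cc$h1, cc$bn1$xhat,
                            p[[paste0(b$pfx, "_bn1_g")]], cc$bn1$istd,
                            cc$bn1$training)
      grads[[paste0(b$pfx, "_bn1_g")]] <- bn1_bw$ggamma
      grads[[paste0(b$pfx, "_bn1_b")]] <- bn1_bw$gbeta
      gy <- bn1_bw$gx
      if (!b$proj) gy <- .tensor_add(gy, gy_in)
    } else if (b$type == "conv0") {
      if ("stem" %in% capture) captured$stem <- .from_f32(gy)
      need_gx <- need_input_grad || "input" %in% capture
      bw0 <- .conv2d_bw(cc$x, p$conv0_w, gy, 1L, need_gx = need_gx)
      grads$conv0_w <- bw0$gw
      if (need_gx) captured$input <- .from_f32(bw0$gx)
      gy <- NULL
    }
  }
  list(grads = grads, captured = captured)
}

#' Class probabilities for a batch of frames
#'
#' @param model an `oct_model`.
#' @param frames a [frame_set()] or `(H, W, N)` array of standardized frames.
#' @param chunk forward batch size.
#' @return `N x 3` probability matrix (rows sum to 1).
#' @export
predict_proba <- function(model, frames, chunk = 32L) {
  x <- if (inherits(frames, "frame_set")) frames$x else frames
  d <- dim(x)
  if (length(d) == 2) dim(x) <- c(d, 1L)
  n <- dim(x)[3]
  out <- matrix(0, n, model$config$n_classes,
                dimnames = list(NULL, tissue_classes()))
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + chunk - 1L)
    out[idx, ] <- model_forward(model, x[, , idx, drop = FALSE])$probs
    at <- at + chunk
  }
  out
}

#' Penultimate-layer embeddings
#'
#' Features at the global average pooling layer (one vector per frame, of
#' length equal to the last stage's filter count), the representation
#' visualized with t-SNE.
#'
#' @inheritParams predict_proba
#' @return `N x 64` matrix (for the default configuration).
#' @export
extract_features <- function(model, frames, chunk = 32L) {
  x <- if (inherits(frames, "frame_set")) frames$x else frames
  d <- dim(x)
  if (length(d) == 2) dim(x) <- c(d, 1L)
  n <- dim(x)[3]
  f4 <- model$config$stage_filters[length(model$config$stage_filters)]
  out <- matrix(0, n, f4)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + chunk - 1L)
    out[idx, ] <- model_forward(model, x[, , idx, drop = FALSE])$embedding
    at <- at + chunk
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a weights file (`.rds`) plus the exact configuration
#' in a JSON sidecar; loading rebuilds the network from the configuration
#' and restores the weights.
#'
#' @param model an `oct_model`.
#' @param path checkpoint path (`.rds`).
#' @return `path` / the restored model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(params = model$env$params, state = model$env$state,
               trained = model$env$trained, seed = model$seed), path)
  cfg <- unclass(model$config)
  jsonlite::write_json(cfg, sub("\\.rds$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  cfgp <- sub("\\.rds$", ".json", path)
  if (!file.exists(cfgp))
    oct_error("metadata_error", "missing model config sidecar: expected %s",
              cfgp)
  cfg <- jsonlite::read_json(cfgp, simplifyVector = TRUE)
  config <- model_config(cfg$input_shape, cfg$stage_filters,
                         cfg$units_per_stage, cfg$attention_stages,
                         cfg$alpha_init, cfg$n_classes, cfg$l2_coefficient)
  blob <- readRDS(path)
  model <- build_model(config, seed = blob$seed %||% 1L)
  model$env$params <- blob$params
  model$env$state <- blob$state
  model$env$trained <- isTRUE(blob$trained)
  model
}
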