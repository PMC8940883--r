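test_that("model configuration invariants are enforced", {
  expect_error(model_config(stage_filters = c(8, 8, 32, 64)),
               class = "octbrain_config_error")
  expect_error(model_config(units_per_stage = c(1, 1, 1, 1)),
               class = "octbrain_config_error")
  expect_error(model_config(attention_stages = c(12)),
               class = "octbrain_config_error")
  expect_error(model_config(n_classes = 2), class = "octbrain_config_error")
  expect_error(model_config(alpha_init = -0.1),
               class = "octbrain_config_error")
})

test_that("the built network has the documented shape and layer count", {
  m <- build_model(model_config(), seed = 1)
  # 1 stem conv + 6 units x 2 convs + 1 dense = 14 counted layers
  tab <- model_layer_table(m)
  n_unit_convs <- sum(tab$kind == "conv" & grepl("conv[12]_w$", tab$layer))
  expect_identical(n_unit_convs, 12L)
  expect_identical(sum(tab$layer == "conv0_w"), 1L)
  expect_identical(sum(tab$layer == "dense_w"), 1L)
  expect_identical(n_unit_convs + 2L, 14L)
  # embedding length equals the last stage filter count (64)
  x <- array(runif(128 * 256 * 2), c(128, 256, 2))
  fw <- model_forward(m, x)
  expect_identical(ncol(fw$embedding), 64L)
  # deepest feature map: input reduced by the three stride-2 stages
  expect_identical(dim(fw$stage_map)[1:3], c(16L, 32L, 64L))
  # identical parameter count across two builds of the same config
  m2 <- build_model(model_config(), seed = 99)
  expect_identical(model_parameter_count(m), model_parameter_count(m2))
})

test_that("stride arithmetic of the convolution kernels", {
  x <- array(rnorm(32 * 64 * 3 * 2), c(32, 64, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 5), c(3, 3, 3, 5))
  expect_identical(dim(octbrain:::.conv2d_fw(x, w, 1L)), c(32L, 64L, 5L, 2L))
  expect_identical(dim(octbrain:::.conv2d_fw(x, w, 2L)), c(16L, 32L, 5L, 2L))
})

test_that("zeroed residual branches make every unit its shortcut exactly", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 3)
  set_attention_alpha(m, 0)
  for (nm in grep("conv2_w$", names(m$env$params), value = TRUE))
    m$env$params[[nm]] <- m$env$params[[nm]] * 0
  x <- array(runif(32 * 48 * 2), c(32, 48, 1, 2))
  got <- model_forward(m, x)$stage_map
  # replicate the pure shortcut chain with the same parameters
  h <- octbrain:::.conv2d_fw(x, m$env$params$conv0_w, 1L)
  for (b in m$plan) {
    if (b$type != "unit") next
    if (b$proj) {
      h1 <- octbrain:::bn_relu(m, paste0(b$pfx, "_bn1"), h, FALSE)$h
      h <- octbrain:::.conv2d_fw(h1, m$env$params[[paste0(b$pfx, "_proj_w")]],
                                 b$stride)
    } # identity shortcut: h unchanged
  }
  expect_equal(got, h, tolerance = 1e-12)
})

test_that("attention gating is a bounded multiplicative gain", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 4)
  # reproduce one gate on a random trunk tensor
  t <- array(rnorm(8 * 12 * 9 * 2), c(8, 12, 9, 2))
  w1 <- m$env$params$att9_w1; w2 <- m$env$params$att9_w2
  r1 <- octbrain:::relu(octbrain:::.conv2d_fw(t, w1, 1L))
  M <- 1 / (1 + exp(-octbrain:::.conv2d_fw(r1, w2, 1L)))
  expect_true(all(M >= 0 & M <= 1))
  for (alpha in c(0, 0.7)) {
    y <- t * (1 + alpha * M)
    expect_identical(dim(y), dim(t))
    expect_true(all(abs(y) >= abs(t) - 1e-12))   # gain factor >= 1
    if (alpha == 0) expect_identical(y, t)
  }
})

test_that("the gated model at alpha 0 equals the attention-free trunk", {
  m <- build_model(tiny_model_config(), seed = 5)
  set_attention_alpha(m, 0)
  plain <- strip_attention(m)
  set.seed(6)
  x <- array(runif(32 * 48 * 8), c(32, 48, 8))
  d <- max(abs(model_forward(m, x)$logits - model_forward(plain, x)$logits))
  expect_lt(d, 1e-6)
  # and alpha > 0 departs from the trunk
  set_attention_alpha(m, 0.5)
  expect_gt(max(abs(model_forward(m, x)$logits -
                      model_forward(plain, x)$logits)), 1e-4)
})

test_that("softmax rows are normalized and inference is deterministic", {
  m <- build_model(tiny_model_config(), seed = 7)
  set.seed(8)
  x <- array(runif(32 * 48 * 5), c(32, 48, 5))
  x[, , 3] <- x[, , 1]                       # duplicated frame
  p <- predict_proba(m, x)
  expect_identical(dim(p), c(5L, 3L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_equal(p[1, ], p[3, ], tolerance = 1e-12)
  e <- extract_features(m, x)
  expect_identical(dim(e), c(5L, 9L))
  expect_true(all(is.finite(e)))
  expect_equal(e[1, ], e[3, ], tolerance = 1e-12)
  expect_error(predict_proba(m, array(0, c(16, 16, 2))),
               class = "octbrain_shape_error")
})

test_that("analytic gradients match finite differences", {
  m <- build_model(tiny_model_config(), seed = 9)
  set_attention_alpha(m, 0.3)
  set.seed(10)
  x <- array(runif(32 * 48 * 3), c(32, 48, 3))
  y <- c(1L, 3L, 2L)
  lossfun <- function() {
    p <- model_forward(m, x)$probs
    mean(-log(pmax(p[cbind(1:3, y)], 1e-12)))
  }
  fw <- model_forward(m, x, keep_cache = TRUE)
  dlog <- (fw$probs - diag(3)[y, ]) / 3
  bw <- model_backward(m, fw$cache, dlog, capture = c("stem", "gcam"))
  # float32 kernels: check at a step large enough to beat rounding noise
  eps <- 1e-3
  set.seed(11)
  for (nm in c("dense_w", "bnf_g", "s4u1_conv1_w", "s2u1_proj_w",
               "att7_alpha", "att9_w1", "s1u1_bn1_b")) {
    p0 <- m$env$params[[nm]]
    i <- sample(length(p0), 1)
    pp <- p0; pp[i] <- p0[i] + eps; m$env$params[[nm]] <- pp; lp <- lossfun()
    pm <- p0; pm[i] <- p0[i] - eps; m$env$params[[nm]] <- pm; lm_ <- lossfun()
    m$env$params[[nm]] <- p0
    fd <- (lp - lm_) / (2 * eps)
    an <- bw$grads[[nm]][i]
    expect_equal(an, fd, tolerance = 0.05,
                 label = sprintf("gradient of %s[%d] (= %g)", nm, i, an),
                 expected.label = sprintf("finite difference %g", fd))
  }
  # gradient flow: non-zero gradient reaches the first unit's input
  expect_gt(max(abs(bw$captured$stem)), 0)
  expect_identical(dim(bw$captured$gcam)[3], 9L)
})

test_that("the network can memorize a small random-labeled set", {
  # capacity smoke test: same architecture, reduced raster, random labels
  cfg <- model_config(input_shape = c(32L, 64L, 1L))
  m <- build_model(cfg, seed = 12)
  set.seed(13)
  n <- 18
  x <- array(runif(32 * 64 * n), c(32, 64, n))
  labs <- sample(tissue_classes(), n, replace = TRUE)
  train <- frame_set(x, labs, sprintf("VT%02d", seq_len(n)), rep(1L, n))
  val <- frame_set(x, labs, sprintf("VV%02d", seq_len(n)), rep(1L, n))
  tc <- train_config(batch_size = 18L, learning_rate = 5e-3,
                     patience_epochs = 200L, max_epochs = 150L, seed = 14,
                     augment = FALSE)
  fit <- train_classifier(m, train, val, tc)
  expect_equal(max(fit$history$val_accuracy), 1)
})

test_that("checkpoints rebuild from config and restore weights", {
  m <- build_model(tiny_model_config(), seed = 15)
  set.seed(16)
  x <- array(runif(32 * 48 * 2), c(32, 48, 2))
  p0 <- predict_proba(m, x)
  path <- file.path(tempdir(), "ckpt.rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict_proba(m2, x), p0, tolerance = 1e-12)
  file.remove(path, sub("\\.rds$", ".json", path))
})
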