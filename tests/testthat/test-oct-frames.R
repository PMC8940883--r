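test_that("volume I/O round-trips pixels and metadata losslessly", {
  acq <- small_acq()
  vol <- render_volume(small_phantom("GBM", seed = 1, n_inc = 3L), acq, 4,
                       seed = 2, metadata = list(volume_id = "VRT",
                                                 patient_id = "P1"))
  path <- file.path(tempdir(), "VRT.tiff")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(back$frames, vol$frames)     # 16-bit values unrescaled
  expect_identical(back$metadata$volume_id, "VRT")
  expect_identical(back$metadata$patient_id, "P1")
  expect_identical(back$metadata$label, "GBM")
  # missing sidecar names the expected file
  file.remove(octbrain:::sidecar_path(path))
  err <- tryCatch(read_volume(path), error = identity)
  expect_s3_class(err, "octbrain_metadata_error")
  expect_match(conditionMessage(err), "VRT.json")
  unlink(path)
})

test_that("registration recovers integer shifts exactly", {
  acq <- small_acq()
  vol <- render_volume(small_phantom("GBM", seed = 3, n_inc = 4L), acq, 1,
                       seed = 5, jitter = 0)
  m <- vol$frames[, , 1]
  expect_identical(register_translation(m, m), c(dz = 0L, dx = 0L))
  expect_identical(register_translation(m, shift_frame(m, 3, -2)),
                   c(dz = 3L, dx = -2L))
  # agrees with the naive exhaustive cross-correlation oracle
  mv <- shift_frame(m, -2, 4)
  expect_identical(unname(register_translation(m, mv)),
                   naive_best_shift(m, mv))
  # exact recovery under additive noise at SNR >= 10, 20 seeded trials
  for (s in 1:20) {
    set.seed(s)
    shift <- sample(-3:3, 2, replace = TRUE)
    sigma <- sd(m) / sqrt(10)
    ref <- m + matrix(rnorm(length(m), sd = sigma), nrow(m))
    mov <- shift_frame(m, shift[1], shift[2]) +
      matrix(rnorm(length(m), sd = sigma), nrow(m))
    expect_identical(unname(register_translation(ref, mov)), shift)
  }
  expect_error(register_translation(m, m[1:10, ]),
               class = "octbrain_geometry_error")
})

test_that("despeckling averages registered windows with the right count", {
  acq <- small_acq()
  vol <- render_volume(small_phantom("NOR", seed = 4), acq, 25, seed = 6)
  out <- despeckle_stack(vol, window = 10, stride = 1)
  expect_length(out, 25 - 10 + 1)
  out3 <- despeckle_stack(vol, window = 10, stride = 3)
  expect_length(out3, (25 - 10) %/% 3 + 1)
  expect_error(despeckle_stack(vol, window = 30),
               class = "octbrain_insufficient_frames")
  # all-identical frames: every output equals the input frame
  same <- vol
  for (i in 2:25) same$frames[, , i] <- same$frames[, , 1]
  outs <- despeckle_stack(same, window = 10)
  expect_equal(outs[[1]]$pixels, same$frames[, , 1])
  expect_equal(outs[[16]]$pixels, same$frames[, , 1])
})

test_that("known integer jitter is removed exactly before averaging", {
  acq <- small_acq()
  vol0 <- render_volume(small_phantom("GBM", seed = 7, n_inc = 4L), acq, 12,
                        seed = 8, jitter = 0)
  volj <- vol0
  set.seed(1)
  jit <- rbind(c(0L, 0L),
               matrix(sample(-3:3, 22, replace = TRUE), 11, 2))
  for (i in 2:12)
    volj$frames[, , i] <- shift_frame(vol0$frames[, , i], jit[i, 1],
                                      jit[i, 2])
  a <- despeckle_stack(vol0, window = 10)
  b <- despeckle_stack(volj, window = 10)
  # each window is aligned to its (jittered) first frame, so the jittered
  # volume's output is the clean output shifted by that frame's jitter
  for (k in seq_along(a))
    expect_equal(b[[k]]$pixels,
                 shift_frame(a[[k]]$pixels, jit[k, 1], jit[k, 2]))
})

test_that("sliding-window averaging divides speckle variance by the window", {
  # i.i.d. unit-shape gamma speckle at flat expected intensity, no jitter
  acq <- acquisition_spec(64L, 128L, speckle_shape = 1, noise_floor = 0)
  ph <- build_phantom(phantom_spec("NOR", mu_base = 1e-9, surface_depth = 0,
                                   seed = 1), c(64L, 128L))
  vol <- render_volume(ph, acq, 100, seed = 11, jitter = 0)
  out <- despeckle_stack(vol, window = 10, stride = 10)
  vin <- var(as.numeric(vol$frames))
  vout <- var(as.numeric(vapply(out, function(f) f$pixels,
                                matrix(0, 64, 128))))
  expect_equal(vin / vout, 10, tolerance = 0.1)
})

test_that("saturation filtering is monotone and keeps clean frames", {
  acq <- small_acq(saturation_probability = 0)
  vol <- render_volume(small_phantom("GBM", seed = 9, n_inc = 4L), acq, 12,
                       seed = 10)
  frames <- despeckle_stack(vol, window = 10)
  expect_length(filter_frames(frames, 0.02), length(frames))
  # inject 5% of columns at max -> score >= 0.05, excluded at the default
  bad <- inject_saturation(frames[[1]], seq_len(ceiling(0.05 * 96)),
                           max_intensity = 65535)
  expect_gte(saturation_score(bad), 0.05)
  expect_length(filter_frames(list(bad), 0.02), 0)
  expect_length(filter_frames(list(bad), 1.0), 1)  # threshold 1 keeps all
  # raising the threshold never decreases the number kept
  mixed <- c(frames[1:3], list(bad))
  kept <- vapply(c(0.001, 0.02, 0.1, 1), function(t)
    length(filter_frames(mixed, t)), 1L)
  expect_true(all(diff(kept) >= 0))
})

test_that("standardization yields 128 x 256 frames in [0, 1]", {
  acq <- small_acq()
  vol <- render_volume(small_phantom("GBM", seed = 12, n_inc = 3L), acq, 10,
                       seed = 13)
  f <- despeckle_stack(vol, window = 10)[[1]]
  s <- standardize(f)
  expect_identical(dim(s$pixels), c(128L, 256L))
  expect_identical(range(s$pixels), c(0, 1))
  # idempotence up to resampling round-off
  s2 <- standardize(s)
  expect_lt(max(abs(s2$pixels - s$pixels)), 1e-6)
  # deeper-than-target frames are cropped to the target depth before resize
  deep <- bscan_frame(rbind(f$pixels, f$pixels), 5.0, 5.0)
  sdeep <- standardize(deep)
  expect_identical(dim(sdeep$pixels), c(128L, 256L))
  # constant frame: all zeros plus a degenerate-frame warning
  flat <- bscan_frame(matrix(3, 64, 96), 2.5, 5)
  expect_warning(sflat <- standardize(flat), "degenerate")
  expect_true(all(sflat$pixels == 0))
})

test_that("augmentation is bounded, seeded and identity at zero magnitude", {
  acq <- small_acq()
  vol <- render_volume(small_phantom("NOR", seed = 14), acq, 10, seed = 15)
  s <- standardize(despeckle_stack(vol, window = 10)[[1]])
  zero <- augment(s, seed = 1, params = list(rotation = 0, translation = 0,
                                             shear = 0, zoom = 0))
  expect_identical(zero$pixels, s$pixels)
  a1 <- augment(s, seed = 33)
  a2 <- augment(s, seed = 33)
  expect_identical(a1$pixels, a2$pixels)
  expect_false(identical(a1$pixels, augment(s, seed = 34)$pixels))
  expect_identical(dim(a1$pixels), dim(s$pixels))
  expect_error(augment(s, seed = 1, params = list(shear = 0.2)),
               class = "octbrain_invalid_parameter")
  expect_error(augment(s, seed = 1, params = list(zoom = 0.11)),
               class = "octbrain_invalid_parameter")
})

test_that("frame sets keep volume bookkeeping through preprocessing", {
  acq <- small_acq()
  vol <- render_volume(small_phantom("PCNSL", seed = 16, mu = 0.8), acq, 12,
                       seed = 17, metadata = list(volume_id = "VBOOK"))
  fs <- preprocess_volume(vol, window = 10, target_rows = 64L,
                          target_cols = 96L)
  expect_identical(unique(fs$volume_id), "VBOOK")
  expect_identical(as.character(unique(fs$labels)), "PCNSL")
  expect_identical(fs$window_start, 1:3)
  sub <- subset_frames(fs, 2)
  expect_identical(n_frames(sub), 1L)
  both <- bind_frames(fs, sub)
  expect_identical(n_frames(both), 4L)
})
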