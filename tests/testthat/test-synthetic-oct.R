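test_that("axial resolution follows the Gaussian coherence-length formula", {
  # 1.31 um center, 100 nm bandwidth: 7.57 um, i.e. ~8 um in air
  expect_equal(axial_resolution(1.31, 100), 7.5727, tolerance = 1e-4)
  expect_equal(round(axial_resolution(1.31, 100)), 8)
  # hand-evaluated second point
  expect_equal(axial_resolution(1.00, 50), 8.8254, tolerance = 1e-4)
  # doubling the bandwidth halves the resolution length
  for (lc in c(0.8, 1.06, 1.31))
    expect_equal(axial_resolution(lc, 160), axial_resolution(lc, 80) / 2)
  expect_error(axial_resolution(-1, 100), class = "octbrain_invalid_parameter")
  expect_error(axial_resolution(1.31, 0), class = "octbrain_invalid_parameter")
})

test_that("phantom specs enforce class-conditional constraints", {
  expect_error(phantom_spec("NOR", mu_base = 2, n_inclusions = 3),
               class = "octbrain_invalid_parameter")
  expect_error(phantom_spec("PCNSL", mu_base = 1, n_inclusions = 1),
               class = "octbrain_invalid_parameter")
  expect_error(phantom_spec("GBM", mu_base = 0),
               class = "octbrain_invalid_parameter")
  expect_error(phantom_spec("GBM", mu_base = 2,
                            inclusion_radius_range = c(0.3, 0.1)),
               class = "octbrain_invalid_parameter")
  # GBM with zero inclusions is allowed (only logged)
  expect_s3_class(phantom_spec("GBM", mu_base = 2, n_inclusions = 0),
                  "phantom_spec")
})

test_that("phantom construction realizes the class signatures", {
  nor <- small_phantom("NOR", seed = 3)
  expect_false(any(nor$inclusion_mask))
  # laterally constant attenuation below the surface
  below <- nor$mu_map[nor$surface_row:nrow(nor$mu_map), ]
  expect_true(all(apply(below, 1, function(r) diff(range(r)) == 0)))

  gbm <- small_phantom("GBM", seed = 5, n_inc = 5L)
  # component-labeling oracle on the generated mask
  lab <- EBImage::bwlabel(gbm$inclusion_mask)
  expect_identical(as.integer(max(lab)), 5L)
  # lateral variation amplitude exceeds the normal (zero) amplitude
  prof <- gbm$mu_map[nrow(gbm$mu_map), ]
  expect_gt(diff(range(prof)) / mean(prof), 0.4)

  pcnsl <- small_phantom("PCNSL", seed = 7, mu = 0.9)
  expect_false(any(pcnsl$inclusion_mask))
})

test_that("PCNSL attenuation range lies strictly below the normal range", {
  d <- class_signature_defaults()
  expect_lt(d$PCNSL$mu_range[2], d$NOR$mu_range[1])
  expect_gt(d$GBM$mu_lateral_variation, d$NOR$mu_lateral_variation)
  mus <- vapply(1:20, function(s) {
    c(random_phantom_spec("PCNSL", s)$mu_base,
      random_phantom_spec("NOR", s)$mu_base)
  }, numeric(2))
  expect_true(all(mus[1, ] < mus[2, ]))
})

test_that("phantoms are deterministic given spec and seed", {
  a <- small_phantom("GBM", seed = 11, n_inc = 4L)
  b <- small_phantom("GBM", seed = 11, n_inc = 4L)
  expect_identical(a, b)
  c2 <- small_phantom("GBM", seed = 12, n_inc = 4L)
  expect_false(identical(a$mu_map, c2$mu_map))
})

test_that("rendering obeys the Beer-Lambert model", {
  acq <- small_acq(noise_floor = 0)
  # mu = 0 (approached by epsilon), constant reflectivity, no speckle/noise:
  # constant A-line below the surface
  ph <- build_phantom(phantom_spec("NOR", mu_base = 1e-9, surface_depth = 0,
                                   seed = 1), c(64L, 96L))
  f <- render_bscan(ph, acq, seed = 1, speckle = FALSE, noise = FALSE)
  expect_lt(diff(range(f$pixels)), 1e-6)

  # homogeneous mu: slope of the depth-averaged log intensity = -2 mu dz
  acq2 <- acquisition_spec(256L, 1200L)
  dz <- acq2$scan_depth / acq2$n_depth_pixels
  for (mu in c(0.5, 2)) {
    ph <- build_phantom(phantom_spec("NOR", mu_base = mu, surface_depth = 0,
                                     seed = 2), c(256L, 1200L))
    fb <- render_bscan(ph, acq2, seed = 5, noise = FALSE)
    ml <- rowMeans(log(fb$pixels))
    slope <- stats::coef(stats::lm(ml ~ seq_along(ml)))[[2]]
    expect_equal(slope, -2 * mu * dz, tolerance = 0.05)
  }
})

test_that("speckle statistics match the gamma model", {
  # coefficient of variation at fixed expected intensity is 1/sqrt(k)
  acq <- acquisition_spec(256L, 512L, speckle_shape = 4, noise_floor = 0)
  ph <- build_phantom(phantom_spec("NOR", mu_base = 1e-9, surface_depth = 0,
                                   seed = 1), c(256L, 512L))
  f <- render_bscan(ph, acq, seed = 3, noise = FALSE)
  cv <- sd(f$pixels) / mean(f$pixels)
  expect_equal(cv, 1 / sqrt(4), tolerance = 0.05)
})

test_that("GBM inclusions are darker than surrounding tissue", {
  acq <- small_acq()
  gbm <- small_phantom("GBM", seed = 5, n_inc = 5L)
  f <- render_bscan(gbm, acq, seed = 2)
  mask <- gbm$inclusion_mask
  rows_with <- unique(which(mask, arr.ind = TRUE)[, 1])
  band <- matrix(FALSE, nrow(mask), ncol(mask))
  band[rows_with, ] <- TRUE
  expect_lt(mean(f$pixels[mask]), mean(f$pixels[band & !mask]))
})

test_that("render_volume honors frame count, metadata and saturation flags", {
  acq <- small_acq(saturation_probability = 0)
  ph <- small_phantom("NOR", seed = 2)
  expect_error(render_volume(ph, acq, 0), class = "octbrain_invalid_parameter")
  vol <- render_volume(ph, acq, 16, seed = 4,
                       metadata = list(volume_id = "V16"))
  expect_identical(dim(vol$frames)[3], 16L)
  expect_identical(vol$metadata$volume_id, "V16")
  expect_identical(vol$metadata$label, "NOR")
  expect_identical(vol$metadata$seed, 4L)
  # saturation_probability = 0: the detector flags nothing
  flags <- apply(vol$frames, 3, function(m) saturation_score(m) >= 0.02)
  expect_false(any(flags))
  # saturation_probability = 1: every frame flagged
  acq1 <- small_acq(saturation_probability = 1)
  vol1 <- render_volume(ph, acq1, 8, seed = 4)
  flags1 <- apply(vol1$frames, 3, function(m) saturation_score(m) >= 0.02)
  expect_true(all(flags1))
})

test_that("saturation injection sets columns to the maximum intensity", {
  acq <- small_acq()
  ph <- small_phantom("NOR", seed = 9)
  vol <- render_volume(ph, acq, 1, seed = 1)
  f <- bscan_frame(vol$frames[, , 1], 2.5, 5)
  expect_identical(inject_saturation(f, integer(0)), f)
  fi <- inject_saturation(f, c(4L, 10L), max_intensity = 65535)
  expect_equal(mean(fi$pixels[, 4]), 65535)
  expect_gt(saturation_score(fi), saturation_score(f))
  expect_error(inject_saturation(f, 5000L), class = "octbrain_index_error")
})

test_that("generate_dataset writes a consistent, reproducible manifest", {
  acq <- small_acq()
  d1 <- file.path(tempdir(), "ds_a")
  man <- generate_dataset(d1, train_volumes = c(NOR = 2, GBM = 3, PCNSL = 3),
                          test_volumes = c(NOR = 0, GBM = 0, PCNSL = 0),
                          frames_per_volume = 3L, acq = acq, seed = 21)
  expect_identical(nrow(man), 8L)
  expect_identical(as.integer(table(man$label)[tissue_classes()]),
                   c(2L, 3L, 3L))
  expect_false(any(duplicated(man$volume_id)))
  expect_true(all(file.exists(man$path)))
  expect_true(all(file.exists(sub("\\.tiff$", ".json", man$path))))

  # regeneration with the same seed is byte-identical
  d2 <- file.path(tempdir(), "ds_b")
  man2 <- generate_dataset(d2, train_volumes = c(NOR = 2, GBM = 3, PCNSL = 3),
                           test_volumes = c(NOR = 0, GBM = 0, PCNSL = 0),
                           frames_per_volume = 3L, acq = acq, seed = 21)
  for (i in seq_len(nrow(man)))
    expect_identical(readBin(man$path[i], "raw", file.size(man$path[i])),
                     readBin(man2$path[i], "raw", file.size(man2$path[i])))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the study volume layout yields 38 manifest rows (15/10/5 + 2/3/3)", {
  acq <- acquisition_spec(n_depth_pixels = 16L, n_lateral_pixels = 24L)
  d <- file.path(tempdir(), "ds_layout")
  man <- generate_dataset(d, frames_per_volume = 1L, acq = acq, seed = 3)
  expect_identical(nrow(man), 38L)
  expect_identical(sum(man$split_hint == "train"), 30L)
  expect_identical(as.integer(table(man$label[man$split_hint == "test"])[
    tissue_classes()]), c(2L, 3L, 3L))
  unlink(d, recursive = TRUE)
})
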