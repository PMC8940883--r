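# Preprocessing: translational registration, 10-frame averaging despeckle,
# saturation-frame exclusion, standardization to 128 x 256 in [0, 1], and
# bounded affine augmentation.

#' Circularly shift a frame by integer pixels
#'
#' `shift_frame(m, dz, dx)` moves content down by `dz` rows and right by
#' `dx` columns with wraparound; `shift_frame(., -dz, -dx)` inverts it
#' exactly.
#'
#' @param m matrix.
#' @param dz,dx integer shifts (rows, columns).
#' @return the shifted matrix.
#' @export
shift_frame <- function(m, dz, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1 - dz) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dx) %% nc) + 1
  m[ri, ci, drop = FALSE]
}

#' Estimate the integer translation between two frames
#'
#' Returns the integer `(dz, dx)` maximizing the circular cross-correlation
#' (computed by FFT), such that `moving == shift_frame(reference, dz, dx)`
#' for a pure shift; applying `(-dz, -dx)` to `moving` aligns it to
#' `reference`.
#'
#' @param reference,moving equal-shaped matrices or [bscan_frame()]s.
#' @return integer vector `c(dz, dx)`.
#' @export
register_translation <- function(reference, moving) {
  a <- as_pixels(reference); b <- as_pixels(moving)
  if (!all(dim(a) == dim(b)))
    oct_error("geometry_error", "frames must share one shape")
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE))
  idx <- which.max(cc)
  nr <- nrow(a)
  dz <- (idx - 1) %% nr
  dx <- (idx - 1) %/% nr
  if (dz > nr / 2) dz <- dz - nr
  if (dx > ncol(a) / 2) dx <- dx - ncol(a)
  c(dz = as.integer(dz), dx = as.integer(dx))
}

#' Despeckle a volume by registered sliding-window averaging
#'
#' Each output frame is the pixel-wise mean of `window` consecutive B-scans,
#' every frame registered (integer-pixel translation) to the first frame of
#' its window before averaging. With stride `s` the output count is
#' `floor((N - window) / s) + 1`.
#'
#' @param volume an `oct_volume`.
#' @param window number of adjacent B-scans to average (default 10).
#' @param stride window stride (default 1; the sliding window is what
#'   reproduces the frame counts reported for 1000-B-scan volumes).
#' @return list of [bscan_frame()]s, each carrying `window_start` and
#'   `volume_id` attributes.
#' @export
despeckle_stack <- function(volume, window = 10L, stride = 1L) {
  stopifnot(inherits(volume, "oct_volume"))
  n <- dim(volume$frames)[3]
  window <- as.integer(window); stride <- as.integer(stride)
  if (n < window)
    oct_error("insufficient_frames",
              "volume has %d frames but the despeckle window is %d", n, window)
  meta <- volume$metadata
  depth_extent <- (meta$pixel_pitch_axial %||%
                     (2.5 / dim(volume$frames)[1])) * dim(volume$frames)[1]
  lateral_extent <- (meta$pixel_pitch_lateral %||%
                       (5 / dim(volume$frames)[2])) * dim(volume$frames)[2]

  # register every frame once against frame 1; per-window alignment to the
  # window's first frame then uses exact shift differences (circular shifts
  # compose exactly). The reference FFT is computed once.
  shifts <- matrix(0L, n, 2)
  ref_fft <- Conj(fft(volume$frames[, , 1]))
  nr <- dim(volume$frames)[1]; nc <- dim(volume$frames)[2]
  for (i in seq_len(n)[-1]) {
    cc <- Re(fft(ref_fft * fft(volume$frames[, , i]), inverse = TRUE))
    idx <- which.max(cc)
    dz <- (idx - 1) %% nr
    dx <- (idx - 1) %/% nr
    if (dz > nr / 2) dz <- dz - nr
    if (dx > nc / 2) dx <- dx - nc
    shifts[i, ] <- c(dz, dx)
  }

  starts <- seq(1L, n - window + 1L, by = stride)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    acc <- volume$frames[, , s]
    for (j in seq(s + 1L, length.out = window - 1L)) {
      rel <- shifts[j, ] - shifts[s, ]
      acc <- acc + shift_frame(volume$frames[, , j], -rel[1], -rel[2])
    }
    f <- bscan_frame(acc / window, depth_extent, lateral_extent)
    attr(f, "window_start") <- s
    attr(f, "volume_id") <- meta$volume_id %||% NA_character_
    attr(f, "label") <- meta$label %||% NA_character_
    out[[k]] <- f
  }
  out
}

#' Saturation score of a frame
#'
#' Fraction of columns that are bright at every depth: a column is flagged
#' when its minimum intensity over depth exceeds half the frame maximum.
#' Saturation stripes from specular reflections are near the maximum
#' representable intensity along the whole depth, whereas tissue columns
#' always decay toward the noise floor, so the statistic needs no global
#' calibration and is insensitive to the lateral attenuation structure that
#' characterizes tumor tissue.
#'
#' @param frame a [bscan_frame()] or matrix.
#' @return score in `[0, 1]`.
#' @export
saturation_score <- function(frame) {
  px <- as_pixels(frame)
  mx <- max(px)
  if (mx <= 0) return(0)
  col_min <- apply(px, 2, min)
  mean(col_min > 0.5 * mx)
}

#' Exclude saturated frames
#'
#' Keeps frames whose [saturation_score()] is strictly below `threshold`
#' and logs every exclusion.
#'
#' @param frames list of frames.
#' @param threshold exclusion threshold on the score (default 0.02, i.e. a
#'   frame is dropped when more than 2 percent of its columns are flagged);
#'   `threshold >= 1` keeps every frame.
#' @return the kept frames.
#' @export
filter_frames <- function(frames, threshold = 0.02) {
  scores <- vapply(frames, saturation_score, numeric(1))
  keep <- if (threshold >= 1) rep(TRUE, length(frames)) else scores < threshold
  if (any(!keep))
    log_event("info", "preprocess", "excluded %d/%d frames (saturation)",
              sum(!keep), length(frames))
  if (!any(keep) && length(frames) > 0)
    log_event("warning", "preprocess",
              "all %d frames excluded by the saturation filter", length(frames))
  frames[keep]
}

resize_bilinear <- function(m, rows, cols) {
  # antialias only when downsampling: on upsampling EBImage's antialias
  # filter samples past the border and darkens the frame edge
  aa <- rows <= nrow(m) && cols <= ncol(m)
  out <- EBImage::resize(m, w = rows, h = cols, filter = "bilinear",
                         antialias = aa)
  matrix(as.numeric(out), rows, cols)
}

#' Standardize a frame for the classifier
#'
#' Crops or zero-pads the depth axis to `target_depth` mm when the frame's
#' depth extent differs, resamples to exactly `target_rows x target_cols`
#' (bilinear, anti-aliased), and min-max normalizes to `[0, 1]`. A constant
#' frame yields all zeros with a degenerate-frame warning.
#'
#' @param frame a [bscan_frame()].
#' @param target_rows,target_cols output raster size (128 x 256).
#' @param target_depth physical depth of the standardized frame, mm.
#' @return a standardized [bscan_frame()] (attributes of the input frame
#'   are preserved).
#' @export
standardize <- function(frame, target_rows = 128L, target_cols = 256L,
                        target_depth = 2.5) {
  stopifnot(inherits(frame, "bscan_frame"))
  px <- frame$pixels
  if (length(px) == 0) oct_error("invalid_parameter", "empty frame")
  dz <- frame$depth_extent / nrow(px)
  if (abs(frame$depth_extent - target_depth) > 1e-9) {
    n_keep <- max(1L, as.integer(round(target_depth / dz)))
    if (n_keep <= nrow(px)) {
      px <- px[seq_len(n_keep), , drop = FALSE]
    } else {
      px <- rbind(px, matrix(0, n_keep - nrow(px), ncol(px)))
    }
  }
  if (nrow(px) != target_rows || ncol(px) != target_cols)
    px <- resize_bilinear(px, target_rows, target_cols)
  rng <- range(px)
  if (diff(rng) == 0) {
    log_event("warning", "preprocess", "degenerate constant frame standardized to zeros")
    px <- matrix(0, target_rows, target_cols)
  } else {
    px <- (px - rng[1]) / diff(rng)
  }
  out <- frame
  out$pixels <- px
  out$depth_extent <- target_depth
  out
}

# inverse-mapped bilinear affine warp about the frame center; zero outside
warp_affine <- function(m, A, t_px) {
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  R0 <- matrix(seq_len(nr) - cr, nr, nc)
  C0 <- matrix(seq_len(nc) - cc, nr, nc, byrow = TRUE)
  Ai <- solve(A)
  r1 <- R0 - t_px[1]; c1 <- C0 - t_px[2]
  sr <- Ai[1, 1] * r1 + Ai[1, 2] * c1 + cr
  sc <- Ai[2, 1] * r1 + Ai[2, 2] * c1 + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  get_px <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * get_px(r0, c0) +
    (1 - fr) * fc * get_px(r0, c0 + 1) +
    fr * (1 - fc) * get_px(r0 + 1, c0) +
    fr * fc * get_px(r0 + 1, c0 + 1)
  matrix(v, nr, nc)
}

#' Default augmentation bounds
#'
#' Shear and zoom are hard-capped at a ratio of 0.1 to preserve the
#' morphological features the classifier relies on; rotation and
#' translation default to +/-10 degrees and +/-5 percent of the frame
#' extent.
#'
#' @return named list of bounds.
#' @export
augment_params <- function() {
  list(rotation = 10, translation = 0.05, shear = 0.1, zoom = 0.1)
}

.AUG_HARD_CAP <- 0.1

#' Randomly augment a standardized frame
#'
#' Applies a random affine transform (rotation, translation, shear, zoom)
#' with magnitudes drawn uniformly within `params`; shear and zoom bounds
#' above the hard cap of 0.1 are rejected. Deterministic given `seed`; all
#' zero bounds return the input unchanged.
#'
#' @param frame standardized [bscan_frame()] (or matrix).
#' @param seed integer seed.
#' @param params bounds, see [augment_params()].
#' @return augmented frame of the same shape.
#' @export
augment <- function(frame, seed, params = augment_params()) {
  p <- utils::modifyList(augment_params(), params)
  if (p$shear > .AUG_HARD_CAP + 1e-12 || p$zoom > .AUG_HARD_CAP + 1e-12)
    oct_error("invalid_parameter",
              "shear and zoom ratios are capped at 0.1 (got shear=%g, zoom=%g)",
              p$shear, p$zoom)
  px <- as_pixels(frame)
  out <- with_seed(seed, {
    theta <- runif(1, -p$rotation, p$rotation) * pi / 180
    tr <- runif(2, -p$translation, p$translation) * dim(px)
    sh <- runif(1, -p$shear, p$shear)
    zm <- 1 + runif(1, -p$zoom, p$zoom)
    if (theta == 0 && all(tr == 0) && sh == 0 && zm == 1) px
    else {
      Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      Sh <- matrix(c(1, 0, sh, 1), 2, 2)
      A <- (Rm %*% Sh) * zm
      warp_affine(px, A, tr)
    }
  })
  if (inherits(frame, "bscan_frame")) { frame$pixels <- out; frame } else out
}

# ---- frame sets --------------------------------------------------------

#' Bundle standardized frames into a frame set
#'
#' A frame set is the in-memory dataset handed to the classifier: a
#' `(rows, cols, n)` array of standardized frames plus per-frame label,
#' source volume id and despeckle window start (the volume id bookkeeping
#' is what the volume-wise leakage guarantee is asserted on).
#'
#' @param frames list of standardized [bscan_frame()]s carrying `volume_id`,
#'   `label` and `window_start` attributes, or a 3-d array.
#' @param labels,volume_id,window_start per-frame metadata (required when
#'   `frames` is an array).
#' @return an object of class `frame_set`.
#' @export
frame_set <- function(frames, labels = NULL, volume_id = NULL,
                      window_start = NULL) {
  if (is.list(frames)) {
    labels <- labels %||% vapply(frames, function(f) attr(f, "label"), "")
    volume_id <- volume_id %||%
      vapply(frames, function(f) attr(f, "volume_id"), "")
    window_start <- window_start %||%
      vapply(frames, function(f) as.integer(attr(f, "window_start") %||% NA),
             1L)
    d <- dim(frames[[1]]$pixels)
    x <- array(0, c(d, length(frames)))
    for (i in seq_along(frames)) x[, , i] <- frames[[i]]$pixels
  } else {
    x <- frames
  }
  n <- dim(x)[3]
  stopifnot(length(labels) == n, length(volume_id) == n)
  structure(list(x = x, labels = as_tissue_label(labels),
                 volume_id = as.character(volume_id),
                 window_start = as.integer(window_start %||% rep(NA, n))),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames (%d x %d), %d volumes: %s\n",
              dim(x$x)[3], dim(x$x)[1], dim(x$x)[2],
              length(unique(x$volume_id)),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}

#' Number of frames in a frame set
#' @param fs a [frame_set()].
#' @return integer count.
#' @export
n_frames <- function(fs) dim(fs$x)[3]

#' Subset a frame set
#' @param fs a [frame_set()].
#' @param idx integer or logical index over frames.
#' @return a [frame_set()].
#' @export
subset_frames <- function(fs, idx) {
  frame_set(fs$x[, , idx, drop = FALSE], fs$labels[idx], fs$volume_id[idx],
            fs$window_start[idx])
}

#' Concatenate frame sets
#' @param ... [frame_set()]s with equal frame shape.
#' @return a [frame_set()].
#' @export
bind_frames <- function(...) {
  sets <- list(...)
  x <- array(0, c(dim(sets[[1]]$x)[1:2], sum(vapply(sets, n_frames, 1L))))
  at <- 0L
  for (s in sets) {
    n <- n_frames(s)
    if (n > 0) x[, , at + seq_len(n)] <- s$x
    at <- at + n
  }
  frame_set(x, unlist(lapply(sets, function(s) as.character(s$labels))),
            unlist(lapply(sets, function(s) s$volume_id)),
            unlist(lapply(sets, function(s) s$window_start)))
}

#' Preprocess one volume into standardized frames
#'
#' Despeckles by registered `window`-frame averaging, excludes saturated
#' despeckled frames, and standardizes the survivors to
#' `target_rows x target_cols` in `[0, 1]`.
#'
#' @param volume an `oct_volume`.
#' @inheritParams despeckle_stack
#' @param sat_threshold see [filter_frames()].
#' @param target_rows,target_cols see [standardize()].
#' @return a [frame_set()] (possibly empty).
#' @export
preprocess_volume <- function(volume, window = 10L, stride = 1L,
                              sat_threshold = 0.02,
                              target_rows = 128L, target_cols = 256L) {
  frames <- despeckle_stack(volume, window, stride)
  frames <- filter_frames(frames, sat_threshold)
  if (length(frames) == 0)
    return(frame_set(array(0, c(target_rows, target_cols, 0)),
                     character(0), character(0), integer(0)))
  frames <- lapply(frames, standardize, target_rows = target_rows,
                   target_cols = target_cols)
  frame_set(frames)
}

#' Preprocess every volume of a manifest
#'
#' @param manifest data frame from [generate_dataset()] (columns volume_id,
#'   label, path, split_hint).
#' @param split optional value of `split_hint` to restrict to.
#' @inheritParams preprocess_volume
#' @return a [frame_set()] pooling all kept frames.
#' @export
preprocess_manifest <- function(manifest, split = NULL, window = 10L,
                                stride = 1L, sat_threshold = 0.02,
                                target_rows = 128L, target_cols = 256L) {
  if (!is.null(split)) manifest <- manifest[manifest$split_hint == split, ]
  sets <- lapply(seq_len(nrow(manifest)), function(i) {
    vol <- read_volume(manifest$path[i])
    preprocess_volume(vol, window, stride, sat_threshold,
                      target_rows, target_cols)
  })
  do.call(bind_frames, sets)
}
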