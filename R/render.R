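# Single-scattering Beer-Lambert rendering of B-scans from tissue phantoms.
# Expected intensity at depth row z, lateral column x is
#   reflectivity(z, x) * exp(-2 * sum_{z' <= z} mu(z', x) * dz)
# (round-trip factor 2), multiplied by unit-mean gamma speckle and with an
# additive exponential noise floor. No confocal/roll-off function is
# modelled.

#' Construct a B-scan frame
#'
#' @param pixels numeric matrix, depth rows x lateral columns, finite and
#'   non-negative.
#' @param depth_extent,lateral_extent physical extents, mm.
#' @return an object of class `bscan_frame`.
#' @export
bscan_frame <- function(pixels, depth_extent, lateral_extent) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    oct_error("invalid_parameter", "pixels must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    oct_error("invalid_parameter", "pixels must be finite and >= 0")
  structure(list(pixels = pixels, depth_extent = depth_extent,
                 lateral_extent = lateral_extent),
            class = "bscan_frame")
}

as_pixels <- function(x) {
  if (inherits(x, "bscan_frame")) x$pixels else if (is.matrix(x)) x
  else oct_error("invalid_parameter", "expected a bscan_frame or a matrix")
}

#' @export
print.bscan_frame <- function(x, ...) {
  cat(sprintf("<bscan_frame> %d x %d px, %.2f x %.2f mm, range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), x$depth_extent,
              x$lateral_extent, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Render one synthetic B-scan
#'
#' @param phantom a [build_phantom()] result whose raster matches the
#'   acquisition geometry.
#' @param acq an [acquisition_spec()].
#' @param seed integer seed for speckle and noise.
#' @param speckle,noise logical switches (useful for physics tests).
#' @return a [bscan_frame()] of continuous linear intensities.
#' @export
render_bscan <- function(phantom, acq, seed = 1L, speckle = TRUE, noise = TRUE) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(acq, "acquisition_spec"))
  dmu <- dim(phantom$mu_map)
  if (dmu[1] != acq$n_depth_pixels || dmu[2] != acq$n_lateral_pixels)
    oct_error("geometry_error",
              "phantom raster %d x %d does not match acquisition %d x %d",
              dmu[1], dmu[2], acq$n_depth_pixels, acq$n_lateral_pixels)
  dz <- acq$scan_depth / acq$n_depth_pixels
  transmission <- exp(-2 * dz * apply(phantom$mu_map, 2, cumsum))
  iexp <- phantom$reflectivity_map * transmission
  with_seed(seed, {
    img <- iexp
    if (speckle)
      img <- img * matrix(rgamma(length(img), shape = acq$speckle_shape,
                                 rate = acq$speckle_shape), dmu[1], dmu[2])
    if (noise)
      img <- img + acq$noise_floor * matrix(rexp(length(img)), dmu[1], dmu[2])
    bscan_frame(img, acq$scan_depth, acq$scan_width)
  })
}

#' Inject saturation stripes into a frame
#'
#' Sets the listed columns to the frame's maximum representable intensity
#' at every depth, mimicking the straight striped lines caused by strong
#' specular reflections.
#'
#' @param frame a [bscan_frame()].
#' @param columns integer column indices (1-based).
#' @param max_intensity saturation value; defaults to the frame's
#'   `max_intensity` attribute (set for digitized frames) or the current
#'   maximum.
#' @return the modified frame.
#' @export
inject_saturation <- function(frame, columns, max_intensity = NULL) {
  px <- as_pixels(frame)
  columns <- as.integer(columns)
  if (length(columns) == 0) return(frame)
  if (any(columns < 1 | columns > ncol(px)))
    oct_error("index_error", "saturation column out of range 1..%d", ncol(px))
  mx <- max_intensity %||% attr(frame, "max_intensity") %||% max(px)
  px[, columns] <- mx
  if (inherits(frame, "bscan_frame")) frame$pixels <- px else frame <- px
  frame
}

# digitize a continuous frame to 16-bit counts
digitize16 <- function(pixels, gain = 2e4) {
  pmin(round(gain * pixels), 65535)
}

#' Render a synthetic OCT volume
#'
#' Renders `n_frames` B-scans of one phantom with independent speckle
#' realizations, small integer-pixel inter-frame translations (uniform in
#' \[-3, 3\] px on both axes, circular, exactly recoverable by
#' registration), 16-bit digitization, and saturation stripes injected per
#' frame with probability `acq$saturation_probability`.
#'
#' @param phantom a [build_phantom()] result.
#' @param acq an [acquisition_spec()].
#' @param n_frames number of B-scans (>= 1).
#' @param seed integer seed.
#' @param metadata optional named list merged into the volume metadata
#'   (volume_id, patient_id, specimen_id, ...).
#' @param jitter maximum absolute inter-frame shift in px.
#' @return an object of class `oct_volume`: a (depth, lateral, frame) array
#'   of 16-bit counts plus metadata.
#' @export
render_volume <- function(phantom, acq, n_frames, seed = 1L,
                          metadata = list(), jitter = 3L) {
  if (n_frames < 1)
    oct_error("invalid_parameter", "n_frames must be >= 1")
  n_frames <- as.integer(n_frames)
  H <- acq$n_depth_pixels; W <- acq$n_lateral_pixels
  frames <- array(0, c(H, W, n_frames))
  shifts <- matrix(0L, n_frames, 2)
  sat <- logical(n_frames)
  with_seed(seed, {
    frame_seeds <- sample.int(2^31 - 2, n_frames)
    for (i in seq_len(n_frames)) {
      f <- render_bscan(phantom, acq, seed = frame_seeds[i])
      px <- digitize16(f$pixels)
      if (i > 1 && jitter > 0) {
        shifts[i, ] <- sample(seq(-jitter, jitter), 2, replace = TRUE)
        px <- shift_frame(px, shifts[i, 1], shifts[i, 2])
      }
      if (runif(1) < acq$saturation_probability) {
        sat[i] <- TRUE
        n_cols <- max(2L, as.integer(round(runif(1, 0.03, 0.06) * W)))
        n_runs <- sample(1:3, 1)
        run_len <- diff(round(seq(0, n_cols, length.out = n_runs + 1)))
        cols <- integer(0)
        for (l in run_len[run_len > 0]) {
          s0 <- sample(seq_len(W - l + 1L), 1)
          cols <- union(cols, s0:(s0 + l - 1L))
        }
        px[, cols] <- 65535
      }
      frames[, , i] <- px
    }
  })
  meta <- utils::modifyList(list(
    volume_id = "VOL000", patient_id = "P000", specimen_id = "S000",
    label = phantom$label,
    pixel_pitch_axial = acq$scan_depth / H,
    pixel_pitch_lateral = acq$scan_width / W,
    scan_depth = acq$scan_depth, scan_width = acq$scan_width,
    seed = as.integer(seed), bit_depth = 16L), metadata)
  structure(list(frames = frames, metadata = meta,
                 true_shifts = shifts, saturated_frames = which(sat)),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<oct_volume> %s [%s] %d x %d px x %d frames\n",
              x$metadata$volume_id, x$metadata$label, d[1], d[2], d[3]))
  invisible(x)
}
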