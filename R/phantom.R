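# Tissue phantoms: class-conditional attenuation / reflectivity maps that
# carry the OCT signatures of the three tissue classes. Normal cortex is
# homogeneous and uniformly attenuating; glioblastoma (GBM) carries
# low-reflectivity microstructural inclusions and laterally nonuniform
# attenuation; primary CNS lymphoma (PCNSL) is homogeneous but attenuates
# slowly, with only mild smooth lateral variation.

#' Tissue class labels
#'
#' The fixed three-class label set, in canonical order: `NOR` (normal brain
#' tissue), `GBM` (glioblastoma), `PCNSL` (primary CNS lymphoma).
#'
#' @return character vector of the three class names.
#' @export
tissue_classes <- function() c("NOR", "GBM", "PCNSL")

as_tissue_label <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), tissue_classes())
  if (length(bad))
    oct_error("label_error", "unknown tissue class label: %s",
              paste(bad, collapse = ", "))
  factor(x, levels = tissue_classes())
}

#' Class-conditional phantom signature defaults
#'
#' Default attenuation ranges and microstructure settings per tissue class.
#' The PCNSL attenuation range lies strictly below the normal range (slow
#' attenuation is its decisive OCT feature) and GBM carries strong lateral
#' attenuation nonuniformity plus low-reflectivity inclusions. The numeric
#' ranges are simulator conventions expressed in mm^-1, chosen within the
#' span reported for soft brain tissue; they are configuration, not
#' measured values.
#'
#' @return named list of per-class defaults.
#' @export
class_signature_defaults <- function() {
  list(
    NOR = list(mu_range = c(1.5, 2.5), mu_lateral_variation = 0,
               lateral_correlation_length = 0.5, n_inclusions = 0L,
               inclusion_radius_range = c(0, 0)),
    GBM = list(mu_range = c(1.5, 3.5), mu_lateral_variation = 0.4,
               lateral_correlation_length = 0.3, n_inclusions = c(4L, 9L),
               inclusion_radius_range = c(0.08, 0.25)),
    PCNSL = list(mu_range = c(0.6, 1.2), mu_lateral_variation = 0.1,
                 lateral_correlation_length = 1.0, n_inclusions = 0L,
                 inclusion_radius_range = c(0, 0))
  )
}

#' Specify a tissue phantom
#'
#' @param label one of [tissue_classes()].
#' @param mu_base base attenuation coefficient, mm^-1 (> 0).
#' @param mu_lateral_variation relative lateral variation amplitude in
#'   `[0, 1]`; forced to 0 for `NOR`.
#' @param lateral_correlation_length lateral smoothing scale, mm.
#' @param n_inclusions number of low-reflectivity elliptical inclusions;
#'   must be 0 for `NOR` and `PCNSL`.
#' @param inclusion_radius_range `(min, max)` inclusion radius, mm.
#' @param surface_depth depth of the air/tissue interface, mm.
#' @param inclusion_contrast reflectivity multiplier inside inclusions.
#' @param seed integer seed controlling all random structure.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(label,
                         mu_base,
                         mu_lateral_variation = 0,
                         lateral_correlation_length = 0.5,
                         n_inclusions = 0L,
                         inclusion_radius_range = c(0.08, 0.25),
                         surface_depth = 0.2,
                         inclusion_contrast = 0.12,
                         seed = 1L) {
  label <- as.character(label)
  if (!label %in% tissue_classes())
    oct_error("invalid_parameter", "label must be one of %s",
              paste(tissue_classes(), collapse = "/"))
  if (!is.finite(mu_base) || mu_base <= 0)
    oct_error("invalid_parameter", "mu_base must be > 0")
  if (mu_lateral_variation < 0 || mu_lateral_variation > 1)
    oct_error("invalid_parameter", "mu_lateral_variation must be in [0, 1]")
  if (inclusion_radius_range[1] > inclusion_radius_range[2])
    oct_error("invalid_parameter",
              "inclusion_radius_range must be (min, max) with min <= max")
  n_inclusions <- as.integer(n_inclusions)
  if (n_inclusions < 0)
    oct_error("invalid_parameter", "n_inclusions must be >= 0")
  if (label %in% c("NOR", "PCNSL") && n_inclusions > 0)
    oct_error("invalid_parameter",
              "%s phantoms must have n_inclusions = 0", label)
  if (label == "GBM" && n_inclusions == 0)
    log_event("info", "phantom", "GBM spec with n_inclusions = 0")
  if (label == "NOR") mu_lateral_variation <- 0
  structure(list(label = label, mu_base = mu_base,
                 mu_lateral_variation = mu_lateral_variation,
                 lateral_correlation_length = lateral_correlation_length,
                 n_inclusions = n_inclusions,
                 inclusion_radius_range = inclusion_radius_range,
                 surface_depth = surface_depth,
                 inclusion_contrast = inclusion_contrast,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Draw a class-typical phantom specification
#'
#' Samples `mu_base` (and, for GBM, the inclusion count) from the
#' class-conditional defaults of [class_signature_defaults()].
#'
#' @param label tissue class.
#' @param seed integer seed.
#' @param defaults per-class defaults, see [class_signature_defaults()].
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(label, seed,
                                defaults = class_signature_defaults()) {
  d <- defaults[[as.character(label)]]
  if (is.null(d)) oct_error("invalid_parameter", "unknown label %s", label)
  with_seed(seed, {
    mu <- runif(1, d$mu_range[1], d$mu_range[2])
    ninc <- if (length(d$n_inclusions) == 2)
      sample(d$n_inclusions[1]:d$n_inclusions[2], 1) else d$n_inclusions
    phantom_spec(label, mu_base = mu,
                 mu_lateral_variation = d$mu_lateral_variation,
                 lateral_correlation_length = d$lateral_correlation_length,
                 n_inclusions = ninc,
                 inclusion_radius_range = d$inclusion_radius_range,
                 seed = as.integer(seed))
  })
}

# moving-average smoothing with edge replication, used to soften the
# piecewise attenuation "cliffs"
smooth_profile <- function(p, width) {
  width <- max(1L, as.integer(width))
  if (width <= 1L) return(p)
  n <- length(p)
  pad <- c(rep(p[1], width), p, rep(p[n], width))
  k <- 2L * width + 1L
  cs <- cumsum(c(0, pad))
  (cs[(k + 1):(k + n)] - cs[1:n]) / k
}

gaussian_smooth <- function(p, sigma_px) {
  if (sigma_px <= 0) return(p)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-0.5 * ((-half):half / sigma_px)^2)
  k <- k / sum(k)
  n <- length(p)
  pad <- c(rep(p[1], half), p, rep(p[n], half))
  as.numeric(stats::filter(pad, k, sides = 2))[(half + 1):(half + n)]
}

#' Build a tissue phantom raster
#'
#' Realizes a [phantom_spec()] on a `(rows, cols)` = (depth, lateral) grid.
#' `NOR` gives a laterally constant attenuation map; `GBM` a piecewise
#' lateral attenuation field with softened region borders plus elliptical
#' low-reflectivity inclusions recorded in `inclusion_mask`; `PCNSL` a
#' laterally smooth low-attenuation field. Deterministic given the spec
#' seed.
#'
#' @param spec a [phantom_spec()].
#' @param shape integer `(rows, cols)`.
#' @param scan_depth,scan_width physical extents in mm.
#' @return an object of class `tissue_phantom` with elements `mu_map`,
#'   `reflectivity_map`, `inclusion_mask`, `label`, `pixel_pitch_axial`,
#'   `pixel_pitch_lateral`, `surface_row`.
#' @export
build_phantom <- function(spec, shape = c(256L, 512L),
                          scan_depth = 2.5, scan_width = 5) {
  stopifnot(inherits(spec, "phantom_spec"))
  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  dz <- scan_depth / rows
  dx <- scan_width / cols
  surface_row <- min(rows, max(1L, as.integer(round(spec$surface_depth / dz)) + 1L))

  with_seed(spec$seed, {
    v <- spec$mu_lateral_variation
    profile <- switch(spec$label,
      NOR = rep(1, cols),
      GBM = {
        k <- sample(2:4, 1)
        min_w <- max(4L, cols %/% 8L)
        bounds <- sort(sample(seq(min_w, cols - min_w), k - 1))
        bounds <- c(0L, bounds, cols)
        mult <- runif(k, 1 - v, 1 + v)
        # guarantee the full +/-v swing regardless of draw
        lo_hi <- sample(k, 2)
        mult[lo_hi[1]] <- 1 - v
        mult[lo_hi[2]] <- 1 + v
        p <- rep(mult, times = diff(bounds))
        smooth_profile(p, round(spec$lateral_correlation_length / dx / 4))
      },
      PCNSL = {
        z <- gaussian_smooth(rnorm(cols), spec$lateral_correlation_length / dx)
        if (max(abs(z)) > 0) z <- z / max(abs(z))
        1 + v * z
      })

    depth_ind <- c(rep(0, surface_row - 1L), rep(1, rows - surface_row + 1L))
    mu_map <- outer(depth_ind, spec$mu_base * profile)
    refl <- outer(depth_ind, rep(1, cols))

    mask <- matrix(FALSE, rows, cols)
    if (spec$label == "GBM" && spec$n_inclusions > 0) {
      rr <- spec$inclusion_radius_range
      placed <- 0L
      tries <- 0L
      rows_grid <- matrix(seq_len(rows), rows, cols)
      cols_grid <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
      while (placed < spec$n_inclusions && tries < 500L) {
        tries <- tries + 1L
        r_mm <- runif(1, rr[1], rr[2])
        ra <- max(1.5, r_mm / dz)
        rc <- max(1.5, r_mm / dx)
        margin_r <- ceiling(ra) + 2L
        margin_c <- ceiling(rc) + 2L
        if (surface_row + 2L * margin_r >= rows) break
        cr <- runif(1, surface_row + margin_r, rows - margin_r)
        cc <- runif(1, margin_c, cols - margin_c)
        ell <- ((rows_grid - cr) / ra)^2 + ((cols_grid - cc) / rc)^2 <= 1
        # keep inclusions disjoint (2 px guard ring) so components stay
        # countable
        guard <- ((rows_grid - cr) / (ra + 2))^2 +
          ((cols_grid - cc) / (rc + 2))^2 <= 1
        if (any(mask & guard)) next
        mask <- mask | ell
        placed <- placed + 1L
      }
      if (placed < spec$n_inclusions)
        log_event("warning", "phantom",
                  "placed %d of %d requested inclusions", placed,
                  spec$n_inclusions)
      refl[mask] <- refl[mask] * spec$inclusion_contrast
    }

    structure(list(mu_map = mu_map, reflectivity_map = refl,
                   inclusion_mask = mask, label = spec$label,
                   pixel_pitch_axial = dz, pixel_pitch_lateral = dx,
                   surface_row = surface_row, spec = spec),
              class = "tissue_phantom")
  })
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("<tissue_phantom> %s, %d x %d px (%.4f x %.4f mm/px), %d inclusion px\n",
              x$label, nrow(x$mu_map), ncol(x$mu_map),
              x$pixel_pitch_axial, x$pixel_pitch_lateral,
              sum(x$inclusion_mask)))
  invisible(x)
}

#' Theoretical OCT axial resolution
#'
#' Gaussian-source coherence length `(2 ln 2 / pi) * lambda_c^2 / delta_lambda`.
#' For a source centered at 1.31 um with 100 nm FWHM bandwidth this gives
#' 7.57 um, i.e. about 8 um in air.
#'
#' @param center_wavelength center wavelength, um.
#' @param fwhm_bandwidth full-width-half-maximum bandwidth, nm.
#' @return axial resolution in um.
#' @export
axial_resolution <- function(center_wavelength, fwhm_bandwidth) {
  if (!is.finite(center_wavelength) || center_wavelength <= 0 ||
      !is.finite(fwhm_bandwidth) || fwhm_bandwidth <= 0)
    oct_error("invalid_parameter",
              "center_wavelength and fwhm_bandwidth must be > 0")
  (2 * log(2) / pi) * center_wavelength^2 / (fwhm_bandwidth / 1000)
}

#' Specify acquisition geometry and noise
#'
#' @param n_depth_pixels,n_lateral_pixels raster size of one B-scan.
#' @param scan_width,scan_depth physical extents, mm.
#' @param center_wavelength source center wavelength, um.
#' @param fwhm_bandwidth source FWHM bandwidth, nm.
#' @param speckle_shape gamma-speckle shape parameter `k` (unit mean;
#'   `k = 1` is fully developed intensity speckle, coefficient of
#'   variation `1/sqrt(k)`).
#' @param noise_floor additive noise scale, linear intensity units.
#' @param saturation_probability per-frame probability of a saturation
#'   stripe artifact.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_depth_pixels = 256L, n_lateral_pixels = 512L,
                             scan_width = 5, scan_depth = 2.5,
                             center_wavelength = 1.31, fwhm_bandwidth = 100,
                             speckle_shape = 1, noise_floor = 1e-4,
                             saturation_probability = 0) {
  if (n_depth_pixels < 1 || n_lateral_pixels < 1)
    oct_error("invalid_parameter", "pixel counts must be positive")
  if (scan_width <= 0 || scan_depth <= 0)
    oct_error("invalid_parameter", "scan dimensions must be positive")
  if (speckle_shape <= 0)
    oct_error("invalid_parameter", "speckle_shape must be positive")
  if (saturation_probability < 0 || saturation_probability > 1)
    oct_error("invalid_parameter", "saturation_probability must be in [0, 1]")
  structure(list(n_depth_pixels = as.integer(n_depth_pixels),
                 n_lateral_pixels = as.integer(n_lateral_pixels),
                 scan_width = scan_width, scan_depth = scan_depth,
                 center_wavelength = center_wavelength,
                 fwhm_bandwidth = fwhm_bandwidth,
                 speckle_shape = speckle_shape, noise_floor = noise_floor,
                 saturation_probability = saturation_probability),
            class = "acquisition_spec")
}
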