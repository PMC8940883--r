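# Volume I/O: multi-page 16-bit grayscale TIFF stacks (page order = frame
# order) with a JSON sidecar named <volume_id>.json carrying ids, label,
# pixel pitches and the generator seed.

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

#' Write an OCT volume to disk
#'
#' Writes a multi-page 16-bit TIFF plus a JSON metadata sidecar next to it.
#' The round trip through [read_volume()] is lossless for integer counts in
#' `[0, 65535]`.
#'
#' @param volume an `oct_volume`.
#' @param path TIFF file path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0)
    oct_error("io_error", "output directory not writable: %s", dir)
  n <- dim(volume$frames)[3]
  pages <- lapply(seq_len(n), function(i) volume$frames[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- volume$metadata
  meta$n_frames <- n
  meta$n_depth_pixels <- dim(volume$frames)[1]
  meta$n_lateral_pixels <- dim(volume$frames)[2]
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an OCT volume from disk
#'
#' @param path TIFF file path written by [write_volume()]. The JSON sidecar
#'   must be present alongside.
#' @return an `oct_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    oct_error("io_error", "volume stack not found: %s", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    oct_error("metadata_error", "missing metadata sidecar: expected %s", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    oct_error("format_error", "TIFF pages have inconsistent shapes in %s", path)
  frames <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  meta$source_path <- path
  structure(list(frames = frames, metadata = meta), class = "oct_volume")
}

#' Generate a labeled synthetic OCT dataset
#'
#' Renders one phantom per volume with class-typical signatures, writes each
#' volume as TIFF + JSON sidecar under `out_dir`, and writes a
#' `manifest.csv` with one row per volume (volume_id, patient_id,
#' specimen_id, label, path, split_hint, seed). Per-volume seeds derive from
#' `seed`, so regeneration is byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param train_volumes,test_volumes named integer vectors of per-class
#'   volume counts; names from [tissue_classes()]. The defaults mirror the
#'   15/10/5 training + 2/3/3 testing volume layout of the study design.
#' @param frames_per_volume B-scans per volume.
#' @param acq an [acquisition_spec()].
#' @param seed master seed.
#' @param defaults class signature defaults, see [class_signature_defaults()].
#' @return the manifest data frame.
#' @export
generate_dataset <- function(out_dir,
                             train_volumes = c(NOR = 15, GBM = 10, PCNSL = 5),
                             test_volumes = c(NOR = 2, GBM = 3, PCNSL = 3),
                             frames_per_volume = 16L,
                             acq = acquisition_spec(),
                             seed = 1L,
                             defaults = class_signature_defaults()) {
  if (any(train_volumes < 0) || any(test_volumes < 0))
    oct_error("invalid_parameter", "volume counts must be >= 0")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    oct_error("io_error", "output path not writable: %s", out_dir)

  layout <- data.frame(
    label = c(rep(names(train_volumes), train_volumes),
              rep(names(test_volumes), test_volumes)),
    split_hint = c(rep("train", sum(train_volumes)),
                   rep("test", sum(test_volumes))),
    stringsAsFactors = FALSE)
  n <- nrow(layout)
  if (n == 0) oct_error("invalid_parameter", "no volumes requested")

  vol_seeds <- with_seed(seed, sample.int(2^31 - 2, n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- layout$label[i]
    # deterministic id scheme: ~2 volumes per specimen, ~2 specimens per
    # patient within each class
    k <- sum(layout$label[seq_len(i)] == lab)
    patient <- sprintf("P_%s_%02d", lab, (k - 1) %/% 4 + 1)
    specimen <- sprintf("S_%s_%02d", lab, (k - 1) %/% 2 + 1)
    vid <- sprintf("VOL%03d", i)
    spec <- random_phantom_spec(lab, vol_seeds[i], defaults)
    phantom <- build_phantom(spec,
                             c(acq$n_depth_pixels, acq$n_lateral_pixels),
                             acq$scan_depth, acq$scan_width)
    vol <- render_volume(phantom, acq, frames_per_volume,
                         seed = vol_seeds[i],
                         metadata = list(volume_id = vid, patient_id = patient,
                                         specimen_id = specimen))
    path <- file.path(out_dir, paste0(vid, ".tiff"))
    write_volume(vol, path)
    rows[[i]] <- data.frame(volume_id = vid, patient_id = patient,
                            specimen_id = specimen, label = lab, path = path,
                            split_hint = layout$split_hint[i],
                            seed = vol_seeds[i], stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  log_event("info", "simulate", "wrote %d volumes to %s", n, out_dir)
  manifest
}
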