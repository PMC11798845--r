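#' Region-of-interest specification
#'
#' An ROI is either a circle in physical (mm) coordinates or an explicit
#' binary pixel mask. The standard study regions are a large `whole_brain`
#' region, a 5-mm `central_thalamic` circle over the basal ganglia/thalami,
#' and a 5-mm `peripheral_parenchyma` circle over predominately white matter.
#'
#' Pixel `(i, j)` (1-based row, column) has its center at physical position
#' `((i - 0.5) * s, (j - 0.5) * s)` mm where `s` is the pixel spacing.
#'
#' @param label ROI label; one of `"whole_brain"`, `"central_thalamic"`,
#'   `"peripheral_parenchyma"` or any caller-chosen string.
#' @param center_mm length-2 numeric, circle center `(row_mm, col_mm)`.
#' @param diameter_mm circle diameter, mm.
#' @param mask logical matrix: explicit ROI mask (overrides the circle).
#' @param clip_id provenance: id of the clip the ROI was drawn on.
#' @return A list of class `roi_spec`.
#' @export
roi_spec <- function(label, center_mm = NULL, diameter_mm = NULL,
                     mask = NULL, clip_id = NA_character_) {
  if (is.null(mask)) {
    if (is.null(center_mm) || is.null(diameter_mm))
      stop_invalid("either `mask` or both `center_mm` and `diameter_mm` needed")
    if (length(center_mm) != 2L || !all(is.finite(center_mm)))
      stop_invalid("`center_mm` must be two finite coordinates")
    check_scalar(diameter_mm, "diameter_mm", positive = TRUE)
  } else {
    mask <- as.matrix(mask)
    if (!is.logical(mask)) stop_invalid("`mask` must be a logical matrix")
    if (!any(mask)) stop_invalid("explicit ROI mask is empty")
  }
  structure(list(label = label, center_mm = center_mm,
                 diameter_mm = diameter_mm, mask = mask, clip_id = clip_id),
            class = "roi_spec")
}

#' Rasterize an ROI to a binary pixel mask
#'
#' Circle ROIs include every pixel whose center lies within `diameter_mm / 2`
#' of the circle center, with distances measured in mm through the clip's
#' pixel spacing. Explicit masks pass through unchanged (after a grid check).
#'
#' @param spec a [roi_spec()].
#' @param clip the [cine_clip()] whose grid the mask is for.
#' @return Logical matrix of the clip's grid size with at least one `TRUE`.
#' @export
rasterize_roi <- function(spec, clip) {
  stopifnot(inherits(spec, "roi_spec"), inherits(clip, "cine_clip"))
  h <- dim(clip$frames)[1L]; w <- dim(clip$frames)[2L]
  if (!is.null(spec$mask)) {
    if (!identical(dim(spec$mask), c(h, w)))
      stop_invalid("explicit mask does not match the clip grid")
    return(spec$mask)
  }
  s <- clip$pixel_spacing_mm
  r <- spec$diameter_mm / 2
  ctr <- spec$center_mm
  if (ctr[1L] - r < 0 || ctr[1L] + r > h * s ||
      ctr[2L] - r < 0 || ctr[2L] + r > w * s)
    stop_invalid("circle ROI extends outside the image grid")
  rows <- (seq_len(h) - 0.5) * s
  cols <- (seq_len(w) - 0.5) * s
  d2 <- outer((rows - ctr[1L])^2, (cols - ctr[2L])^2, `+`)
  mask <- d2 <= r^2 + 1e-12
  if (!any(mask))
    stop_invalid("circle ROI covers no pixel centers; enlarge or recenter it")
  mask
}

#' Detect the end of the destruction (flash) window
#'
#' If the clip metadata records `flash_end_index` it is returned directly.
#' Otherwise the whole-frame mean intensity is scanned for its global
#' minimum (the last frame attaining it, so a flat destruction floor maps to
#' the start of replenishment); the minimum qualifies only if it falls below
#' 50% of the running mean of the frames preceding it, i.e. only if a real
#' destruction event is visible.
#'
#' @param clip a [cine_clip()].
#' @return Integer frame index of the first post-destruction frame.
#' @export
detect_flash <- function(clip) {
  stopifnot(inherits(clip, "cine_clip"))
  if (!is.na(clip$flash_end_index)) return(clip$flash_end_index)
  nt <- dim(clip$frames)[3L]
  if (nt < 5L) stop_invalid("flash detection needs at least 5 frames")
  means <- apply(clip$frames, 3L, mean)
  m <- min(means)
  tol <- 1e-12 * max(means, 1)
  idx <- max(which(means <= m + tol))       # last frame at the floor
  first_min <- min(which(means <= m + tol))
  if (first_min <= 1L)
    stop(errorCondition(
      paste0("no pre-destruction frames before the intensity minimum; ",
             "specify flash_end_index explicitly"),
      class = c("ceusperf_flash_detection", "error")))
  pre_mean <- mean(means[seq_len(first_min - 1L)])
  if (!(m < 0.5 * pre_mean))
    stop(errorCondition(
      paste0("no destruction event found (intensity never drops below 50% ",
             "of the preceding mean); specify flash_end_index explicitly"),
      class = c("ceusperf_flash_detection", "error")))
  if (idx >= nt)
    stop(errorCondition("no post-destruction frames after detected flash end",
                        class = c("ceusperf_flash_detection", "error")))
  idx
}

#' Extract an ROI-mean time-intensity curve
#'
#' @param clip a [cine_clip()].
#' @param mask logical mask from [rasterize_roi()], or a [roi_spec()] to
#'   rasterize on the fly.
#' @param roi label stored on the curve (taken from the spec if one is given).
#' @param replicate replicate index of the acquisition.
#' @param meta optional named list of exam metadata (animal, group, day, ...).
#' @return An object of class `tic`: ROI-averaged intensity against time,
#'   with `times_s`, `intensities_au`, `roi`, `replicate`, `meta` and the
#'   clip's `flash_end_index` carried along.
#' @export
extract_tic <- function(clip, mask, roi = NULL, replicate = 1L, meta = list()) {
  stopifnot(inherits(clip, "cine_clip"))
  if (inherits(mask, "roi_spec")) {
    if (is.null(roi)) roi <- mask$label
    mask <- rasterize_roi(mask, clip)
  }
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(clip$frames)[1:2]))
    stop_invalid("mask does not match the clip grid")
  if (!any(mask)) stop_invalid("empty ROI mask")
  nt <- dim(clip$frames)[3L]
  idx <- which(mask)
  npix <- length(idx)
  flat <- matrix(clip$frames, nrow = prod(dim(clip$frames)[1:2]), ncol = nt)
  intensities <- colSums(flat[idx, , drop = FALSE]) / npix
  structure(list(times_s = clip_times(clip),
                 intensities_au = as.numeric(intensities),
                 roi = if (is.null(roi)) "roi" else roi,
                 replicate = as.integer(replicate),
                 n_pixels = npix,
                 flash_end_index = clip$flash_end_index,
                 frame_interval_s = clip$frame_interval_s,
                 meta = meta),
            class = "tic")
}

#' Construct a time-intensity curve directly
#'
#' @param times_s strictly increasing sample times, seconds (0 = clip start).
#' @param intensities_au non-negative ROI-mean intensities, au.
#' @inheritParams extract_tic
#' @param flash_end_index optional index of the first post-destruction sample.
#' @return An object of class `tic`.
#' @export
tic <- function(times_s, intensities_au, roi = "roi", replicate = 1L,
                meta = list(), flash_end_index = NA_integer_) {
  if (length(times_s) != length(intensities_au))
    stop_invalid("times and intensities must have equal length")
  if (any(diff(times_s) <= 0))
    stop_invalid("times must be strictly increasing")
  if (anyNA(intensities_au) || min(intensities_au) < 0)
    stop_invalid("intensities must be non-negative")
  structure(list(times_s = as.numeric(times_s),
                 intensities_au = as.numeric(intensities_au),
                 roi = roi, replicate = as.integer(replicate),
                 n_pixels = NA_integer_,
                 flash_end_index = as.integer(flash_end_index),
                 frame_interval_s = if (length(times_s) > 1)
                   times_s[2] - times_s[1] else NA_real_,
                 meta = meta),
            class = "tic")
}

#' Export a time-intensity curve to CSV
#'
#' @param x a `tic`.
#' @param path output CSV path with columns `time_s`, `intensity_au`.
#' @export
write_tic_csv <- function(x, path) {
  stopifnot(inherits(x, "tic"))
  write.csv(data.frame(time_s = x$times_s, intensity_au = x$intensities_au),
            path, row.names = FALSE)
  invisible(path)
}
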