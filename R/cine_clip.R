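#' Cine clip container
#'
#' A cine clip is a stack of grayscale intensity frames from one
#' flash-replenishment acquisition, plus the acquisition metadata needed to
#' interpret it: the frame interval, the physical pixel spacing, and
#' (optionally) the index of the first post-destruction frame.
#'
#' @param frames numeric array with dim `c(height, width, n_frames)`;
#'   intensities in arbitrary units (au), all non-negative.
#' @param frame_interval_s time between consecutive frames, seconds.
#' @param pixel_spacing_mm physical size of one pixel, millimetres
#'   (square pixels assumed).
#' @param flash_end_index 1-based index of the first frame after the
#'   destruction pulse (the frame at which replenishment time is zero), or
#'   `NA` if unknown.
#' @param id character provenance identifier.
#' @param seed seed used to generate the clip, or `NA` for acquired data.
#'
#' @return An object of class `cine_clip`.
#' @export
cine_clip <- function(frames, frame_interval_s, pixel_spacing_mm,
                      flash_end_index = NA_integer_, id = "clip",
                      seed = NA_integer_) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_invalid("`frames` must be a height x width x time array")
  nt <- dim(frames)[3L]
  if (nt < 2L) stop_invalid("a cine clip needs at least 2 frames")
  if (dim(frames)[1L] < 1L || dim(frames)[2L] < 1L)
    stop_invalid("empty pixel grid")
  if (anyNA(frames) || min(frames) < 0)
    stop_invalid("frame intensities must be non-negative and non-missing")
  check_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  check_scalar(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  if (!is.na(flash_end_index)) {
    check_scalar(flash_end_index, "flash_end_index", positive = TRUE,
                 integerish = TRUE)
    if (flash_end_index > nt)
      stop_invalid("flash_end_index exceeds the number of frames")
  }
  structure(
    list(frames = frames,
         frame_interval_s = as.numeric(frame_interval_s),
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         flash_end_index = as.integer(flash_end_index),
         id = as.character(id),
         seed = seed),
    class = "cine_clip")
}

#' @export
print.cine_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<cine_clip '%s'> %d x %d px (%.3g mm/px), %d frames @ %.4g s, flash end %s\n",
    x$id, d[1L], d[2L], x$pixel_spacing_mm, d[3L], x$frame_interval_s,
    ifelse(is.na(x$flash_end_index), "unknown", x$flash_end_index)))
  invisible(x)
}

#' Frame times of a cine clip
#'
#' @param clip a [cine_clip()].
#' @return Numeric vector of frame times in seconds, `0` at the first frame.
#' @export
clip_times <- function(clip) {
  stopifnot(inherits(clip, "cine_clip"))
  (seq_len(dim(clip$frames)[3L]) - 1) * clip$frame_interval_s
}
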