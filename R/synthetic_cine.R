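#' Cine acquisition configuration
#'
#' Describes a synthetic flash-replenishment acquisition: grid geometry,
#' frame rate, the duration of the baseline (steady-state contrast), the
#' microbubble destruction pulse, and post-destruction imaging, plus the
#' multiplicative speckle-noise scale.
#'
#' @param height_px,width_px grid size in pixels.
#' @param pixel_spacing_mm physical pixel size, mm.
#' @param frame_rate_hz frames per second.
#' @param destruction_duration_s duration of the destruction pulse, seconds.
#' @param imaging_duration_s post-destruction imaging duration, seconds; at
#'   least 10 frames of replenishment imaging are required.
#' @param baseline_duration_s steady-state frames before the pulse, seconds.
#' @param noise_sigma log-scale standard deviation of the unit-mean
#'   multiplicative (log-normal) speckle-like noise; `0` disables noise.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#'
#' @return A list of class `cine_config`.
#' @export
cine_config <- function(height_px = 40L, width_px = 40L,
                        pixel_spacing_mm = 0.5, frame_rate_hz = 15,
                        destruction_duration_s = 3.0,
                        imaging_duration_s = 15.0,
                        baseline_duration_s = 1.0,
                        noise_sigma = 0.05, seed = NULL) {
  check_scalar(height_px, "height_px", positive = TRUE, integerish = TRUE)
  check_scalar(width_px, "width_px", positive = TRUE, integerish = TRUE)
  check_scalar(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  check_scalar(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  check_scalar(destruction_duration_s, "destruction_duration_s", nonneg = TRUE)
  check_scalar(imaging_duration_s, "imaging_duration_s", positive = TRUE)
  check_scalar(baseline_duration_s, "baseline_duration_s", nonneg = TRUE)
  check_scalar(noise_sigma, "noise_sigma", nonneg = TRUE)
  if (imaging_duration_s * frame_rate_hz < 10)
    stop_invalid("imaging_duration_s x frame_rate_hz must be >= 10 frames")
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 pixel_spacing_mm = pixel_spacing_mm,
                 frame_rate_hz = frame_rate_hz,
                 destruction_duration_s = destruction_duration_s,
                 imaging_duration_s = imaging_duration_s,
                 baseline_duration_s = baseline_duration_s,
                 noise_sigma = noise_sigma,
                 seed = seed),
            class = "cine_config")
}

#' Per-pixel tissue kinetic parameter maps
#'
#' Holds, for every pixel of the cine grid, the plateau amplitude `A` (au),
#' the replenishment rate `beta` (1/s) and the post-destruction residual
#' offset `O` (au) of the mono-exponential refill model.
#'
#' @param amplitude matrix of plateau amplitudes A(x), au.
#' @param rate matrix of replenishment rates beta(x), 1/s.
#' @param offset matrix of residual offsets O(x), au; defaults to zero.
#' @return A list of class `tissue_map`.
#' @export
tissue_map <- function(amplitude, rate, offset = NULL) {
  amplitude <- as.matrix(amplitude)
  rate <- as.matrix(rate)
  if (is.null(offset)) offset <- matrix(0, nrow(amplitude), ncol(amplitude))
  offset <- as.matrix(offset)
  dims <- dim(amplitude)
  if (!identical(dims, dim(rate)) || !identical(dims, dim(offset)))
    stop_invalid("amplitude, rate and offset maps must share one pixel grid")
  if (anyNA(amplitude) || anyNA(rate) || anyNA(offset) ||
      min(amplitude) < 0 || min(rate) < 0 || min(offset) < 0)
    stop_invalid("tissue map entries must be non-negative and non-missing")
  structure(list(amplitude = amplitude, rate = rate, offset = offset),
            class = "tissue_map")
}

# Uniform tissue over the configured grid (convenience, mostly for tests).
#' @rdname tissue_map
#' @param config a [cine_config()] giving the grid.
#' @param A,beta,O scalar kinetic parameters applied to every pixel.
#' @export
uniform_tissue <- function(config, A, beta, O = 0) {
  h <- config$height_px; w <- config$width_px
  tissue_map(matrix(A, h, w), matrix(beta, h, w), matrix(O, h, w))
}

#' Simulate a flash-replenishment cine clip
#'
#' Generates a synthetic destruction-replenishment acquisition. The noiseless
#' mean intensity of pixel `x` is `O(x) + A(x)` during the baseline segment,
#' `O(x)` during the destruction pulse, and
#' `O(x) + A(x) * (1 - exp(-beta(x) * (t - t_f)))` for frames at `t >= t_f`,
#' where `t_f` is the time of the first post-destruction frame (recorded as
#' `flash_end_index`). When `noise_sigma > 0` every pixel-frame value is
#' multiplied by an independent unit-mean log-normal factor.
#'
#' @param config a [cine_config()].
#' @param tissue a [tissue_map()] on the same grid.
#' @param id provenance identifier for the clip.
#' @return A [cine_clip()].
#' @export
simulate_cine <- function(config, tissue, id = "synthetic") {
  stopifnot(inherits(config, "cine_config"), inherits(tissue, "tissue_map"))
  h <- config$height_px; w <- config$width_px
  if (!identical(dim(tissue$amplitude), c(h, w)))
    stop_invalid("tissue map grid does not match the cine configuration")
  fr <- config$frame_rate_hz
  n_base <- round(config$baseline_duration_s * fr)
  n_destr <- round(config$destruction_duration_s * fr)
  n_img <- round(config$imaging_duration_s * fr)
  if (n_img < 10) stop_invalid("fewer than 10 post-destruction frames")
  nt <- n_base + n_destr + n_img
  dt <- 1 / fr
  flash_end <- n_base + n_destr + 1L   # first post-destruction frame
  t_f <- (flash_end - 1L) * dt

  A <- tissue$amplitude; B <- tissue$rate; O <- tissue$offset
  frames <- array(0, dim = c(h, w, nt))
  if (n_base > 0)
    for (k in seq_len(n_base)) frames[, , k] <- O + A
  if (n_destr > 0)
    for (k in seq_len(n_destr)) frames[, , n_base + k] <- O
  times <- (seq_len(nt) - 1) * dt
  for (k in flash_end:nt) {
    frames[, , k] <- O + A * (1 - exp(-B * (times[k] - t_f)))
  }
  if (config$noise_sigma > 0) {
    s <- config$noise_sigma
    frames <- with_seed(config$seed, {
      frames * array(rlnorm(length(frames), meanlog = -s^2 / 2, sdlog = s),
                     dim = dim(frames))
    })
  }
  cine_clip(frames, frame_interval_s = dt,
            pixel_spacing_mm = config$pixel_spacing_mm,
            flash_end_index = flash_end, id = id,
            seed = if (is.null(config$seed)) NA_integer_ else config$seed)
}
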