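# Clip container on disk: a multi-page 32-bit TIFF (one page per frame) plus
# a plain-text key=value sidecar. Intensities are stored as 31-bit integer
# counts of a power-of-two full-scale value recorded in the sidecar
# (intensity_scale), so a saved clip reloads bit-exactly and a fresh clip
# round-trips with relative error below 5e-10 of full scale.

QUANT_MAX <- 2147483647          # 2^31 - 1, quantization levels
TIFF_MAX <- 4294967295           # writeTIFF maps [0,1] onto [0, 2^32 - 1]

sidecar_path <- function(path) paste0(path, ".meta")

#' Save or load a cine clip
#'
#' `save_cine()` writes a clip as a multi-page 32-bit TIFF plus a plain-text
#' sidecar (`<path>.meta`) holding `frame_interval_s`, `pixel_spacing_mm`,
#' `flash_end_index`, `intensity_scale`, `id` and `seed`. `load_cine()` reads
#' the pair back. Reloading a file produced by `save_cine()` and saving it
#' again reproduces the file contents exactly.
#'
#' @param clip a [cine_clip()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `save_cine()` returns `path` invisibly; `load_cine()` returns a
#'   [cine_clip()].
#' @export
save_cine <- function(clip, path) {
  stopifnot(inherits(clip, "cine_clip"))
  mx <- max(clip$frames)
  scale <- if (mx <= 0) 1 else 2^ceiling(log2(mx))
  q <- round(clip$frames / scale * QUANT_MAX)
  # half-step offset: writeTIFF truncates to floor(v * (2^32 - 1))
  pages <- lapply(seq_len(dim(q)[3L]),
                  function(k) (q[, , k] + 0.5) / TIFF_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- c(frame_interval_s = clip$frame_interval_s,
            pixel_spacing_mm = clip$pixel_spacing_mm,
            flash_end_index = clip$flash_end_index,
            intensity_scale = scale,
            id = clip$id,
            seed = clip$seed)
  writeLines(paste0(names(meta), "=", as.character(meta)), sidecar_path(path))
  invisible(path)
}

#' @rdname save_cine
#' @export
load_cine <- function(path) {
  if (!file.exists(path)) stop_invalid("cine file not found: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop_invalid("missing sidecar metadata file: ", sp)
  lines <- readLines(sp)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  meta <- setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                   vapply(kv, `[[`, "", 1L))
  for (key in c("frame_interval_s", "pixel_spacing_mm", "intensity_scale")) {
    if (!key %in% names(meta))
      stop_invalid("sidecar is missing required key '", key, "'")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- as.numeric(meta[["intensity_scale"]])
  frames <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]),
                             length(pages)))
  for (k in seq_along(pages))
    frames[, , k] <- pages[[k]] / QUANT_MAX * scale
  fei <- if ("flash_end_index" %in% names(meta))
    suppressWarnings(as.integer(meta[["flash_end_index"]])) else NA_integer_
  sd <- if ("seed" %in% names(meta))
    suppressWarnings(as.integer(meta[["seed"]])) else NA_integer_
  cine_clip(frames,
            frame_interval_s = as.numeric(meta[["frame_interval_s"]]),
            pixel_spacing_mm = as.numeric(meta[["pixel_spacing_mm"]]),
            flash_end_index = fei,
            id = if ("id" %in% names(meta)) meta[["id"]] else basename(path),
            seed = sd)
}
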