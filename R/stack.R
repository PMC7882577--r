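#' Multi-channel image stack with physical spacing
#'
#' A `synq_stack` is a 4-D numeric array `[x, y, section, channel]` carrying
#' the physical pixel size and section spacing in micrometres. The same
#' container holds confocal z-stacks (spacing = optical z-step, 0.15 um by
#' default) and array-tomography section series (spacing = physical section
#' thickness, 0.07 um). Coordinates are physical micrometres with the origin
#' at the field corner: pixel `(i, j)` of section `k` (1-based) has its
#' center at `((i - 0.5) * pixel_size, (j - 0.5) * pixel_size,
#' (k - 0.5) * spacing)`.
#'
#' @param data numeric array `[x, y, section, channel]` (a 3-D array is
#'   promoted to one channel).
#' @param pixel_size_um in-plane pixel size, um.
#' @param spacing_um section spacing (z-step or section thickness), um.
#' @param channels character vector of channel names, one per channel slab.
#' @param mode `"confocal"` or `"array_tomography"`; informational.
#'
#' @return A `synq_stack` object.
#' @export
synq_stack <- function(data, pixel_size_um, spacing_um, channels,
                       mode = c("confocal", "array_tomography")) {
  mode <- match.arg(mode)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) {
    abort("`data` must be a [x, y, section, channel] array.")
  }
  check_num(pixel_size_um, "pixel_size_um", min = 0, allow_zero = FALSE)
  check_num(spacing_um, "spacing_um", min = 0, allow_zero = FALSE)
  if (length(channels) != dim(data)[4L]) {
    abort("`channels` must name every channel slab.")
  }
  structure(data,
            pixel_size_um = pixel_size_um,
            spacing_um = spacing_um,
            channels = as.character(channels),
            mode = mode,
            class = c("synq_stack", "array"))
}

#' @export
print.synq_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<synq_stack> %d x %d px, %d sections, channels: %s\n  pixel %.4f um, spacing %.3f um (%s)\n",
    d[1], d[2], d[3], paste(attr(x, "channels"), collapse = ", "),
    attr(x, "pixel_size_um"), attr(x, "spacing_um"), attr(x, "mode")))
  invisible(x)
}

stack_channel <- function(stack, channel) {
  ch <- attr(stack, "channels")
  idx <- match(channel, ch)
  if (is.na(idx)) abort(sprintf("channel '%s' not in stack (%s)",
                                channel, paste(ch, collapse = ", ")))
  unclass(stack)[, , , idx, drop = FALSE][, , , 1L]
}

#' Write / read a stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are written channel-major (all sections of channel 1, then channel
#' 2, ...) as 32-bit floats scaled to `[0, 1]`; the scale factor, geometry
#' and channel names go to `<path>.json` so the round trip restores physical
#' units.
#'
#' @param stack a [synq_stack()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   a [synq_stack()].
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack)
  lo <- min(stack)
  scale <- max(max(stack) - lo, 1e-12)
  pages <- vector("list", d[3L] * d[4L])
  p <- 1L
  for (c in seq_len(d[4L])) {
    for (k in seq_len(d[3L])) {
      pages[[p]] <- (unclass(stack)[, , k, c] - lo) / scale
      p <- p + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    pixel_size_um = attr(stack, "pixel_size_um"),
    spacing_um = attr(stack, "spacing_um"),
    channels = attr(stack, "channels"),
    mode = attr(stack, "mode"),
    dim = d, intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) abort(sprintf("stack file not found: %s", path))
  if (!file.exists(sidecar)) abort(sprintf("missing sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  arr <- array(0, d)
  p <- 1L
  for (c in seq_len(d[4L])) {
    for (k in seq_len(d[3L])) {
      arr[, , k, c] <- pages[[p]] * meta$intensity_scale +
        (meta$intensity_offset %||% 0)
      p <- p + 1L
    }
  }
  synq_stack(arr, meta$pixel_size_um, meta$spacing_um, meta$channels,
             mode = meta$mode)
}
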