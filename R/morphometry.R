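#' Cell density per field or compartment
#'
#' Count divided by area. When a compartment mask is given (e.g. lesion or
#' perilesion from [perilesion_partition()]), only cells whose position
#' falls on a mask pixel are counted and the area is the mask area.
#'
#' @param cells tibble with `x_um, y_um` positions (or an integer count).
#' @param field_area_mm2 analyzed area, mm2; must be > 0 (ignored when a
#'   mask is given).
#' @param compartment_mask optional logical matrix `[x, y]`.
#' @param pixel_size_um pixel size of the mask, um.
#' @return One-row tibble: `n_cells, area_mm2, cells_per_mm2`.
#' @export
cell_density <- function(cells, field_area_mm2 = NULL,
                         compartment_mask = NULL, pixel_size_um = NULL) {
  if (!is.null(compartment_mask)) {
    if (is.null(pixel_size_um)) {
      abort("`pixel_size_um` is required with a compartment mask.")
    }
    area <- sum(compartment_mask) * pixel_size_um^2 / 1e6
    if (is.data.frame(cells)) {
      i <- pmin(pmax(floor(cells$x_um / pixel_size_um) + 1L, 1L),
                nrow(compartment_mask))
      j <- pmin(pmax(floor(cells$y_um / pixel_size_um) + 1L, 1L),
                ncol(compartment_mask))
      n <- sum(compartment_mask[cbind(i, j)])
    } else {
      n <- as.integer(cells)
    }
  } else {
    area <- field_area_mm2
    n <- if (is.data.frame(cells)) nrow(cells) else as.integer(cells)
  }
  if (is.null(area) || !is.finite(area) || area <= 0) {
    abort("analyzed area must be > 0.")
  }
  tibble(n_cells = as.integer(n), area_mm2 = area,
         cells_per_mm2 = n / area)
}

#' Thresholded signal area of a 2-D field
#'
#' Segments the image with [local_threshold_section()] and reports
#' foreground area in um2. With `exclude_somata = TRUE`, connected
#' components larger than `soma_area_um2` are removed first, so that
#' puncta-scale signal can be quantified while cell bodies are ignored.
#'
#' @param image numeric matrix `[x, y]`.
#' @param params a [seg_params()].
#' @param pixel_size_um pixel size, um.
#' @param exclude_somata drop components larger than the soma cutoff.
#' @param soma_area_um2 component-area cutoff, um2 (default 20).
#' @return One-row tibble: `signal_area_um2, n_foreground_px,
#'   foreground_fraction`.
#' @export
signal_area <- function(image, params, pixel_size_um,
                        exclude_somata = FALSE, soma_area_um2 = 20) {
  check_num(pixel_size_um, "pixel_size_um", min = 0, allow_zero = FALSE)
  mask <- local_threshold_section(image, params)
  if (exclude_somata && any(mask)) {
    lab <- label8(mask)
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    big <- which(sizes * pixel_size_um^2 > soma_area_um2)
    if (length(big) > 0) mask[lab %in% big] <- FALSE
  }
  n <- sum(mask)
  tibble(signal_area_um2 = n * pixel_size_um^2,
         n_foreground_px = as.integer(n),
         foreground_fraction = mean(mask))
}

#' Count axon crossings along a measurement line
#'
#' Rasterises the query segment (nominally 100 um, the standard axonal
#' density measure) and counts distinct foreground runs — maximal stretches
#' of consecutive line pixels that fall on fiber signal. The count is
#' invariant to fiber thickness as long as fibers stay disjoint along the
#' line.
#'
#' @param mask logical matrix `[x, y]` of fiber signal.
#' @param line segment `c(x0, y0, x1, y1)`, um; must lie inside the image.
#' @param pixel_size_um pixel size, um.
#' @param length_um nominal line length, um (default 100); the segment must
#'   match within `length_tol`.
#' @param length_tol relative length tolerance (default 0.05).
#' @return One-row tibble: `n_crossings, line_length_um,
#'   crossings_per_100um`.
#' @export
line_crossings <- function(mask, line, pixel_size_um, length_um = 100,
                           length_tol = 0.05) {
  stopifnot(length(line) == 4L)
  len <- sqrt((line[3] - line[1])^2 + (line[4] - line[2])^2)
  if (abs(len - length_um) > length_tol * length_um) {
    abort(sprintf("line length %.2f um differs from nominal %g um.",
                  len, length_um))
  }
  n_steps <- max(2L, ceiling(len / pixel_size_um) + 1L)
  t <- seq(0, 1, length.out = n_steps)
  xi <- floor((line[1] + t * (line[3] - line[1])) / pixel_size_um) + 1L
  yi <- floor((line[2] + t * (line[4] - line[2])) / pixel_size_um) + 1L
  if (any(xi < 1L | xi > nrow(mask) | yi < 1L | yi > ncol(mask))) {
    abort("line outside image.")
  }
  on <- mask[cbind(xi, yi)]
  r <- rle(on)
  n_runs <- sum(r$values)
  tibble(n_crossings = as.integer(n_runs), line_length_um = len,
         crossings_per_100um = n_runs / len * 100)
}

#' Partition a field into lesion, perilesion band and outside
#'
#' The perilesion compartment is the band of pixels outside the lesion
#' whose Euclidean distance to the lesion border is at most `band_um`
#' (default 150 um); the remainder is "outside". Masks are mutually
#' exclusive and jointly cover the field. Distances are physical um via a
#' Euclidean distance transform.
#'
#' @param lesion_mask non-empty logical matrix `[x, y]`.
#' @param pixel_size_um pixel size, um.
#' @param band_um perilesion band width, um (default 150).
#' @return A `synq_partition`: list of logical masks `lesion, perilesion,
#'   outside` plus `band_um` and `pixel_size_um`. `tidy()` gives per-
#'   compartment pixel counts and areas.
#' @export
perilesion_partition <- function(lesion_mask, pixel_size_um,
                                 band_um = 150) {
  if (!any(lesion_mask)) abort("empty lesion mask.")
  check_num(band_um, "band_um", min = 0, allow_zero = FALSE)
  d <- EBImage::distmap(1 - lesion_mask) * pixel_size_um
  lesion <- lesion_mask
  perilesion <- !lesion & d <= band_um
  outside <- !lesion & !perilesion
  structure(list(lesion = lesion, perilesion = perilesion,
                 outside = outside, band_um = band_um,
                 pixel_size_um = pixel_size_um),
            class = "synq_partition")
}

#' @export
print.synq_partition <- function(x, ...) {
  cat(sprintf("<synq_partition> %g um band; lesion %d px, perilesion %d px, outside %d px\n",
              x$band_um, sum(x$lesion), sum(x$perilesion), sum(x$outside)))
  invisible(x)
}

#' @export
tidy.synq_partition <- function(x, ...) {
  tibble(compartment = c("lesion", "perilesion", "outside"),
         n_px = c(sum(x$lesion), sum(x$perilesion), sum(x$outside)),
         area_mm2 = c(sum(x$lesion), sum(x$perilesion), sum(x$outside)) *
           x$pixel_size_um^2 / 1e6)
}
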