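#' Simulate a 2-D field of cell bodies or fibers with ground truth
#'
#' `mode = "cells"` draws `n_objects` disks of radius `cell_radius_um` with
#' an enforced cap on the fraction of overlapping objects; the truth is the
#' exact count and the centers. `mode = "fibers"` draws `n_objects`
#' straight fibers (random orientation and offset, clipped to the field)
#' of width `fiber_width_um`; the truth records how many fibers properly
#' cross the stored query line (default: a horizontal 100 um segment
#' centered in the field), the quantity [line_crossings()] estimates.
#'
#' Explicit `cells` (tibble `x_um, y_um`) or `fibers` (tibble
#' `x0, y0, x1, y1`, um) override the random draw for constructed scenes.
#'
#' @param field_size_um numeric length-2 field extent, um.
#' @param pixel_size_um pixel size, um.
#' @param mode `"cells"` or `"fibers"`.
#' @param n_objects number of random objects when `cells`/`fibers` are not
#'   given.
#' @param cell_radius_um disk radius, um.
#' @param fiber_width_um rendered fiber width, um.
#' @param line query segment `c(x0, y0, x1, y1)` in um; default horizontal
#'   100 um centered in the field.
#' @param max_overlap_fraction cells mode: maximum tolerated fraction of
#'   disks that touch another disk; exceeded after resampling -> error.
#' @param peak_intensity,background_level,gaussian_noise_sd intensity model.
#' @param cells,fibers optional explicit object tables (see above).
#' @param seed integer RNG seed.
#'
#' @return `list(image = matrix [x, y] with attrs, truth = list(...))`;
#'   for fibers the truth holds `n_crossings` and the query `line`.
#' @export
simulate_field <- function(field_size_um = c(150, 150),
                           pixel_size_um = 0.5,
                           mode = c("cells", "fibers"),
                           n_objects = 20,
                           cell_radius_um = 5,
                           fiber_width_um = 1,
                           line = NULL,
                           max_overlap_fraction = 0.1,
                           peak_intensity = 100,
                           background_level = 5,
                           gaussian_noise_sd = 0,
                           cells = NULL, fibers = NULL,
                           seed = 1L) {
  mode <- match.arg(mode)
  fx <- field_size_um[1]
  fy <- field_size_um[2]
  if (is.null(line)) {
    line <- c(fx / 2 - 50, fy / 2, fx / 2 + 50, fy / 2)
  }
  nx <- floor(fx / pixel_size_um)
  ny <- floor(fy / pixel_size_um)
  with_seed(seed, {
    img <- matrix(0, nx, ny)
    if (mode == "cells") {
      if (is.null(cells)) {
        r <- cell_radius_um
        for (try in 1:50) {
          cx <- runif(n_objects, r, fx - r)
          cy <- runif(n_objects, r, fy - r)
          d <- as.matrix(stats::dist(cbind(cx, cy)))
          diag(d) <- Inf
          overl <- mean(apply(d < 2 * r, 1, any))
          if (overl <= max_overlap_fraction) break
          if (try == 50) {
            abort("overlapping-object fraction above configured limit.")
          }
        }
        cells <- tibble(x_um = cx, y_um = cy)
      }
      xs <- (seq_len(nx) - 0.5) * pixel_size_um
      ys <- (seq_len(ny) - 0.5) * pixel_size_um
      for (p in seq_len(nrow(cells))) {
        d2 <- outer((xs - cells$x_um[p])^2, (ys - cells$y_um[p])^2, `+`)
        img[d2 <= cell_radius_um^2] <- peak_intensity
      }
      truth <- list(mode = "cells", cells = cells, n_cells = nrow(cells),
                    field_size_um = field_size_um,
                    field_area_mm2 = fx * fy / 1e6)
    } else {
      if (is.null(fibers)) {
        diag_len <- sqrt(fx^2 + fy^2)
        th <- runif(n_objects, 0, pi)
        mx <- runif(n_objects, 0, fx)
        my <- runif(n_objects, 0, fy)
        fibers <- tibble(
          x0 = mx - cos(th) * diag_len, y0 = my - sin(th) * diag_len,
          x1 = mx + cos(th) * diag_len, y1 = my + sin(th) * diag_len)
      }
      xs <- (seq_len(nx) - 0.5) * pixel_size_um
      ys <- (seq_len(ny) - 0.5) * pixel_size_um
      for (p in seq_len(nrow(fibers))) {
        img <- pmax(img, peak_intensity *
                      (seg_dist_grid(xs, ys, fibers$x0[p], fibers$y0[p],
                                     fibers$x1[p], fibers$y1[p]) <=
                         fiber_width_um / 2))
      }
      ncross <- sum(vapply(seq_len(nrow(fibers)), function(p) {
        segments_cross(fibers$x0[p], fibers$y0[p], fibers$x1[p],
                       fibers$y1[p], line[1], line[2], line[3], line[4])
      }, logical(1)))
      truth <- list(mode = "fibers", fibers = fibers, line = line,
                    n_crossings = ncross, field_size_um = field_size_um)
    }
    img <- img + background_level
    if (gaussian_noise_sd > 0) {
      img[] <- img + rnorm(length(img), 0, gaussian_noise_sd)
    }
    attr(img, "pixel_size_um") <- pixel_size_um
    list(image = img, truth = truth)
  })
}

# distance from every grid point to a segment
seg_dist_grid <- function(xs, ys, x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  len2 <- dx^2 + dy^2
  px <- matrix(xs, length(xs), length(ys))
  py <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  t <- pmin(pmax(((px - x0) * dx + (py - y0) * dy) / len2, 0), 1)
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}

# proper segment intersection (shared endpoints / collinear overlap do not
# count as a crossing; a fiber running along the line is tangent, not a
# crossing)
segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  orient <- function(px, py, qx, qy, rx, ry) {
    v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
    sign(v)
  }
  o1 <- orient(ax, ay, bx, by, cx, cy)
  o2 <- orient(ax, ay, bx, by, dx, dy)
  o3 <- orient(cx, cy, dx, dy, ax, ay)
  o4 <- orient(cx, cy, dx, dy, bx, by)
  (o1 * o2 < 0) && (o3 * o4 < 0)
}
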