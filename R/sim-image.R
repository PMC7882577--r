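#' Ground truth attached to simulated data
#'
#' Holds true object centers per channel (physical um), true pre/post pairs,
#' flicker artifacts (single-section objects), and the derived true
#' densities. Returned by all simulators; consumed by recovery tests.
#'
#' @name synq_truth
NULL

new_truth <- function(centers, pairs, flickers, field_size_um, depth_um) {
  vol <- prod(field_size_um) * depth_um
  n_ch <- vapply(centers, nrow, integer(1))
  dens <- tibble(channel = names(centers), n = n_ch,
                 true_density_per_mm3 = n_ch / vol * 1e9)
  structure(list(
    centers = centers,
    pairs = pairs,
    flickers = flickers,
    field_size_um = field_size_um,
    depth_um = depth_um,
    volume_um3 = vol,
    densities = dens,
    paired_density_per_mm3 = nrow(pairs) / vol * 1e9),
    class = "synq_truth")
}

#' @export
print.synq_truth <- function(x, ...) {
  cat(sprintf(
    "<synq_truth> %s in %.3g um^3; %d pairs (%.3g /mm^3); %d flickers\n",
    paste(sprintf("%s: %d", names(x$centers),
                  vapply(x$centers, nrow, integer(1))), collapse = ", "),
    x$volume_um3, nrow(x$pairs), x$paired_density_per_mm3,
    nrow(x$flickers)))
  invisible(x)
}

# draw puncta centers for all channels; channels 1 and 2 act as pre/post for
# colocalization. Every RNG call is ordered deterministically.
place_centers <- function(cfg, depth_um) {
  fx <- cfg$field_size_um[1]
  fy <- cfg$field_size_um[2]
  vol <- fx * fy * depth_um
  n_vox <- floor(fx / cfg$pixel_size_um) * floor(fy / cfg$pixel_size_um) *
    cfg$n_sections
  ch <- cfg$channels
  counts <- rpois(nrow(ch), ch$puncta_density_per_mm3 * vol / 1e9)
  if (any(counts > n_vox)) {
    abort("field too small to place requested puncta count.")
  }
  runif3 <- function(n) {
    cbind(runif(n, 0, fx), runif(n, 0, fy), runif(n, 0, depth_um))
  }
  centers <- vector("list", nrow(ch))
  names(centers) <- ch$name
  pairs <- tibble(pre_id = integer(), post_id = integer())
  # pre channel
  pre_xyz <- runif3(counts[1])
  centers[[1]] <- tibble(id = seq_len(counts[1]),
                         x_um = pre_xyz[, 1], y_um = pre_xyz[, 2],
                         z_um = pre_xyz[, 3])
  if (nrow(ch) >= 2L) {
    n_pre <- counts[1]
    n_paired <- round(cfg$colocalization_fraction * n_pre)
    paired_pre <- if (n_paired > 0) sort(sample.int(n_pre, n_paired)) else integer()
    # post partner = pre center + isotropic Gaussian offset, resampled until
    # inside the field so truth coordinates always lie in the stated extent
    ppos <- pre_xyz[paired_pre, , drop = FALSE]
    if (n_paired > 0 && cfg$pair_offset_sd_um > 0) {
      out <- ppos + matrix(rnorm(3 * n_paired, 0, cfg$pair_offset_sd_um),
                           ncol = 3)
      bad <- which(out[, 1] < 0 | out[, 1] > fx | out[, 2] < 0 |
                     out[, 2] > fy | out[, 3] < 0 | out[, 3] > depth_um)
      while (length(bad) > 0) {
        out[bad, ] <- ppos[bad, , drop = FALSE] +
          matrix(rnorm(3 * length(bad), 0, cfg$pair_offset_sd_um), ncol = 3)
        bad <- which(out[, 1] < 0 | out[, 1] > fx | out[, 2] < 0 |
                       out[, 2] > fy | out[, 3] < 0 | out[, 3] > depth_um)
      }
      ppos <- out
    }
    n_extra <- max(counts[2] - n_paired, 0L)
    extra <- runif3(n_extra)
    post_xyz <- rbind(ppos, extra)
    centers[[2]] <- tibble(id = seq_len(nrow(post_xyz)),
                           x_um = post_xyz[, 1], y_um = post_xyz[, 2],
                           z_um = post_xyz[, 3])
    pairs <- tibble(pre_id = paired_pre, post_id = seq_len(n_paired))
    if (nrow(ch) > 2L) {
      for (c in 3:nrow(ch)) {
        xyz <- runif3(counts[c])
        centers[[c]] <- tibble(id = seq_len(counts[c]), x_um = xyz[, 1],
                               y_um = xyz[, 2], z_um = xyz[, 3])
      }
    }
  }
  list(centers = centers, pairs = pairs)
}

# add a Gaussian blob footprint to one 2-D section (in place via return)
add_blob <- function(section, cx_um, cy_um, amp, sigma_um, px) {
  if (amp <= 0) return(section)
  nx <- nrow(section)
  ny <- ncol(section)
  half <- ceiling(4 * sigma_um / px)
  ci <- cx_um / px + 0.5            # fractional pixel index of the center
  cj <- cy_um / px + 0.5
  i0 <- max(1L, floor(ci) - half)
  i1 <- min(nx, floor(ci) + half)
  j0 <- max(1L, floor(cj) - half)
  j1 <- min(ny, floor(cj) + half)
  if (i0 > i1 || j0 > j1) return(section)
  gx <- exp(-((i0:i1 - 0.5) * px - cx_um)^2 / (2 * sigma_um^2))
  gy <- exp(-((j0:j1 - 0.5) * px - cy_um)^2 / (2 * sigma_um^2))
  section[i0:i1, j0:j1] <- section[i0:i1, j0:j1] + amp * outer(gx, gy)
  section
}

apply_noise <- function(arr, cfg) {
  arr <- arr + cfg$background_level
  if (cfg$poisson_noise) {
    arr[] <- rpois(length(arr), pmax(arr, 0))
  }
  if (cfg$gaussian_noise_sd > 0) {
    arr[] <- arr + rnorm(length(arr), 0, cfg$gaussian_noise_sd)
  }
  arr
}

#' Simulate a two-channel confocal puncta stack with ground truth
#'
#' Places Poisson-distributed puncta per channel in the physical field,
#' gives a controlled fraction of pre puncta a post partner at a Gaussian
#' center offset, renders each punctum as a Gaussian blob (object size and
#' PSF combined analytically), and adds Poisson shot noise plus Gaussian
#' read noise over a constant background. Identical config + seed gives
#' bit-identical output.
#'
#' @param cfg a [sim_image_config()].
#' @return `list(stack = synq_stack, truth = synq_truth)`.
#' @export
simulate_puncta_stack <- function(cfg) {
  stopifnot(inherits(cfg, "sim_image_config"))
  with_seed(cfg$seed, {
    depth <- cfg$n_sections * cfg$z_step_um
    placed <- place_centers(cfg, depth)
    nx <- floor(cfg$field_size_um[1] / cfg$pixel_size_um)
    ny <- floor(cfg$field_size_um[2] / cfg$pixel_size_um)
    nz <- cfg$n_sections
    arr <- array(0, c(nx, ny, nz, nrow(cfg$channels)))
    zk <- (seq_len(nz) - 0.5) * cfg$z_step_um
    for (c in seq_len(nrow(cfg$channels))) {
      chp <- cfg$channels[c, ]
      s_xy <- sqrt((chp$punctum_radius_um / 2)^2 + chp$psf_sigma_xy_um^2)
      s_z <- sqrt((chp$punctum_radius_um / 2)^2 + chp$psf_sigma_z_um^2)
      cen <- placed$centers[[c]]
      for (p in seq_len(nrow(cen))) {
        ks <- which(abs(zk - cen$z_um[p]) <= 4 * s_z)
        for (k in ks) {
          amp <- chp$peak_intensity *
            exp(-(zk[k] - cen$z_um[p])^2 / (2 * s_z^2))
          arr[, , k, c] <- add_blob(arr[, , k, c], cen$x_um[p], cen$y_um[p],
                                    amp, s_xy, cfg$pixel_size_um)
        }
      }
    }
    arr <- apply_noise(arr, cfg)
    truth <- new_truth(placed$centers, placed$pairs,
                       tibble(channel = character(), x_um = numeric(),
                              y_um = numeric(), z_um = numeric(),
                              section = integer()),
                       cfg$field_size_um, depth)
    list(stack = synq_stack(arr, cfg$pixel_size_um, cfg$z_step_um,
                            cfg$channels$name, mode = "confocal"),
         truth = truth)
  })
}

#' Simulate an array-tomography section series with ground truth
#'
#' Each 3-D punctum (z-extent = center +/- radius) is rendered only on the
#' physical sections its extent intersects, with intensity scaled by the
#' overlapped fraction of each 70 nm slab; there is no optical z-blur
#' across sections. Flicker artifacts — the single-section noise class the
#' persistence filter removes — are added at `flicker_density_per_mm3`
#' (default 10% of the first channel's puncta density) and recorded
#' separately in the truth.
#'
#' @param cfg a [sim_image_config()]; `n_sections` must be at least 2 or
#'   the downstream persistence filter is undefined.
#' @return `list(stack = synq_stack, truth = synq_truth)`.
#' @export
simulate_section_series <- function(cfg) {
  stopifnot(inherits(cfg, "sim_image_config"))
  if (cfg$n_sections < 2L) {
    abort("n_sections must be >= 2 (persistence filter undefined otherwise).")
  }
  with_seed(cfg$seed, {
    th <- cfg$section_thickness_um
    depth <- cfg$n_sections * th
    placed <- place_centers(cfg, depth)
    nx <- floor(cfg$field_size_um[1] / cfg$pixel_size_um)
    ny <- floor(cfg$field_size_um[2] / cfg$pixel_size_um)
    nz <- cfg$n_sections
    arr <- array(0, c(nx, ny, nz, nrow(cfg$channels)))
    flick_dens <- cfg$flicker_density_per_mm3 %||%
      (0.1 * cfg$channels$puncta_density_per_mm3[1])
    vol <- prod(cfg$field_size_um) * depth
    flickers <- tibble(channel = character(), x_um = numeric(),
                       y_um = numeric(), z_um = numeric(),
                       section = integer())
    for (c in seq_len(nrow(cfg$channels))) {
      chp <- cfg$channels[c, ]
      s_xy <- sqrt((chp$punctum_radius_um / 2)^2 + chp$psf_sigma_xy_um^2)
      r <- chp$punctum_radius_um
      cen <- placed$centers[[c]]
      for (p in seq_len(nrow(cen))) {
        z0 <- cen$z_um[p] - r
        z1 <- cen$z_um[p] + r
        ks <- which(seq_len(nz) * th > z0 & (seq_len(nz) - 1L) * th < z1)
        for (k in ks) {
          # fraction of this slab covered by the punctum's z-extent
          ov <- (min(z1, k * th) - max(z0, (k - 1L) * th)) / th
          arr[, , k, c] <- add_blob(arr[, , k, c], cen$x_um[p], cen$y_um[p],
                                    chp$peak_intensity * min(ov, 1), s_xy,
                                    cfg$pixel_size_um)
        }
      }
      n_fl <- rpois(1, flick_dens * vol / 1e9)
      if (n_fl > 0) {
        fx <- runif(n_fl, 0, cfg$field_size_um[1])
        fy <- runif(n_fl, 0, cfg$field_size_um[2])
        fk <- sample.int(nz, n_fl, replace = TRUE)
        for (p in seq_len(n_fl)) {
          arr[, , fk[p], c] <- add_blob(arr[, , fk[p], c], fx[p], fy[p],
                                        chp$peak_intensity, s_xy,
                                        cfg$pixel_size_um)
        }
        flickers <- dplyr::bind_rows(flickers, tibble(
          channel = chp$name, x_um = fx, y_um = fy,
          z_um = (fk - 0.5) * th, section = as.integer(fk)))
      }
    }
    arr <- apply_noise(arr, cfg)
    truth <- new_truth(placed$centers, placed$pairs, flickers,
                       cfg$field_size_um, depth)
    list(stack = synq_stack(arr, cfg$pixel_size_um, th,
                            cfg$channels$name, mode = "array_tomography"),
         truth = truth)
  })
}

#' Write / read ground truth as JSON
#'
#' @param truth a `synq_truth`.
#' @param path JSON path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` a
#'   `synq_truth`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    centers = truth$centers, pairs = truth$pairs, flickers = truth$flickers,
    field_size_um = truth$field_size_um, depth_um = truth$depth_um),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- purrr::map(x$centers, as_tibble)
  new_truth(centers, as_tibble(x$pairs), as_tibble(x$flickers),
            x$field_size_um, x$depth_um)
}
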