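#' Build a grid of neuropil regions of interest
#'
#' Tiles the field with non-overlapping axis-aligned `roi_size_um` x
#' `roi_size_um` boxes (floor arithmetic: a 184.58 um field gives 18 x 18 =
#' 324 ROIs at the default 10 um) and drops ROIs overlapping an exclusion
#' mask (cell bodies, blood vessels) beyond `max_excluded_fraction`
#' (default: any overlap drops the ROI). The analyzed volume is the kept
#' ROI area times the stack depth.
#'
#' @param field_extent_um numeric length-2 field extent, um.
#' @param depth_um analyzed stack depth, um.
#' @param exclusion_mask optional logical matrix `[x, y]` marking excluded
#'   pixels; requires `pixel_size_um` and must match the field extent.
#' @param pixel_size_um pixel size of `exclusion_mask`, um.
#' @param roi_size_um ROI side length, um (default 10).
#' @param max_excluded_fraction maximum tolerated excluded-pixel fraction
#'   inside a kept ROI (default 0 = any overlap drops it).
#'
#' @return A `synq_roi_grid`: list with `rois` (tibble `roi_id, x0, y0, x1,
#'   y1, excluded_fraction, kept`), `roi_size_um`, `depth_um`,
#'   `analyzed_volume_um3`.
#' @export
make_neuropil_rois <- function(field_extent_um, depth_um,
                               exclusion_mask = NULL, pixel_size_um = NULL,
                               roi_size_um = 10,
                               max_excluded_fraction = 0) {
  stopifnot(length(field_extent_um) == 2L)
  check_num(roi_size_um, "roi_size_um", min = 0, allow_zero = FALSE)
  check_num(depth_um, "depth_um", min = 0, allow_zero = FALSE)
  if (roi_size_um > min(field_extent_um)) {
    abort("roi_size_um exceeds the field extent.")
  }
  nx <- floor(field_extent_um[1] / roi_size_um)
  ny <- floor(field_extent_um[2] / roi_size_um)
  g <- tidyr::expand_grid(ix = seq_len(nx), iy = seq_len(ny))
  rois <- tibble(
    roi_id = seq_len(nrow(g)),
    x0 = (g$ix - 1) * roi_size_um, x1 = g$ix * roi_size_um,
    y0 = (g$iy - 1) * roi_size_um, y1 = g$iy * roi_size_um)
  if (!is.null(exclusion_mask)) {
    if (is.null(pixel_size_um)) {
      abort("`pixel_size_um` is required with an exclusion mask.")
    }
    expect_dim <- c(floor(field_extent_um[1] / pixel_size_um),
                    floor(field_extent_um[2] / pixel_size_um))
    if (!all(dim(exclusion_mask) == expect_dim)) {
      abort("exclusion mask shape does not match the field extent.")
    }
    xs <- (seq_len(nrow(exclusion_mask)) - 0.5) * pixel_size_um
    ys <- (seq_len(ncol(exclusion_mask)) - 0.5) * pixel_size_um
    rois$excluded_fraction <- vapply(seq_len(nrow(rois)), function(r) {
      ii <- which(xs >= rois$x0[r] & xs < rois$x1[r])
      jj <- which(ys >= rois$y0[r] & ys < rois$y1[r])
      if (length(ii) == 0 || length(jj) == 0) return(0)
      mean(exclusion_mask[ii, jj])
    }, numeric(1))
  } else {
    rois$excluded_fraction <- 0
  }
  rois$kept <- rois$excluded_fraction <= max_excluded_fraction
  structure(list(
    rois = rois,
    roi_size_um = roi_size_um,
    depth_um = depth_um,
    field_extent_um = field_extent_um,
    analyzed_volume_um3 = sum(rois$kept) * roi_size_um^2 * depth_um),
    class = "synq_roi_grid")
}

#' @export
print.synq_roi_grid <- function(x, ...) {
  cat(sprintf("<synq_roi_grid> %d/%d ROIs kept (%g um boxes), %.4g um^3 analyzed\n",
              sum(x$rois$kept), nrow(x$rois), x$roi_size_um,
              x$analyzed_volume_um3))
  invisible(x)
}

#' Pair pre- and post-synaptic objects by center distance
#'
#' Declares a putative structural synapse where a pre and a post punctum
#' have centers within `max_dist_um` (1 um for human material, 0.5 um for
#' mouse). Default matching is greedy one-to-one: candidate cross-channel
#' pairs within the radius are sorted by ascending distance (ties broken by
#' pre then post id) and accepted iff neither object is already used, which
#' prevents one punctum from being counted against many partners.
#' `mode = "any_within"` instead accepts every candidate pair, for
#' sensitivity analysis.
#'
#' @param pre,post `synq_objects` tibbles (or any tibble with `id` and
#'   `centroid_x_um/_y_um/_z_um`) in the same physical frame.
#' @param max_dist_um maximum center distance, um; must be > 0.
#' @param mode `"one_to_one"` (default) or `"any_within"`.
#' @return A tibble of class `synq_pairing` (`pre_id, post_id,
#'   distance_um`), with attributes `unmatched_pre`, `unmatched_post`,
#'   `max_dist_um`, `mode`.
#' @export
pair_puncta <- function(pre, post, max_dist_um,
                        mode = c("one_to_one", "any_within")) {
  mode <- match.arg(mode)
  check_num(max_dist_um, "max_dist_um", min = 0, allow_zero = FALSE)
  cand <- cross_candidates(pre, post, max_dist_um)
  if (mode == "one_to_one" && nrow(cand) > 0) {
    cand <- cand[order(cand$distance_um, cand$pre_id, cand$post_id), ]
    pid <- match(cand$pre_id, pre$id)
    qid <- match(cand$post_id, post$id)
    used_pre <- logical(nrow(pre))
    used_post <- logical(nrow(post))
    take <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!used_pre[pid[i]] && !used_post[qid[i]]) {
        used_pre[pid[i]] <- TRUE
        used_post[qid[i]] <- TRUE
        take[i] <- TRUE
      }
    }
    cand <- cand[take, ]
  }
  pairs <- as_tibble(cand)
  structure(pairs,
            class = c("synq_pairing", class(pairs)),
            unmatched_pre = setdiff(pre$id, pairs$pre_id),
            unmatched_post = setdiff(post$id, pairs$post_id),
            max_dist_um = max_dist_um, mode = mode)
}

# all cross-channel pairs within radius, blocked to bound memory
cross_candidates <- function(pre, post, max_dist_um) {
  if (nrow(pre) == 0L || nrow(post) == 0L) {
    return(tibble(pre_id = integer(), post_id = integer(),
                  distance_um = numeric()))
  }
  a <- cbind(pre$centroid_x_um, pre$centroid_y_um, pre$centroid_z_um)
  b <- cbind(post$centroid_x_um, post$centroid_y_um, post$centroid_z_um)
  blocks <- split(seq_len(nrow(a)),
                  ceiling(seq_len(nrow(a)) / max(1L, 2e6 %/% nrow(b))))
  purrr::map_dfr(blocks, function(ii) {
    d2 <- outer(a[ii, 1], b[, 1], `-`)^2 +
      outer(a[ii, 2], b[, 2], `-`)^2 +
      outer(a[ii, 3], b[, 3], `-`)^2
    hit <- which(d2 <= max_dist_um^2, arr.ind = TRUE)
    tibble(pre_id = pre$id[ii[hit[, 1L]]],
           post_id = post$id[hit[, 2L]],
           distance_um = sqrt(d2[hit]))
  })
}

#' Volumetric synapse and puncta densities over an ROI grid
#'
#' Counts pairs whose *pre* centroid lies inside a kept ROI (the
#' deterministic ownership rule) and each channel's puncta likewise, then
#' converts counts to per-mm3 densities: `count / analyzed_volume_um3 *
#' 1e9`. Per-ROI and aggregate values are returned.
#'
#' @param pairing a [pair_puncta()] result.
#' @param objects_by_channel named list of `synq_objects` tibbles; the
#'   first entry must be the pre channel used in the pairing.
#' @param grid a [make_neuropil_rois()] grid with `analyzed_volume_um3 > 0`.
#' @return A `synq_density`: list with one-row `summary`
#'   (`synapse_density_per_mm3`, `<channel>_per_mm3`, `n_pairs`,
#'   `analyzed_volume_um3`) and `per_roi` tibble. `tidy()` returns
#'   `per_roi`; `glance()` the summary.
#' @export
compute_densities <- function(pairing, objects_by_channel, grid) {
  stopifnot(inherits(grid, "synq_roi_grid"))
  if (grid$analyzed_volume_um3 <= 0) abort("zero analyzed volume.")
  kept <- grid$rois[grid$rois$kept, ]
  roi_of <- function(x, y) {
    # ROIs are disjoint; at most one match per point
    idx <- rep(NA_integer_, length(x))
    for (r in seq_len(nrow(kept))) {
      sel <- x >= kept$x0[r] & x < kept$x1[r] &
        y >= kept$y0[r] & y < kept$y1[r]
      idx[sel] <- kept$roi_id[r]
    }
    idx
  }
  pre <- objects_by_channel[[1L]]
  pre_roi <- roi_of(pre$centroid_x_um, pre$centroid_y_um)
  pair_roi <- pre_roi[match(pairing$pre_id, pre$id)]
  roi_vol <- grid$roi_size_um^2 * grid$depth_um
  per_roi <- tibble(roi_id = kept$roi_id)
  per_roi$n_pairs <- as.integer(table(factor(pair_roi,
                                             levels = kept$roi_id)))
  per_roi$synapse_density_per_mm3 <- per_roi$n_pairs / roi_vol * 1e9
  summary <- tibble(
    n_pairs = sum(per_roi$n_pairs),
    synapse_density_per_mm3 = sum(per_roi$n_pairs) /
      grid$analyzed_volume_um3 * 1e9,
    analyzed_volume_um3 = grid$analyzed_volume_um3)
  for (ch in names(objects_by_channel)) {
    ob <- objects_by_channel[[ch]]
    in_roi <- roi_of(ob$centroid_x_um, ob$centroid_y_um)
    cnt <- as.integer(table(factor(in_roi, levels = kept$roi_id)))
    per_roi[[paste0("n_", ch)]] <- cnt
    per_roi[[paste0(ch, "_per_mm3")]] <- cnt / roi_vol * 1e9
    summary[[paste0(ch, "_per_mm3")]] <- sum(cnt) /
      grid$analyzed_volume_um3 * 1e9
  }
  structure(list(summary = summary, per_roi = per_roi, grid = grid),
            class = "synq_density")
}

#' @export
print.synq_density <- function(x, ...) {
  cat("<synq_density>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.synq_density <- function(x, ...) x$per_roi

#' @export
glance.synq_density <- function(x, ...) x$summary
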