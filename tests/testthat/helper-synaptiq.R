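# shared fixtures and independent oracles for the test suite

# a small, fast image config; overrides via ...
tiny_image_config <- function(...) {
  sim_image_config(field_size_um = c(10, 10), ...)
}

# independent per-pixel local-threshold oracle: explicit window loops,
# no integral images
oracle_local_threshold <- function(img, r, method = "niblack", k = 3,
                                   offset = 0) {
  nx <- nrow(img)
  ny <- ncol(img)
  out <- matrix(FALSE, nx, ny)
  tol <- 1e-9 * (max(abs(img)) + 1)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      win <- img[max(1, i - r):min(nx, i + r),
                 max(1, j - r):min(ny, j + r)]
      thr <- if (method == "niblack") {
        m <- mean(win)
        v <- mean(win^2) - m^2
        m + k * sqrt(max(v, 0))
      } else {
        mean(win) + offset
      }
      out[i, j] <- img[i, j] > thr + tol
    }
  }
  out
}

# independent brute-force greedy one-to-one pairing on raw coordinates:
# repeatedly pick the globally closest unused cross pair within radius
oracle_greedy_pairs <- function(a, b, max_dist) {
  pairs <- NULL
  used_a <- logical(nrow(a))
  used_b <- logical(nrow(b))
  d <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2 +
    outer(a[, 3], b[, 3], `-`)^2
  d <- sqrt(d)
  repeat {
    d_av <- d
    d_av[used_a, ] <- Inf
    d_av[, used_b] <- Inf
    hits <- which(d_av <= max_dist, arr.ind = TRUE)
    if (nrow(hits) == 0) break
    dd <- d_av[hits]
    best <- hits[order(dd, hits[, 1], hits[, 2])[1], ]
    pairs <- rbind(pairs, c(best[1], best[2], d[best[1], best[2]]))
    used_a[best[1]] <- TRUE
    used_b[best[2]] <- TRUE
  }
  if (is.null(pairs)) {
    return(data.frame(pre = integer(), post = integer(), d = numeric()))
  }
  data.frame(pre = pairs[, 1], post = pairs[, 2], d = pairs[, 3])
}

# tibble of point objects in the shape pair_puncta() expects
as_objects <- function(xyz) {
  tibble::tibble(id = seq_len(nrow(xyz)),
                 centroid_x_um = xyz[, 1],
                 centroid_y_um = xyz[, 2],
                 centroid_z_um = xyz[, 3])
}

# greedy matching of detected to true onsets at a tolerance; returns counts
match_onsets <- function(true_s, det_s, tol_s = 0.002) {
  used <- logical(length(det_s))
  matched <- 0L
  for (o in true_s) {
    j <- which(!used & abs(det_s - o) <= tol_s)
    if (length(j) > 0) {
      used[j[1]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(matched = matched,
       recall = if (length(true_s) > 0) matched / length(true_s) else NA,
       precision = if (length(det_s) > 0) matched / length(det_s) else NA)
}

# independent check for "has >= k consecutive section indices"
oracle_has_run <- function(sections, k) {
  s <- sort(unique(sections))
  if (length(s) == 0) return(FALSE)
  best <- run <- 1
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      run <- if (s[i] == s[i - 1] + 1) run + 1 else 1
      best <- max(best, run)
    }
  }
  best >= k
}
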