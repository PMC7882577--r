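# internal helpers shared across modules

# scalar validators ---------------------------------------------------------

check_num <- function(x, name, min = NULL, max = NULL, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (!is.null(min) && (x < min || (!allow_zero && x == min))) {
    abort(sprintf("`%s` must be %s %s.", name,
                  if (allow_zero) ">=" else ">", format(min)))
  }
  if (!is.null(max) && x > max) {
    abort(sprintf("`%s` must be <= %s.", name, format(max)))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  check_num(x, name, min = 0, max = 1)
}

# seeded RNG: all generator randomness goes through this so that identical
# configs + seeds give bit-identical output while leaving the caller's RNG
# stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# union-find with path compression; closure-based, sized for the tens of
# thousands of per-section labels a stack produces
union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  union <- function(a, b) {
    ra <- find(a)
    rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    invisible(NULL)
  }
  roots <- function() vapply(seq_len(n), find, integer(1))
  list(find = find, union = union, roots = roots)
}

# longest run of consecutive integers in a (possibly unsorted) index set
max_consecutive_run <- function(idx) {
  if (length(idx) == 0L) return(0L)
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 1L) return(1L)
  r <- rle(diff(idx) == 1L)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) 1L else max(runs) + 1L
}

# integral-image window sums with clamped (shrinking) windows at the border;
# returns the sum of m over [i-r, i+r] x [j-r, j+r] for every pixel
box_sum <- function(m, r) {
  nx <- nrow(m)
  ny <- ncol(m)
  s <- apply(m, 2L, cumsum)
  if (nx == 1L) s <- matrix(s, nrow = 1L)
  s <- t(apply(s, 1L, cumsum))
  if (ny == 1L) s <- matrix(s, ncol = 1L)
  sp <- matrix(0, nx + 1L, ny + 1L)
  sp[-1L, -1L] <- s
  i0 <- pmax(seq_len(nx) - r, 1L)
  i1 <- pmin(seq_len(nx) + r, nx)
  j0 <- pmax(seq_len(ny) - r, 1L)
  j1 <- pmin(seq_len(ny) + r, ny)
  sp[i1 + 1L, j1 + 1L, drop = FALSE] -
    sp[i0, j1 + 1L, drop = FALSE] -
    sp[i1 + 1L, j0, drop = FALSE] +
    sp[i0, j0, drop = FALSE]
}

box_count <- function(nx, ny, r) {
  wi <- pmin(seq_len(nx) + r, nx) - pmax(seq_len(nx) - r, 1L) + 1L
  wj <- pmin(seq_len(ny) + r, ny) - pmax(seq_len(ny) - r, 1L) + 1L
  outer(wi, wj)
}
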