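#' Detect miniature PSCs by scaled template matching
#'
#' Slides the template along the trace and, at every lag, fits scale and
#' offset by least squares; the detection criterion is the fitted scale
#' divided by the standard deviation of the pointwise fit residual (the
#' conventional scaled-template criterion). Local maxima of the criterion
#' above `threshold` (typically 4-7) become candidate events; around every
#' accepted peak an asymmetric refractory window — one template rise time
#' before it, and after it the span until the template has decayed to 20%
#' of peak — absorbs weaker criterion maxima, which are echoes of the same
#' event on its own decay rather than new events. Candidates whose fitted,
#' baseline-subtracted peak amplitude fails to exceed 3x the SD of the
#' baseline noise (estimated from event-free stretches) are discarded.
#' Per-event charge is the integral of the baseline-subtracted current over
#' the event window.
#'
#' The trace is sign-flipped internally according to polarity so events are
#' always positive during matching; reported amplitudes and charges carry
#' the polarity sign (inward negative, outward positive). The criterion is
#' invariant to constant offsets and to positive rescaling of the trace.
#'
#' @param rec a [synq_recording()].
#' @param template a [make_template()] template, shorter than the trace.
#' @param threshold detection-criterion threshold; must be > 0 (4-7 in
#'   routine use, default 5).
#' @param polarity `"inward"` or `"outward"`; defaults to the recording's.
#' @param amplitude_sd_mult amplitude filter in baseline-noise SDs
#'   (default 3).
#' @param noise_estimator `"sd"` or `"mad"` for the baseline noise SD.
#' @param max_passes detection passes with template subtraction between
#'   them (default 3): after each pass the fitted events are subtracted
#'   from the working trace and the criterion is recomputed, which exposes
#'   events whose first-pass fit was contaminated by an overlapping
#'   neighbour in the template window. Passes stop early when no new event
#'   is found. `max_passes = 1` is plain single-pass matching.
#' @return A tibble of class `synq_events`: `onset_s, peak_amplitude_pA,
#'   criterion_value, charge_pC`, with attributes `baseline_sd_pA`,
#'   `threshold`, `polarity`, `duration_s`.
#' @export
detect_events <- function(rec, template, threshold = 5,
                          polarity = NULL,
                          amplitude_sd_mult = 3,
                          noise_estimator = c("sd", "mad"),
                          max_passes = 3L) {
  stopifnot(inherits(rec, "synq_recording"),
            inherits(template, "synq_template"))
  noise_estimator <- match.arg(noise_estimator)
  if (threshold <= 0) abort("threshold must be > 0.")
  check_num(max_passes, "max_passes", min = 1)
  polarity <- polarity %||% rec$polarity
  sgn <- if (polarity == "inward") -1 else 1
  y <- sgn * rec$current_pA
  w <- template$waveform
  L <- length(w)
  n <- length(y)
  if (L >= n) abort("template must be shorter than the trace.")
  fs <- rec$sampling_hz

  # refractory window: a weaker criterion peak from one rise time before an
  # accepted event up to where its template has decayed to 20% of peak is
  # part of that event (a "ghost" on the decay), not a new one
  sep_pre <- max(1L, round(template$rise_time_s * fs))
  i_pk <- which.max(abs(w))
  sep_post <- i_pk + max(which(abs(w[i_pk:L]) >= 0.2)) - 1L

  y_work <- y
  onsets <- integer(0)
  amp <- numeric(0)
  crit_at <- numeric(0)
  offset_at <- numeric(0)
  base_sd <- 0
  for (pass in seq_len(max_passes)) {
    cb <- cb_criterion(y_work, w)
    crit <- cb$criterion
    nl <- length(crit)
    up <- c(TRUE, crit[-1L] >= crit[-nl])
    down <- c(crit[-nl] > crit[-1L], TRUE)
    cand <- which(crit > threshold & up & down)
    # ghost suppression among this pass's candidates; previously accepted
    # events are already subtracted, but a residue echo right at an old
    # onset is blocked by the rise-time guard
    cand <- cand[order(crit[cand], decreasing = TRUE)]
    new <- integer(0)
    for (i in cand) {
      if (length(onsets) > 0 && any(abs(i - onsets) < sep_pre)) next
      if (length(new) > 0 && any(i > new - sep_pre & i < new + sep_post)) next
      new <- c(new, i)
    }
    if (pass == 1L) {
      # baseline noise from event-free stretches of the raw trace; first
      # differences keep slow drift out of the estimate
      free <- rep(TRUE, n)
      free[seq_len(nl)][crit > threshold] <- FALSE
      for (i in new) free[i:min(i + L - 1L, n)] <- FALSE
      dfree <- free[-1L] & free[-n]
      dy <- diff(y)
      base_sd <- if (sum(dfree) > 10) {
        if (noise_estimator == "sd") sd(dy[dfree]) / sqrt(2)
        else stats::mad(dy[dfree]) / sqrt(2)
      } else 0
    }
    keep <- cb$scale[new] >= amplitude_sd_mult * base_sd
    new <- new[keep]
    if (length(new) == 0L) break
    for (i in new) {
      win <- i:min(i + L - 1L, n)
      y_work[win] <- y_work[win] - cb$scale[i] * w[seq_along(win)]
    }
    onsets <- c(onsets, new)
    amp <- c(amp, cb$scale[new])
    crit_at <- c(crit_at, crit[new])
    offset_at <- c(offset_at, cb$offset[new])
  }
  ord <- order(onsets)
  onsets <- onsets[ord]
  amp <- amp[ord]
  crit_at <- crit_at[ord]
  offset_at <- offset_at[ord]

  # per-event charge on the decomposed trace: each event window integrates
  # its own fitted contribution plus unexplained residue, not neighbours
  resid <- y_work
  charge <- vapply(seq_along(onsets), function(e) {
    i <- onsets[e]
    win <- i:min(i + L - 1L, n)
    sum(amp[e] * w[seq_along(win)] + resid[win] - offset_at[e]) / fs
  }, numeric(1))

  ev <- tibble(
    onset_s = (onsets - 1L) / fs,
    peak_amplitude_pA = sgn * amp,
    criterion_value = crit_at,
    charge_pC = sgn * charge)
  structure(ev, class = c("synq_events", class(ev)),
            baseline_sd_pA = base_sd, threshold = threshold,
            polarity = polarity, duration_s = rec$duration_s)
}

# sliding least-squares fit of scale+offset template to the trace;
# O(n log n) via running sums and FFT cross-correlation
cb_criterion <- function(y, w) {
  n <- length(y)
  L <- length(w)
  nl <- n - L + 1L
  sw <- sum(w)
  sww <- sum(w^2)
  csy <- c(0, cumsum(y))
  csy2 <- c(0, cumsum(y^2))
  sy <- csy[(L + 1L):(n + 1L)] - csy[1L:nl]
  syy <- csy2[(L + 1L):(n + 1L)] - csy2[1L:nl]
  # cross-correlation sum_j y[i+j-1] w[j] for every lag i
  m <- stats::nextn(n + L, 2)
  fy <- fft(c(y, numeric(m - n)))
  fw <- fft(c(w, numeric(m - L)))
  swy <- Re(fft(fy * Conj(fw), inverse = TRUE))[1L:nl] / m
  denom <- sww - sw^2 / L
  scale <- (swy - sw * sy / L) / denom
  offset <- (sy - scale * sw) / L
  sse <- pmax(syy - offset * sy - scale * swy, 0)
  criterion <- scale / sqrt(pmax(sse, 1e-12) / (L - 1L))
  list(criterion = criterion, scale = scale, offset = offset)
}

#' Charge transferred by a current segment
#'
#' Time integral of the baseline-subtracted current: `sum(current -
#' baseline) / sampling_hz`, in picocoulombs (1 pA s = 1 pC). A rectangular
#' 10 pA step lasting 10 ms carries exactly 0.1 pC.
#'
#' @param current_pA current samples, pA.
#' @param sampling_hz sampling rate, Hz.
#' @param baseline_pA baseline to subtract (default 0).
#' @return Charge in pC.
#' @export
charge_transfer <- function(current_pA, sampling_hz, baseline_pA = 0) {
  check_num(sampling_hz, "sampling_hz", min = 0, allow_zero = FALSE)
  sum(current_pA - baseline_pA) / sampling_hz
}

#' Summarise detected miniature events
#'
#' Frequency = event count / duration; inter-event intervals from sorted
#' onsets; mean amplitude and total charge use magnitudes (polarity is a
#' sign convention, the reported quantities are sizes). Empty input gives
#' zeros and an empty interval list.
#'
#' @param events a [detect_events()] tibble (or any tibble with `onset_s`,
#'   `peak_amplitude_pA`, `charge_pC`).
#' @param duration_s analysis window, s; must be > 0. Defaults to the
#'   `duration_s` attribute of `events` when present.
#' @return One-row tibble of class `synq_ephys_summary`: `n_events,
#'   frequency_hz, mean_amplitude_pA, mean_iei_s, total_charge_pC,
#'   ieis_s` (list-column).
#' @export
summarize_events <- function(events, duration_s = NULL) {
  duration_s <- duration_s %||% attr(events, "duration_s")
  check_num(duration_s, "duration_s", min = 0, allow_zero = FALSE)
  n <- nrow(events)
  ieis <- if (n >= 2L) diff(sort(events$onset_s)) else numeric(0)
  out <- tibble(
    n_events = as.integer(n),
    frequency_hz = n / duration_s,
    mean_amplitude_pA = if (n > 0) mean(abs(events$peak_amplitude_pA)) else 0,
    mean_iei_s = if (length(ieis) > 0) mean(ieis) else NA_real_,
    total_charge_pC = if (n > 0) sum(abs(events$charge_pC)) else 0,
    ieis_s = list(ieis))
  class(out) <- c("synq_ephys_summary", class(out))
  out
}
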