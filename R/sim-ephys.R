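#' Voltage-clamp recording container
#'
#' A `synq_recording` bundles the current trace (pA) with its sampling rate,
#' polarity of interest and the quality-control metadata the rejection
#' rules need (holding current, series resistance before/after).
#'
#' @param current_pA numeric trace, pA.
#' @param sampling_hz sampling rate, Hz.
#' @param polarity `"inward"` (events deflect negative, e.g. mEPSC at
#'   -70 mV) or `"outward"` (e.g. mIPSC near 0 mV).
#' @param holding_current_pA,rs_before_mohm,rs_after_mohm QC metadata;
#'   `NA` when unknown.
#'
#' @return A `synq_recording` object.
#' @export
synq_recording <- function(current_pA, sampling_hz = 20000,
                           polarity = c("outward", "inward"),
                           holding_current_pA = NA_real_,
                           rs_before_mohm = NA_real_,
                           rs_after_mohm = NA_real_) {
  polarity <- match.arg(polarity)
  check_num(sampling_hz, "sampling_hz", min = 0, allow_zero = FALSE)
  structure(list(
    current_pA = as.numeric(current_pA),
    sampling_hz = sampling_hz,
    duration_s = length(current_pA) / sampling_hz,
    polarity = polarity,
    qc = list(holding_current_pA = holding_current_pA,
              rs_before_mohm = rs_before_mohm,
              rs_after_mohm = rs_after_mohm)),
    class = "synq_recording")
}

#' @export
print.synq_recording <- function(x, ...) {
  cat(sprintf("<synq_recording> %.1f s @ %g kHz, %s events of interest\n",
              x$duration_s, x$sampling_hz / 1000, x$polarity))
  invisible(x)
}

#' @export
as_tibble.synq_recording <- function(x, ...) {
  tibble(time_s = (seq_along(x$current_pA) - 1) / x$sampling_hz,
         current_pA = x$current_pA)
}

#' Simulate a miniature-PSC recording with ground truth
#'
#' Event onsets follow a Poisson process at `event_rate_hz`; each event
#' adds the unit-peak triexponential kernel scaled by a zero-truncated
#' normal amplitude, signed by polarity. Gaussian baseline noise and an
#' optional linear drift are added. Truth stores the onsets and the (always
#' positive) amplitudes.
#'
#' @param cfg a [sim_ephys_config()].
#' @return `list(recording = synq_recording, truth = list(onsets_s,
#'   amplitudes_pA, event_rate_hz, ...))`.
#' @export
simulate_mpsc_trace <- function(cfg) {
  stopifnot(inherits(cfg, "sim_ephys_config"))
  n <- round(cfg$duration_s * cfg$sampling_hz)
  tmpl <- make_template(cfg$tau_rise_ms, cfg$tau_decay1_ms,
                        cfg$tau_decay2_ms, cfg$decay_mix,
                        length_ms = cfg$kernel_ms,
                        sampling_hz = cfg$sampling_hz)
  L <- length(tmpl$waveform)
  if (L > n) abort("kernel longer than trace.")
  with_seed(cfg$seed, {
    n_ev <- rpois(1, cfg$event_rate_hz * cfg$duration_s)
    onsets <- sort(runif(n_ev, 0, cfg$duration_s - cfg$kernel_ms / 1000))
    amps <- numeric(n_ev)
    if (n_ev > 0) {
      amps <- rnorm(n_ev, cfg$amplitude_mean_pA, cfg$amplitude_sd_pA)
      bad <- which(amps <= 0)       # truncate at 0: no sign flips
      while (length(bad) > 0) {
        amps[bad] <- rnorm(length(bad), cfg$amplitude_mean_pA,
                           cfg$amplitude_sd_pA)
        bad <- which(amps <= 0)
      }
    }
    sign <- if (cfg$polarity == "inward") -1 else 1
    y <- numeric(n)
    on_idx <- pmin(floor(onsets * cfg$sampling_hz) + 1L, n - L + 1L)
    for (e in seq_len(n_ev)) {
      win <- on_idx[e]:(on_idx[e] + L - 1L)
      y[win] <- y[win] + sign * amps[e] * tmpl$waveform
    }
    if (cfg$baseline_noise_sd_pA > 0) {
      y <- y + rnorm(n, 0, cfg$baseline_noise_sd_pA)
    }
    if (cfg$drift_pA_per_s != 0) {
      y <- y + cfg$drift_pA_per_s * (seq_len(n) - 1) / cfg$sampling_hz
    }
    truth <- list(onsets_s = (on_idx - 1L) / cfg$sampling_hz,
                  amplitudes_pA = amps,
                  event_rate_hz = cfg$event_rate_hz,
                  kernel_integral_s = sum(tmpl$waveform) / cfg$sampling_hz,
                  total_charge_pC = sum(amps) * sum(tmpl$waveform) /
                    cfg$sampling_hz)
    list(recording = synq_recording(y, cfg$sampling_hz,
                                    polarity = cfg$polarity),
         truth = truth)
  })
}

#' Write / read a recording as 2-column CSV with a JSON QC sidecar
#'
#' The CSV has columns `time_s, current_pA`; sampling rate, polarity and QC
#' metadata go to `<path>.json`.
#'
#' @param rec a [synq_recording()].
#' @param path CSV path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   a [synq_recording()].
#' @export
write_recording <- function(rec, path) {
  readr::write_csv(as_tibble(rec), path)
  jsonlite::write_json(c(list(sampling_hz = rec$sampling_hz,
                              polarity = rec$polarity), rec$qc),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(sprintf("recording not found: %s", path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  synq_recording(df$current_pA, meta$sampling_hz, meta$polarity,
                 meta$holding_current_pA %||% NA_real_,
                 meta$rs_before_mohm %||% NA_real_,
                 meta$rs_after_mohm %||% NA_real_)
}
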