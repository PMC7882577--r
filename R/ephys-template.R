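#' Triexponential miniature-PSC template
#'
#' Builds the unit-peak waveform
#' `w(t) = N * (1 - exp(-t/tau_rise)) * (m * exp(-t/tau_d1) +
#' (1 - m) * exp(-t/tau_d2))`, the standard kinetic description of a
#' miniature postsynaptic current (single rise, double decay). `N` is
#' chosen so the peak magnitude is exactly 1. With `decay_mix = 1` the
#' biexponential special case has the closed-form peak time
#' `t* = tau_rise * log(1 + tau_d1 / tau_rise)`.
#'
#' A warning (not an error) is raised for slow-rise parameter sets
#' (`tau_rise >= min(tau_d1, tau_d2)`) and when the waveform has not
#' decayed below 1% of peak at the end of the window.
#'
#' @param tau_rise_ms,tau_decay1_ms,tau_decay2_ms time constants, ms; > 0.
#' @param decay_mix weight of the fast decay, in `[0, 1]`.
#' @param length_ms template window length, ms.
#' @param sampling_hz sampling rate, Hz.
#' @return A `synq_template`: list with `waveform` (unit peak),
#'   `peak_time_s`, `rise_time_s` (time to peak), the parameters and
#'   `sampling_hz`.
#' @export
make_template <- function(tau_rise_ms, tau_decay1_ms, tau_decay2_ms = tau_decay1_ms,
                          decay_mix = 1, length_ms = 60,
                          sampling_hz = 20000) {
  for (nm in c("tau_rise_ms", "tau_decay1_ms", "tau_decay2_ms")) {
    check_num(get(nm), nm, min = 0, allow_zero = FALSE)
  }
  check_fraction(decay_mix, "decay_mix")
  check_num(length_ms, "length_ms", min = 0, allow_zero = FALSE)
  if (tau_rise_ms >= min(tau_decay1_ms, tau_decay2_ms)) {
    warn("slow-rise template: tau_rise >= min(decay taus).")
  }
  t_ms <- seq(0, length_ms, by = 1000 / sampling_hz)
  w <- (1 - exp(-t_ms / tau_rise_ms)) *
    (decay_mix * exp(-t_ms / tau_decay1_ms) +
       (1 - decay_mix) * exp(-t_ms / tau_decay2_ms))
  pk <- max(abs(w))
  w <- w / pk
  if (abs(w[length(w)]) > 0.01) {
    warn("template has not decayed below 1% of peak at the window end.")
  }
  i_pk <- which.max(abs(w))
  structure(list(waveform = w,
                 peak_time_s = (i_pk - 1L) / sampling_hz,
                 rise_time_s = (i_pk - 1L) / sampling_hz,
                 tau_rise_ms = tau_rise_ms,
                 tau_decay1_ms = tau_decay1_ms,
                 tau_decay2_ms = tau_decay2_ms,
                 decay_mix = decay_mix,
                 length_ms = length_ms,
                 sampling_hz = sampling_hz),
            class = "synq_template")
}

#' @export
print.synq_template <- function(x, ...) {
  cat(sprintf(
    "<synq_template> rise %.2g ms, decay %.2g/%.2g ms (mix %.2f), %g ms @ %g kHz, peak at %.2f ms\n",
    x$tau_rise_ms, x$tau_decay1_ms, x$tau_decay2_ms, x$decay_mix,
    x$length_ms, x$sampling_hz / 1000, x$peak_time_s * 1000))
  invisible(x)
}
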