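#' Configuration for synthetic puncta images
#'
#' Defines the geometry, per-channel puncta statistics, noise model and seed
#' for [simulate_puncta_stack()] (confocal) and [simulate_section_series()]
#' (array tomography). Geometry defaults follow the acquisition this
#' pipeline targets — 0.0587 um pixels (a 184.58 um field at 3144 px),
#' 0.15 um optical z-step over a 2.1 um stack, and 0.07 um physical
#' sections for array tomography — at a desk-scale 30 um field.
#'
#' Puncta are modelled as isotropic Gaussian blobs (object sd =
#' `punctum_radius_um / 2`) convolved analytically with a Gaussian PSF, so
#' the rendered per-axis sd is `sqrt((r/2)^2 + psf_sigma^2)`. A fraction
#' `colocalization_fraction` of pre-channel puncta receives a post-channel
#' partner displaced by an isotropic Gaussian offset
#' (`pair_offset_sd_um` per axis); all remaining puncta are uniform in the
#' field. Flicker artifacts — objects confined to a single section, the
#' class the persistence filter removes — default to 10% of the puncta
#' density in array-tomography mode.
#'
#' @param field_size_um numeric length-2, x/y field extent in um.
#' @param pixel_size_um in-plane pixel size, um.
#' @param z_step_um confocal optical z-step, um.
#' @param section_thickness_um array-tomography section thickness, um.
#' @param n_sections number of sections / z-planes.
#' @param channels tibble with one row per channel: `name`,
#'   `puncta_density_per_mm3`, `punctum_radius_um`, `peak_intensity`,
#'   `psf_sigma_xy_um`, `psf_sigma_z_um`. Defaults give a pre and a post
#'   channel at 2.5e8 puncta/mm3.
#' @param colocalization_fraction fraction of pre puncta given a post
#'   partner, in `[0, 1]`.
#' @param pair_offset_sd_um per-axis sd of the pre-to-post center offset, um.
#' @param flicker_density_per_mm3 density of single-section artifacts;
#'   `NULL` = 10% of the first channel's puncta density (applies to
#'   section-series simulation only).
#' @param background_level constant background intensity (a.u.).
#' @param gaussian_noise_sd sd of additive Gaussian read noise (a.u.).
#' @param poisson_noise logical; apply Poisson shot noise to signal +
#'   background before read noise.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return A `sim_image_config` list.
#' @export
sim_image_config <- function(field_size_um = c(30, 30),
                             pixel_size_um = 0.0587,
                             z_step_um = 0.15,
                             section_thickness_um = 0.07,
                             n_sections = 14,
                             channels = NULL,
                             colocalization_fraction = 0.8,
                             pair_offset_sd_um = 0.1,
                             flicker_density_per_mm3 = NULL,
                             background_level = 20,
                             gaussian_noise_sd = 5,
                             poisson_noise = TRUE,
                             seed = 1L) {
  if (is.null(channels)) {
    channels <- tibble(
      name = c("pre", "post"),
      puncta_density_per_mm3 = 2.5e8,
      punctum_radius_um = 0.2,
      peak_intensity = 150,
      psf_sigma_xy_um = 0.06,
      psf_sigma_z_um = 0.15)
  }
  stopifnot(length(field_size_um) == 2L)
  check_num(field_size_um[1], "field_size_um[1]", min = 0, allow_zero = FALSE)
  check_num(field_size_um[2], "field_size_um[2]", min = 0, allow_zero = FALSE)
  check_num(pixel_size_um, "pixel_size_um", min = 0, allow_zero = FALSE)
  check_num(z_step_um, "z_step_um", min = 0, allow_zero = FALSE)
  check_num(section_thickness_um, "section_thickness_um",
            min = 0, allow_zero = FALSE)
  check_num(n_sections, "n_sections", min = 1)
  check_fraction(colocalization_fraction, "colocalization_fraction")
  check_num(pair_offset_sd_um, "pair_offset_sd_um", min = 0)
  check_num(background_level, "background_level", min = 0)
  check_num(gaussian_noise_sd, "gaussian_noise_sd", min = 0)
  needed <- c("name", "puncta_density_per_mm3", "punctum_radius_um",
              "peak_intensity", "psf_sigma_xy_um", "psf_sigma_z_um")
  if (!all(needed %in% names(channels))) {
    abort(paste("`channels` needs columns:", paste(needed, collapse = ", ")))
  }
  if (any(channels$puncta_density_per_mm3 < 0) ||
      any(channels$punctum_radius_um <= 0)) {
    abort("channel densities must be >= 0 and radii > 0.")
  }
  if (floor(field_size_um[1] / pixel_size_um) < 1 ||
      floor(field_size_um[2] / pixel_size_um) < 1) {
    abort("field must contain at least one pixel per section.")
  }
  structure(list(
    field_size_um = as.numeric(field_size_um),
    pixel_size_um = pixel_size_um,
    z_step_um = z_step_um,
    section_thickness_um = section_thickness_um,
    n_sections = as.integer(n_sections),
    channels = as_tibble(channels),
    colocalization_fraction = colocalization_fraction,
    pair_offset_sd_um = pair_offset_sd_um,
    flicker_density_per_mm3 = flicker_density_per_mm3,
    background_level = background_level,
    gaussian_noise_sd = gaussian_noise_sd,
    poisson_noise = isTRUE(poisson_noise),
    seed = seed), class = "sim_image_config")
}

#' Configuration for synthetic miniature-PSC recordings
#'
#' Defaults mirror the recording protocol this pipeline targets: 5 min of
#' continuous recording digitised at 20 kHz. Events arrive as a Poisson
#' process; each event is a unit-peak triexponential kernel
#' `(1 - exp(-t/tau_rise)) * (m * exp(-t/tau_d1) + (1-m) * exp(-t/tau_d2))`
#' scaled by a zero-truncated normal amplitude, signed by polarity (inward
#' events deflect negative, outward positive). Gaussian baseline noise and
#' an optional linear drift are added.
#'
#' @param duration_s recording length, s.
#' @param sampling_hz sampling rate, Hz; `duration_s * sampling_hz` must be
#'   a whole number of samples.
#' @param event_rate_hz Poisson event rate, Hz.
#' @param amplitude_mean_pA,amplitude_sd_pA amplitude distribution before
#'   truncation at 0 (truncation forbids sign flips).
#' @param tau_rise_ms,tau_decay1_ms,tau_decay2_ms,decay_mix kernel kinetics;
#'   `decay_mix` is the weight of the fast decay, in `[0, 1]`.
#' @param kernel_ms rendered kernel length, ms.
#' @param polarity `"inward"` or `"outward"`.
#' @param baseline_noise_sd_pA Gaussian noise sd, pA.
#' @param drift_pA_per_s linear baseline drift, pA/s.
#' @param seed integer RNG seed.
#'
#' @return A `sim_ephys_config` list.
#' @export
sim_ephys_config <- function(duration_s = 300,
                             sampling_hz = 20000,
                             event_rate_hz = 2,
                             amplitude_mean_pA = 20,
                             amplitude_sd_pA = 5,
                             tau_rise_ms = 0.5,
                             tau_decay1_ms = 4,
                             tau_decay2_ms = 12,
                             decay_mix = 0.7,
                             kernel_ms = 60,
                             polarity = c("outward", "inward"),
                             baseline_noise_sd_pA = 2,
                             drift_pA_per_s = 0,
                             seed = 1L) {
  polarity <- match.arg(polarity)
  check_num(duration_s, "duration_s", min = 0, allow_zero = FALSE)
  check_num(sampling_hz, "sampling_hz", min = 0, allow_zero = FALSE)
  n <- duration_s * sampling_hz
  if (abs(n - round(n)) > 1e-8) {
    abort("duration_s * sampling_hz must be an integer sample count.")
  }
  check_num(event_rate_hz, "event_rate_hz", min = 0)
  check_num(amplitude_mean_pA, "amplitude_mean_pA", min = 0,
            allow_zero = FALSE)
  check_num(amplitude_sd_pA, "amplitude_sd_pA", min = 0)
  for (nm in c("tau_rise_ms", "tau_decay1_ms", "tau_decay2_ms")) {
    check_num(get(nm), nm, min = 0, allow_zero = FALSE)
  }
  check_fraction(decay_mix, "decay_mix")
  check_num(kernel_ms, "kernel_ms", min = 0, allow_zero = FALSE)
  check_num(baseline_noise_sd_pA, "baseline_noise_sd_pA", min = 0)
  structure(list(
    duration_s = duration_s, sampling_hz = sampling_hz,
    event_rate_hz = event_rate_hz,
    amplitude_mean_pA = amplitude_mean_pA,
    amplitude_sd_pA = amplitude_sd_pA,
    tau_rise_ms = tau_rise_ms, tau_decay1_ms = tau_decay1_ms,
    tau_decay2_ms = tau_decay2_ms, decay_mix = decay_mix,
    kernel_ms = kernel_ms, polarity = polarity,
    baseline_noise_sd_pA = baseline_noise_sd_pA,
    drift_pA_per_s = drift_pA_per_s, seed = seed),
    class = "sim_ephys_config")
}
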