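#' Acquisition configuration
#'
#' Bundles the spectrometer and pulse-sequence settings used by the spectrum
#' simulator and the synthetic-sample generators. The defaults reproduce the
#' routine benchtop protocol: a 60 MHz instrument running a 1D presaturation
#' sequence with 64 scans, a 6.4 s acquisition time, a 10 s repetition time,
#' a 90 degree pulse, water presaturation at 4.95 ppm with a 58 dB power
#' setting, and a reference linewidth of 0.55 Hz.
#'
#' @param field_MHz Spectrometer 1H frequency in MHz (> 0).
#' @param n_scans Number of co-added scans (>= 1).
#' @param acq_time_s FID acquisition time in seconds.
#' @param repetition_time_s Scan repetition time (acquisition + relaxation
#'   delay) in seconds.
#' @param pulse_angle_deg Excitation pulse angle in degrees.
#' @param presat_ppm Water presaturation carrier position in ppm. The 400 MHz
#'   protocol irradiates at 4.80 ppm; pass `presat_ppm = 4.80` there.
#' @param presat_power_dB Presaturation power setting in dB (larger values
#'   mean weaker irradiation).
#' @param presat Logical; apply presaturation attenuation in simulations.
#' @param noise_sigma Per-scan spectral noise standard deviation (intensity
#'   units); the co-added spectrum has standard deviation
#'   `noise_sigma / sqrt(n_scans)`.
#' @param linewidth_Hz Base Lorentzian full width at half maximum in Hz.
#' @param sw_ppm Length-2 numeric, the simulated spectral window in ppm.
#' @param ppm_step Rendering grid spacing in ppm.
#' @param water_area Residual (post-presaturation) water resonance area in
#'   the generator's concentration-times-proton units.
#' @param water_linewidth_Hz Residual water Lorentzian FWHM in Hz.
#'
#' @return An object of class `acquisition_config` (a validated list).
#' @examples
#' cfg <- acquisition_config()
#' cfg400 <- acquisition_config(field_MHz = 400, presat_ppm = 4.80,
#'                              presat_power_dB = 50)
#' @export
acquisition_config <- function(field_MHz = 60,
                               n_scans = 64,
                               acq_time_s = 6.4,
                               repetition_time_s = 10,
                               pulse_angle_deg = 90,
                               presat_ppm = 4.95,
                               presat_power_dB = 58,
                               presat = TRUE,
                               noise_sigma = 20,
                               linewidth_Hz = 0.55,
                               sw_ppm = c(-1, 10.5),
                               ppm_step = 0.001,
                               water_area = 3.87,
                               water_linewidth_Hz = 6.0) {
  check_number(field_MHz, "field_MHz", positive = TRUE)
  check_number(n_scans, "n_scans", positive = TRUE)
  if (n_scans < 1 || n_scans != round(n_scans))
    stop_lfnmr("n_scans must be a positive integer",
               class = "lfnmr_validation_error")
  check_number(acq_time_s, "acq_time_s", positive = TRUE)
  check_number(repetition_time_s, "repetition_time_s", positive = TRUE)
  check_number(pulse_angle_deg, "pulse_angle_deg", positive = TRUE)
  check_number(presat_ppm, "presat_ppm")
  check_number(presat_power_dB, "presat_power_dB")
  check_number(noise_sigma, "noise_sigma", nonnegative = TRUE)
  check_number(linewidth_Hz, "linewidth_Hz", positive = TRUE)
  if (!is.numeric(sw_ppm) || length(sw_ppm) != 2L || sw_ppm[1] >= sw_ppm[2])
    stop_lfnmr("sw_ppm must be an increasing length-2 numeric",
               class = "lfnmr_validation_error")
  check_number(ppm_step, "ppm_step", positive = TRUE)
  check_number(water_area, "water_area", nonnegative = TRUE)
  check_number(water_linewidth_Hz, "water_linewidth_Hz", positive = TRUE)
  structure(list(field_MHz = field_MHz, n_scans = as.integer(n_scans),
                 acq_time_s = acq_time_s,
                 repetition_time_s = repetition_time_s,
                 pulse_angle_deg = pulse_angle_deg,
                 presat_ppm = presat_ppm,
                 presat_power_dB = presat_power_dB,
                 presat = isTRUE(presat),
                 noise_sigma = noise_sigma,
                 linewidth_Hz = linewidth_Hz,
                 sw_ppm = sw_ppm, ppm_step = ppm_step,
                 water_area = water_area,
                 water_linewidth_Hz = water_linewidth_Hz),
            class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("<acquisition_config> %g MHz, %d scans, at %gs/rt %gs, %g deg\n",
              x$field_MHz, x$n_scans, x$acq_time_s, x$repetition_time_s,
              x$pulse_angle_deg))
  cat(sprintf("  presat: %s at %g ppm, %g dB; linewidth %g Hz; noise %g\n",
              if (x$presat) "on" else "off", x$presat_ppm,
              x$presat_power_dB, x$linewidth_Hz, x$noise_sigma))
  invisible(x)
}

default_ppm_axis <- function(config) {
  seq(config$sw_ppm[1], config$sw_ppm[2], by = config$ppm_step)
}
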