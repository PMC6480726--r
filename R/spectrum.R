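# Spectrum and FID containers plus rendering from transition lists.

#' Construct a frequency-domain spectrum
#'
#' @param ppm Strictly monotonic chemical-shift axis (stored ascending).
#' @param intensity Real or complex intensities, one per axis point; the
#'   intensity convention throughout the package is signal density per ppm,
#'   so trapezoidal integrals over ppm intervals are in concentration-times-
#'   proton units.
#' @param meta List of acquisition metadata (typically an
#'   [acquisition_config()]).
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, meta = list()) {
  if (length(ppm) != length(intensity))
    stop_lfnmr("ppm and intensity lengths differ",
               class = "lfnmr_validation_error")
  d <- diff(ppm)
  if (length(ppm) < 2L || any(d == 0) || (any(d > 0) && any(d < 0)))
    stop_lfnmr("ppm axis must be strictly monotonic",
               class = "lfnmr_validation_error")
  if (d[1] < 0) { ppm <- rev(ppm); intensity <- rev(intensity) }
  if (any(!is.finite(Mod(intensity))))
    stop_lfnmr("intensities must be finite",
               class = "lfnmr_validation_error")
  structure(list(ppm = as.numeric(ppm), intensity = intensity, meta = meta),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.3f to %.3f ppm%s\n",
              length(x$ppm), min(x$ppm), max(x$ppm),
              if (is.complex(x$intensity)) " (complex)" else ""))
  if (!is.null(x$meta$field_MHz))
    cat(sprintf("  field %g MHz, %s scans\n", x$meta$field_MHz,
                if (is.null(x$meta$n_scans)) "?" else x$meta$n_scans))
  invisible(x)
}

#' @export
plot.nmr_spectrum <- function(x, reverse = TRUE, ...) {
  xv <- x$ppm
  yv <- Re(x$intensity)
  plot(xv, yv, type = "l", xlab = "ppm", ylab = "intensity",
       xlim = if (reverse) rev(range(xv)) else range(xv), ...)
  invisible(x)
}

#' Render a transition list onto a ppm grid
#'
#' Sums unit-area Lorentzian lineshapes centred at each transition, scaled by
#' the transition intensities. The numerical integral of the rendered
#' spectrum over the ppm axis equals the total transition intensity (within
#' discretisation error) for adequately sampled axes.
#'
#' @param transitions A `transition_list` from [compute_transitions()], or
#'   any data frame with columns `frequency_Hz` and `intensity`.
#' @param axis Ascending ppm grid.
#' @param linewidth_Hz Lorentzian FWHM in Hz.
#' @param field_MHz Spectrometer frequency (converts Hz positions/widths to
#'   ppm).
#' @return An `nmr_spectrum`. If any transition falls outside the axis a
#'   warning is raised and the attribute `truncated` is set to `TRUE`.
#' @export
render_spectrum <- function(transitions, axis, linewidth_Hz, field_MHz) {
  check_number(linewidth_Hz, "linewidth_Hz", positive = TRUE)
  check_number(field_MHz, "field_MHz", positive = TRUE)
  y <- numeric(length(axis))
  truncated <- FALSE
  if (nrow(transitions)) {
    pos_ppm <- transitions$frequency_Hz / field_MHz
    gamma <- (linewidth_Hz / field_MHz) / 2  # HWHM in ppm
    outside <- pos_ppm < min(axis) | pos_ppm > max(axis)
    if (any(outside)) {
      warning(sprintf("%d transition(s) fall outside the ppm axis", sum(outside)))
      truncated <- TRUE
    }
    for (k in seq_len(nrow(transitions))) {
      y <- y + transitions$intensity[k] * (gamma / pi) /
        ((axis - pos_ppm[k])^2 + gamma^2)
    }
  }
  sp <- nmr_spectrum(axis, y, meta = list(field_MHz = field_MHz,
                                          linewidth_Hz = linewidth_Hz))
  attr(sp, "truncated") <- truncated
  sp
}

#' Construct a time-domain FID
#'
#' @param signal Complex time-domain samples.
#' @param dwell_s Sampling interval in seconds.
#' @param carrier_hz Receiver carrier offset from the 0 ppm reference in Hz
#'   (frequencies in the FID are relative to this carrier).
#' @param meta Acquisition metadata list.
#' @return An object of class `nmr_fid`.
#' @export
nmr_fid <- function(signal, dwell_s, carrier_hz, meta = list()) {
  if (length(signal) == 0L)
    stop_lfnmr("empty FID", class = "lfnmr_validation_error")
  check_number(dwell_s, "dwell_s", positive = TRUE)
  check_number(carrier_hz, "carrier_hz")
  structure(list(signal = as.complex(signal), dwell_s = dwell_s,
                 carrier_hz = carrier_hz, meta = meta),
            class = "nmr_fid")
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf("<nmr_fid> %d points, dwell %.3g s (sw %.1f Hz), carrier %.1f Hz\n",
              length(x$signal), x$dwell_s, 1 / x$dwell_s, x$carrier_hz))
  invisible(x)
}

#' Synthesize a free induction decay from a transition list
#'
#' Builds the complex time-domain signal
#' \eqn{s(t) = \sum_k A_k \exp\{2\pi i (f_k - f_c) t\} e^{-\pi \lambda t}}
#' with decay rate set by the configured linewidth (\eqn{\lambda} Hz FWHM
#' after Fourier transformation) and the receiver carrier \eqn{f_c} at the
#' centre of the configured spectral window. The Fourier transform of the
#' noise-free FID matches [render_spectrum()] within discretisation error.
#'
#' @param transitions A `transition_list` (columns `frequency_Hz`,
#'   `intensity`).
#' @param config An [acquisition_config()]; `sw_ppm` fixes the sampling rate
#'   and every transition must satisfy Nyquist within that window.
#' @return An `nmr_fid`.
#' @export
synthesize_fid <- function(transitions, config) {
  stopifnot(inherits(config, "acquisition_config"))
  sw_hz <- diff(config$sw_ppm) * config$field_MHz
  carrier_hz <- mean(config$sw_ppm) * config$field_MHz
  dwell <- 1 / sw_hz
  n <- max(2L, round(config$acq_time_s * sw_hz))
  t <- (seq_len(n) - 1L) * dwell
  sig <- complex(real = numeric(n), imaginary = numeric(n))
  if (nrow(transitions)) {
    f_rel <- transitions$frequency_Hz - carrier_hz
    bad <- abs(f_rel) >= sw_hz / 2
    if (any(bad))
      stop_lfnmr("transition at ", paste(signif(
        transitions$frequency_Hz[bad], 6), collapse = ", "),
        " Hz violates Nyquist for the spectral window [",
        config$sw_ppm[1], ", ", config$sw_ppm[2], "] ppm",
        class = "lfnmr_nyquist_error")
    decay <- exp(-pi * config$linewidth_Hz * t)
    for (k in seq_along(f_rel)) {
      sig <- sig + transitions$intensity[k] * decay *
        exp(2i * pi * f_rel[k] * t)
    }
  }
  nmr_fid(sig, dwell, carrier_hz,
          meta = list(field_MHz = config$field_MHz,
                      acq_time_s = config$acq_time_s,
                      linewidth_Hz = config$linewidth_Hz,
                      n_scans = config$n_scans))
}
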