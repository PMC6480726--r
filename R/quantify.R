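# Bucket integration, SNR, LOD/LOQ, calibration fitting and normalisation.

#' Bucket table
#'
#' An ordered set of labelled, non-overlapping ppm integration intervals
#' plus a list of exclusion regions that must stay disjoint from every
#' bucket. [default_bucket_table()] ships the 27-bucket layout used for the
#' urinary case study: 12 resonance-anchored buckets (citrate 2.53-2.70,
#' N-acetyl 1.99-2.13, lactate 1.25-1.34, alanine 1.44-1.52, creatinine
#' 2.98-3.14, acetone 2.14-2.29, acetate 1.87-1.99, 3-HB 1.14-1.25, indoxyl
#' sulphate 7.15-7.33, hippurate 7.55-7.71, and the glucose bulk 3.14-3.99
#' and alpha-C1-H 5.17-5.36 regions) plus filler buckets tiling the
#' remaining unexcluded 1.03-8.52 ppm span, flagged unanchored.
#'
#' @param buckets Data frame with columns `low_ppm`, `high_ppm`, `label`
#'   and optionally `anchored`.
#' @param exclusions Data frame with columns `low_ppm`, `high_ppm`.
#' @return An object of class `bucket_table`.
#' @export
bucket_table <- function(buckets, exclusions = default_exclusions()) {
  stopifnot(all(c("low_ppm", "high_ppm", "label") %in% names(buckets)))
  if (is.null(buckets$anchored)) buckets$anchored <- TRUE
  if (any(buckets$low_ppm >= buckets$high_ppm))
    stop_lfnmr("bucket low_ppm must be < high_ppm",
               class = "lfnmr_validation_error")
  b <- buckets[order(buckets$low_ppm), , drop = FALSE]
  rownames(b) <- NULL
  if (nrow(b) > 1L && any(b$low_ppm[-1] < b$high_ppm[-nrow(b)]))
    stop_lfnmr("buckets must not overlap", class = "lfnmr_validation_error")
  for (i in seq_len(nrow(exclusions))) {
    hit <- b$low_ppm < exclusions$high_ppm[i] &
      b$high_ppm > exclusions$low_ppm[i]
    if (any(hit))
      stop_lfnmr("bucket '", b$label[which(hit)[1]],
                 "' intersects exclusion region [",
                 exclusions$low_ppm[i], ", ", exclusions$high_ppm[i], "]",
                 class = "lfnmr_validation_error")
  }
  structure(list(buckets = b, exclusions = exclusions),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("<bucket_table> %d buckets, %d exclusion regions\n",
              nrow(x$buckets), nrow(x$exclusions)))
  print(x$buckets, row.names = FALSE)
  invisible(x)
}

#' @rdname bucket_table
#' @export
default_bucket_table <- function() {
  path <- system.file("extdata", "buckets_default.csv", package = "lfnmr")
  b <- utils::read.csv(path, comment.char = "#")
  bucket_table(b)
}

#' Spectral exclusion regions
#'
#' The residual water region (4.41-5.16 ppm) and the signal-free regions
#' removed from every low-field spectrum before analysis.
#'
#' @return Data frame with columns `low_ppm`, `high_ppm`, `reason`.
#' @export
default_exclusions <- function() {
  data.frame(
    low_ppm  = c(4.41, 0.08, 1.61, 2.42, 2.71, 5.37, 5.86, 7.09, 8.02, 8.53),
    high_ppm = c(5.16, 1.02, 1.86, 2.52, 2.97, 5.56, 6.83, 7.14, 8.14, 20.0),
    reason = c("residual H2O/HOD", rep("no visible resonances", 9)))
}

#' Trapezoidal bucket integration
#'
#' Cumulative integral of a spectrum over the closed ppm interval
#' `[low_ppm, high_ppm]` using the trapezoid rule on the native grid, with
#' linearly interpolated values at the exact interval bounds so adjacent
#' buckets sum exactly to the integral of their union.
#'
#' @param spectrum An `nmr_spectrum` (the real part is integrated).
#' @param low_ppm,high_ppm Interval bounds (must lie inside the axis).
#' @return The integral (intensity-times-ppm units).
#' @export
integrate_bucket <- function(spectrum, low_ppm, high_ppm) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (low_ppm >= high_ppm)
    stop_lfnmr("low_ppm must be < high_ppm",
               class = "lfnmr_validation_error")
  x <- spectrum$ppm
  y <- Re(spectrum$intensity)
  if (low_ppm < x[1] || high_ppm > x[length(x)])
    stop_lfnmr("bucket [", low_ppm, ", ", high_ppm,
               "] lies outside the spectrum axis [", signif(x[1], 6), ", ",
               signif(x[length(x)], 6), "]",
               class = "lfnmr_validation_error")
  inside <- which(x > low_ppm & x < high_ppm)
  xs <- c(low_ppm, x[inside], high_ppm)
  ys <- c(stats::approx(x, y, low_ppm)$y, y[inside],
          stats::approx(x, y, high_ppm)$y)
  trapz(xs, ys)
}

#' Signal-to-noise ratio of a peak
#'
#' Two estimators are provided. `"flank_mean"` divides the peak height by
#' the mean absolute value of the `n_points` grid points immediately
#' flanking the peak window on each side. `"top10_noise"` divides by the
#' mean of the `n_points` largest-magnitude points within a designated
#' signal-free noise region. The flank estimator uses typical noise
#' excursions, the top-10 estimator extreme ones, so the latter never
#' exceeds the former on the same data in expectation.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param peak_ppm Peak position.
#' @param method `"flank_mean"` or `"top10_noise"`.
#' @param half_width_ppm Half-width of the peak search window.
#' @param noise_region Length-2 ppm interval assumed signal-free (default
#'   9.0-9.5 ppm).
#' @param n_points Number of points per flank / largest noise points.
#' @return The SNR; `Inf` for a noiseless spectrum.
#' @export
estimate_snr <- function(spectrum, peak_ppm,
                         method = c("flank_mean", "top10_noise"),
                         half_width_ppm = 0.05,
                         noise_region = c(9.0, 9.5), n_points = 10) {
  method <- match.arg(method)
  x <- spectrum$ppm
  y <- Re(spectrum$intensity)
  win <- which(x >= peak_ppm - half_width_ppm & x <= peak_ppm + half_width_ppm)
  if (!length(win))
    stop_lfnmr("peak window outside axis", class = "lfnmr_validation_error")
  height <- max(y[win])
  if (method == "flank_mean") {
    lo <- seq(max(1L, min(win) - n_points), min(win) - 1L)
    hi <- seq(max(win) + 1L, min(length(x), max(win) + n_points))
    noise <- mean(abs(y[c(lo, hi)]))
  } else {
    if (noise_region[1] <= peak_ppm + half_width_ppm &&
        noise_region[2] >= peak_ppm - half_width_ppm)
      stop_lfnmr("noise region overlaps the peak window",
                 class = "lfnmr_validation_error")
    idx <- which(x >= noise_region[1] & x <= noise_region[2])
    if (length(idx) < n_points)
      stop_lfnmr("noise region too small", class = "lfnmr_validation_error")
    v <- sort(abs(y[idx]), decreasing = TRUE)
    noise <- mean(v[seq_len(n_points)])
  }
  if (noise == 0) return(Inf)
  height / noise
}

#' Internal-standard normalisation of a single area
#'
#' @param analyte_area,tsp_area Integrated areas; `tsp_area` must be > 0.
#' @return The ratio `analyte_area / tsp_area`.
#' @export
tsp_normalize <- function(analyte_area, tsp_area) {
  if (any(tsp_area <= 0))
    stop_lfnmr("TSP area must be > 0", class = "lfnmr_validation_error")
  analyte_area / tsp_area
}

#' Constant-sum normalisation
#'
#' Scales each row (sample) of a non-negative feature matrix to unit sum,
#' so each bucket becomes a fraction of the total spectral intensity.
#'
#' @param x Numeric matrix (samples x buckets) or `feature_matrix`.
#' @return The row-normalised matrix; feature-matrix state tags gain
#'   `"csn"`.
#' @export
constant_sum_normalize <- function(x) {
  rs <- rowSums(x)
  bad <- which(rs <= 0)
  if (length(bad))
    stop_lfnmr("zero or negative row sum for sample '",
               paste(rownames(x)[bad] %||% bad, collapse = "', '"), "'",
               class = "lfnmr_validation_error")
  out <- sweep(x, 1, rs, "/")
  if (inherits(x, "feature_matrix"))
    attr(out, "state") <- c(attr(x, "state"), "csn")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Anomer correction for glucose
#'
#' The alpha anomer represents 36% of total glucose at equilibrium, so
#' alpha-anomer concentrations convert to total glucose with the factor
#' 100/36 = 2.78.
#'
#' @param alpha_conc Alpha-anomer concentration(s), >= 0.
#' @param anomer_fraction Equilibrium alpha fraction (default 0.36).
#' @return Total glucose concentration(s).
#' @examples
#' alpha_to_total_glucose(36)  # 100
#' @export
alpha_to_total_glucose <- function(alpha_conc, anomer_fraction = 0.36) {
  if (any(alpha_conc < 0))
    stop_lfnmr("alpha_conc must be >= 0", class = "lfnmr_validation_error")
  check_number(anomer_fraction, "anomer_fraction", positive = TRUE)
  alpha_conc / anomer_fraction
}

#' Theoretical proton-bookkeeping calibration slope
#'
#' Slope of TSP-normalised resonance intensity versus total analyte
#' concentration predicted from the known concentrations alone: with one
#' observed proton at abundance `fraction` against the internal standard's
#' nine protons at `tsp_mM`, the ratio per mmol/L is
#' `fraction * analyte_protons / (tsp_mM * tsp_protons)`.
#'
#' @param tsp_mM Internal standard concentration in mmol/L.
#' @param fraction Abundance of the observed species (alpha anomer: 0.36).
#' @param analyte_protons,tsp_protons Contributing proton counts (1 and 9).
#' @return Slope in ratio units per mmol/L.
#' @export
theoretical_slope <- function(tsp_mM, fraction = 0.36,
                              analyte_protons = 1, tsp_protons = 9) {
  check_number(tsp_mM, "tsp_mM", positive = TRUE)
  fraction * analyte_protons / (tsp_mM * tsp_protons)
}

#' Fit a calibration line with LOD/LOQ determination
#'
#' Least-squares fit of TSP-normalised intensity against concentration.
#' The limit of detection is the lowest calibration concentration whose
#' SNR reaches 3, the limit of quantification the lowest reaching SNR 10;
#' the LOQ is additionally raised until the residual-water overlap
#' contribution to the integration window falls below 10%.
#'
#' @param concentrations Analyte concentrations (>= 3 distinct values).
#' @param ratios TSP-normalised intensities.
#' @param snr Optional per-point SNR values (for LOD/LOQ).
#' @param water_overlap Optional per-point water-overlap fractions.
#' @param analyte,resonance_ppm Optional labels stored in the model.
#' @return An object of class `calibration_model` with elements `slope`,
#'   `intercept`, `r`, `lod`, `loq_snr`, `loq` and the fit data.
#' @export
fit_calibration <- function(concentrations, ratios, snr = NULL,
                            water_overlap = NULL, analyte = NULL,
                            resonance_ppm = NULL) {
  if (length(concentrations) < 3L)
    stop_lfnmr("need at least 3 calibration points",
               class = "lfnmr_validation_error")
  if (length(unique(concentrations)) < length(concentrations))
    stop_lfnmr("calibration concentrations must be distinct",
               class = "lfnmr_validation_error")
  fit <- stats::lm(ratios ~ concentrations)
  o <- order(concentrations)
  lod <- loq_snr <- loq <- NA_real_
  if (!is.null(snr)) {
    cs <- concentrations[o]; ss <- snr[o]
    ok3 <- which(ss >= 3); ok10 <- which(ss >= 10)
    if (length(ok3)) lod <- cs[ok3[1]]
    if (length(ok10)) loq_snr <- cs[ok10[1]]
    loq <- loq_snr
    if (!is.null(water_overlap)) {
      wo <- water_overlap[o]
      ok <- which(ss >= 10 & wo < 0.10)
      loq <- if (length(ok)) cs[ok[1]] else NA_real_
    }
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(concentrations, ratios),
                 lod = lod, loq_snr = loq_snr, loq = loq,
                 analyte = analyte, resonance_ppm = resonance_ppm,
                 concentrations = concentrations, ratios = ratios,
                 fit = fit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model>%s slope %.5g, intercept %.5g, r %.4f\n",
              if (is.null(x$analyte)) "" else paste0(" ", x$analyte),
              x$slope, x$intercept, x$r))
  cat(sprintf("  LOD %s, LOQ %s mmol/L (SNR-only LOQ %s)\n",
              format(x$lod), format(x$loq), format(x$loq_snr)))
  invisible(x)
}

#' Concentration from a calibration model
#'
#' Inverts the calibration line; estimates are clamped at zero and flagged
#' when they fall below the model's LOQ.
#'
#' @param tsp_ratio TSP-normalised intensity value(s).
#' @param model A [fit_calibration()] model with positive slope.
#' @return Data frame with columns `concentration`, `below_loq`, `clamped`.
#' @export
quantify_from_calibration <- function(tsp_ratio, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (!is.finite(model$slope) || model$slope <= 0)
    stop_lfnmr("calibration slope must be > 0",
               class = "lfnmr_validation_error")
  conc <- (tsp_ratio - model$intercept) / model$slope
  clamped <- conc < 0
  conc[clamped] <- 0
  below <- if (is.na(model$loq)) rep(FALSE, length(conc)) else
    conc < model$loq
  data.frame(concentration = conc, below_loq = below | clamped,
             clamped = clamped)
}

#' Water-overlap fraction of a bucket in a calibration series
#'
#' Fraction of the integration-window area contributed by the residual
#' presaturated water tail, computed from the generator's noise-free
#' component spectra: water-only area divided by total (analyte + water)
#' area in the bucket.
#'
#' @param series A `calibration_series`.
#' @param low_ppm,high_ppm Bucket bounds (default the alpha-glucose C1-H
#'   bucket 5.17-5.36 ppm).
#' @return Numeric vector, one fraction per series concentration.
#' @export
water_overlap_fraction <- function(series, low_ppm = 5.17,
                                   high_ppm = 5.36) {
  stopifnot(inherits(series, "calibration_series"))
  w <- integrate_bucket(series$water, low_ppm, high_ppm)
  vapply(series$clean, function(sp)
    w / integrate_bucket(sp, low_ppm, high_ppm), numeric(1))
}

#' Calibration model from a synthetic series
#'
#' Convenience wrapper running the full quantification protocol on a
#' [generate_calibration_series()] object: bucket integration of the
#' analyte resonance, TSP normalisation, per-point SNR estimation on the
#' noisy spectra, water-overlap fractions, then [fit_calibration()].
#'
#' @param series A `calibration_series`.
#' @param low_ppm,high_ppm Analyte integration window (default the
#'   alpha-glucose C1-H bucket).
#' @param peak_ppm Peak position for SNR estimation (default 5.25).
#' @param tsp_window TSP integration window in ppm.
#' @param snr_method Passed to [estimate_snr()].
#' @return A `calibration_model`.
#' @export
calibration_from_series <- function(series, low_ppm = 5.17,
                                    high_ppm = 5.36, peak_ppm = 5.25,
                                    tsp_window = c(-0.05, 0.05),
                                    snr_method = "flank_mean") {
  stopifnot(inherits(series, "calibration_series"))
  areas <- vapply(series$spectra, integrate_bucket, numeric(1),
                  low_ppm, high_ppm)
  tsp <- vapply(series$spectra, integrate_bucket, numeric(1),
                tsp_window[1], tsp_window[2])
  ratios <- tsp_normalize(areas, tsp)
  snr <- vapply(series$spectra, estimate_snr, numeric(1), peak_ppm,
                method = snr_method)
  wo <- water_overlap_fraction(series, low_ppm, high_ppm)
  fit_calibration(series$concentrations, ratios, snr = snr,
                  water_overlap = wo, analyte = series$analyte,
                  resonance_ppm = peak_ppm)
}

#' Build a bucket feature matrix from spectra
#'
#' Integrates every bucket of a [bucket_table()] in every spectrum. The
#' result is a `feature_matrix`: a numeric samples-x-buckets matrix
#' carrying the bucket table, per-sample TSP areas and a normalisation
#' state tag (`"raw"`) that downstream transforms update and enforce.
#'
#' @param spectra List of `nmr_spectrum` objects.
#' @param buckets A `bucket_table` (default [default_bucket_table()]).
#' @param tsp_window TSP integration window.
#' @return A `feature_matrix`.
#' @export
build_feature_matrix <- function(spectra, buckets = default_bucket_table(),
                                 tsp_window = c(-0.05, 0.05)) {
  stopifnot(inherits(buckets, "bucket_table"))
  b <- buckets$buckets
  m <- t(vapply(spectra, function(sp)
    vapply(seq_len(nrow(b)), function(i)
      integrate_bucket(sp, b$low_ppm[i], b$high_ppm[i]), numeric(1)),
    numeric(nrow(b))))
  colnames(m) <- b$label
  rownames(m) <- names(spectra) %||% paste0("s", seq_along(spectra))
  tsp <- vapply(spectra, integrate_bucket, numeric(1),
                tsp_window[1], tsp_window[2])
  field <- tryCatch(spectra[[1]]$meta$field_MHz, error = function(e) NULL)
  structure(m, class = c("feature_matrix", "matrix", "array"),
            bucket_table = buckets, tsp_area = tsp,
            field_MHz = field, state = "raw")
}

#' Normalise a feature matrix
#'
#' `"tsp"` divides each sample row by its internal-standard area;
#' `"csn"` applies constant-sum normalisation.
#'
#' @param fm A `feature_matrix`.
#' @param method `"tsp"` or `"csn"`.
#' @return The normalised `feature_matrix` with updated state tags.
#' @export
normalize_features <- function(fm, method = c("tsp", "csn")) {
  method <- match.arg(method)
  stopifnot(inherits(fm, "feature_matrix"))
  if (any(c("tsp", "csn") %in% attr(fm, "state")))
    stop_lfnmr("feature matrix is already normalised (state: ",
               paste(attr(fm, "state"), collapse = " > "), ")",
               class = "lfnmr_state_error")
  if (method == "csn") return(constant_sum_normalize(fm))
  tsp <- attr(fm, "tsp_area")
  if (is.null(tsp) || any(tsp <= 0))
    stop_lfnmr("TSP areas missing or non-positive",
               class = "lfnmr_validation_error")
  out <- sweep(fm, 1, tsp, "/")
  attr(out, "state") <- c(attr(fm, "state"), "tsp")
  out
}

#' Creatinine normalisation with low-field feasibility check
#'
#' Divides every bucket by the creatinine bucket per sample, expressing
#' levels per unit creatinine to correct for urine dilution. At low field
#' the broad glucose ring-proton envelope (3.14-3.99 ppm) abuts the
#' creatinine N-CH3 bucket (2.98-3.14 ppm); when the glucose bulk signal
#' exceeds the creatinine signal in any sample under those conditions the
#' normalisation is flagged infeasible and a warning is raised.
#'
#' @param fm A `feature_matrix`.
#' @param cn_bucket,glucose_bucket Bucket labels.
#' @param field_threshold_MHz Fields at or below this trigger the overlap
#'   check (default 100).
#' @return The creatinine-normalised matrix with attribute `feasible`.
#' @export
creatinine_normalize <- function(fm, cn_bucket = "creatinine",
                                 glucose_bucket = "glucose_bulk",
                                 field_threshold_MHz = 100) {
  if (!cn_bucket %in% colnames(fm))
    stop_lfnmr("creatinine bucket '", cn_bucket, "' not present",
               class = "lfnmr_validation_error")
  cn <- fm[, cn_bucket]
  bad <- which(cn <= 0)
  if (length(bad))
    stop_lfnmr("zero creatinine bucket for sample '",
               paste(rownames(fm)[bad] %||% bad, collapse = "', '"), "'",
               class = "lfnmr_validation_error")
  feasible <- TRUE
  field <- attr(fm, "field_MHz")
  bt <- attr(fm, "bucket_table")
  if (!is.null(field) && field <= field_threshold_MHz &&
      glucose_bucket %in% colnames(fm) && !is.null(bt)) {
    b <- bt$buckets
    cn_b <- b[b$label == cn_bucket, ]
    gl_b <- b[b$label == glucose_bucket, ]
    adjacent <- min(abs(c(gl_b$low_ppm - cn_b$high_ppm,
                          cn_b$low_ppm - gl_b$high_ppm))) <= 0.05
    if (adjacent && any(fm[, glucose_bucket] > cn)) {
      feasible <- FALSE
      warning("creatinine normalisation unreliable at ", field,
              " MHz: glucose bulk signal overlaps the creatinine bucket",
              call. = FALSE)
    }
  }
  out <- sweep(fm, 1, cn, "/")
  if (inherits(fm, "feature_matrix"))
    attr(out, "state") <- c(attr(fm, "state"), "creatinine")
  attr(out, "feasible") <- feasible
  out
}
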