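# Synthetic-sample generators: preparation chemistry, calibration series,
# urine cohorts and multi-method measurement tables.

#' Sample-preparation recipe
#'
#' Dilution bookkeeping for an NMR sample preparation: aliquot volumes of
#' the analyte solution (or biofluid supernatant), phosphate buffer, the
#' 2H2O aliquot carrying the TSP internal standard, and optionally a sodium
#' azide aliquot, together with the TSP stock mass fraction and molar mass.
#'
#' Two standard recipes are provided: [biofluid_recipe()] (450 uL
#' supernatant + 50 uL buffer + 50 uL 2H2O/TSP; final TSP 264 umol/L) and
#' [calibration_recipe()] (500 uL analyte + 50 uL buffer + 50 uL 2H2O/TSP +
#' 50 uL azide; final TSP 223 umol/L).
#'
#' @param analyte_uL,buffer_uL,d2o_tsp_uL,azide_uL Aliquot volumes in uL.
#' @param tsp_mass_fraction_pct TSP stock concentration in % w/v.
#' @param tsp_molar_mass TSP molar mass in g/mol (sodium
#'   3-(trimethylsilyl)propionate-d4, 172.26 g/mol).
#' @return An object of class `preparation_recipe`.
#' @export
preparation_recipe <- function(analyte_uL, buffer_uL, d2o_tsp_uL,
                               azide_uL = 0,
                               tsp_mass_fraction_pct = 0.05,
                               tsp_molar_mass = 172.26) {
  vols <- c(analyte = analyte_uL, buffer = buffer_uL,
            d2o_tsp = d2o_tsp_uL, azide = azide_uL)
  if (any(vols[c("analyte", "buffer", "d2o_tsp")] <= 0) || azide_uL < 0)
    stop_lfnmr("aliquot volumes must be positive",
               class = "lfnmr_validation_error")
  check_number(tsp_mass_fraction_pct, "tsp_mass_fraction_pct",
               nonnegative = TRUE)
  check_number(tsp_molar_mass, "tsp_molar_mass", positive = TRUE)
  structure(list(volumes_uL = vols, final_uL = sum(vols),
                 tsp_mass_fraction_pct = tsp_mass_fraction_pct,
                 tsp_molar_mass = tsp_molar_mass),
            class = "preparation_recipe")
}

#' @rdname preparation_recipe
#' @export
biofluid_recipe <- function() preparation_recipe(450, 50, 50, 0)

#' @rdname preparation_recipe
#' @export
calibration_recipe <- function() preparation_recipe(500, 50, 50, 50)

#' Final TSP concentration of a preparation
#'
#' Computes the internal-standard concentration delivered by the 2H2O/TSP
#' aliquot: stock mass concentration (g/L) scaled by the aliquot dilution
#' and divided by the molar mass.
#'
#' @param recipe A [preparation_recipe()].
#' @return Concentration in umol/L.
#' @examples
#' tsp_final_concentration(biofluid_recipe())      # 264 umol/L
#' tsp_final_concentration(calibration_recipe())   # 223 umol/L
#' @export
tsp_final_concentration <- function(recipe) {
  stopifnot(inherits(recipe, "preparation_recipe"))
  if (recipe$final_uL <= 0)
    stop_lfnmr("final volume must be positive",
               class = "lfnmr_validation_error")
  stock_g_per_L <- recipe$tsp_mass_fraction_pct * 10  # % w/v -> g/L
  final_g_per_L <- stock_g_per_L *
    recipe$volumes_uL[["d2o_tsp"]] / recipe$final_uL
  final_g_per_L / recipe$tsp_molar_mass * 1e6
}

# Assemble the attenuated line list for a named concentration vector
# (mmol/L) under an acquisition configuration: per-line T1 saturation and
# presaturation retention applied, TSP included at the recipe concentration.
mixture_lines <- function(conc_mM, config, recipe, library = NULL,
                          include_tsp = TRUE) {
  conc_mM <- conc_mM[conc_mM > 0]
  if (include_tsp) {
    tsp_mM <- tsp_final_concentration(recipe) / 1000
    conc_mM <- c(conc_mM, tsp = tsp_mM)
  }
  if (!length(conc_mM))
    return(data.frame(frequency_Hz = numeric(), intensity = numeric()))
  presat_hz <- config$presat_ppm * config$field_MHz
  out <- vector("list", length(conc_mM))
  for (i in seq_along(conc_mM)) {
    ln <- metabolite_lines(names(conc_mM)[i], config$field_MHz, library)
    fac <- t1_saturation_factor(ln$t1_s, config$repetition_time_s,
                                config$pulse_angle_deg)
    if (config$presat)
      fac <- fac * presat_attenuation(abs(ln$frequency_Hz - presat_hz),
                                      config$presat_power_dB,
                                      config$field_MHz)
    out[[i]] <- data.frame(frequency_Hz = ln$frequency_Hz,
                           intensity = ln$intensity * conc_mM[i] * fac)
  }
  do.call(rbind, out)
}

# Residual water as a single broad Lorentzian at the presaturation carrier.
water_lines <- function(config) {
  data.frame(frequency_Hz = config$presat_ppm * config$field_MHz,
             intensity = config$water_area)
}

# Render a mixture to a frequency-domain spectrum, optionally adding
# seeded white Gaussian noise with sd noise_sigma / sqrt(n_scans).
simulate_mixture_spectrum <- function(conc_mM, config,
                                      recipe = biofluid_recipe(),
                                      library = NULL, noise = TRUE,
                                      include_water = TRUE,
                                      include_tsp = TRUE) {
  axis <- default_ppm_axis(config)
  lines <- mixture_lines(conc_mM, config, recipe, library, include_tsp)
  sp <- render_spectrum(lines, axis, config$linewidth_Hz, config$field_MHz)
  if (include_water && config$water_area > 0) {
    wsp <- render_spectrum(water_lines(config), axis,
                           config$water_linewidth_Hz, config$field_MHz)
    sp$intensity <- sp$intensity + wsp$intensity
  }
  if (noise && config$noise_sigma > 0)
    sp$intensity <- sp$intensity +
      stats::rnorm(length(axis), 0, config$noise_sigma / sqrt(config$n_scans))
  sp$meta <- config
  sp
}

#' Generate a synthetic calibration series
#'
#' Simulates one spectrum per analyte concentration, each containing the
#' analyte, TSP at the recipe concentration and the residual presaturated
#' water resonance, with presaturation and T1 saturation factors applied and
#' seeded white noise of standard deviation `noise_sigma / sqrt(n_scans)`.
#'
#' @param analyte Library metabolite name.
#' @param concentrations Analyte concentrations in mmol/L (>= 0).
#' @param config An [acquisition_config()].
#' @param recipe A [preparation_recipe()] (default [calibration_recipe()]).
#' @param seed Optional integer seed; identical seeds give identical series.
#' @param library Optional metabolite library.
#' @return An object of class `calibration_series`: list with elements
#'   `concentrations`, `spectra` (noisy), `clean` (noise-free), `water`
#'   (water + TSP background only, noise-free), `config`, `recipe`,
#'   `analyte`.
#' @export
generate_calibration_series <- function(analyte, concentrations,
                                        config = acquisition_config(),
                                        recipe = calibration_recipe(),
                                        seed = NULL, library = NULL) {
  lib <- if (is.null(library)) metabolite_library() else library
  if (!analyte %in% names(lib))
    stop_lfnmr("unknown analyte '", analyte, "'; library entries: ",
               paste(names(lib), collapse = ", "),
               class = "lfnmr_unknown_analyte_error")
  if (any(concentrations < 0))
    stop_lfnmr("concentrations must be >= 0",
               class = "lfnmr_validation_error")
  clean <- lapply(concentrations, function(cc) {
    conc <- stats::setNames(cc, analyte)
    simulate_mixture_spectrum(conc, config, recipe, library,
                              noise = FALSE)
  })
  spectra <- with_seed(seed, lapply(clean, function(sp) {
    out <- sp
    if (config$noise_sigma > 0)
      out$intensity <- out$intensity + stats::rnorm(
        length(sp$ppm), 0, config$noise_sigma / sqrt(config$n_scans))
    out
  }))
  water <- simulate_mixture_spectrum(stats::setNames(numeric(0), character(0)),
                                     config, recipe, library,
                                     noise = FALSE, include_tsp = FALSE)
  structure(list(concentrations = concentrations, spectra = spectra,
                 clean = clean, water = water, config = config,
                 recipe = recipe, analyte = analyte),
            class = "calibration_series")
}

#' Cohort specification
#'
#' Describes per-group sample sizes and per-metabolite concentration
#' distributions for the urine-cohort generator. Distributions are
#' moment-matched log-normals by default (exact group mean/SD, strictly
#' positive), with `"truncnorm"` (normal truncated at zero) as an option;
#' `detect` gives the detection fraction of a zero-inflated analyte (the
#' probability that a sample contains it at all).
#'
#' @param groups Named list; each element is a list with `n` (sample size
#'   >= 2) and `metabolites`, a data frame with columns `metabolite`,
#'   `mean_mM`, `sd_mM`, and optionally `detect` (default 1) and `dist`
#'   (default "lognormal").
#' @return An object of class `cohort_spec`.
#' @seealso [diabetes_cohort_spec()] for the default type 2 diabetic versus
#'   healthy control specification.
#' @export
cohort_spec <- function(groups) {
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (is.null(gr$n) || gr$n < 2)
      stop_lfnmr("group sizes must be >= 2",
                 class = "lfnmr_validation_error")
    m <- gr$metabolites
    if (!all(c("metabolite", "mean_mM", "sd_mM") %in% names(m)))
      stop_lfnmr("metabolites needs columns metabolite, mean_mM, sd_mM",
                 class = "lfnmr_validation_error")
    if (any(m$sd_mM < 0) || any(m$mean_mM < 0))
      stop_lfnmr("means and SDs must be >= 0",
                 class = "lfnmr_validation_error")
    if (is.null(m$detect)) m$detect <- 1
    if (is.null(m$dist)) m$dist <- "lognormal"
    if (any(m$detect < 0 | m$detect > 1))
      stop_lfnmr("detection fractions must lie in [0, 1]",
                 class = "lfnmr_validation_error")
    groups[[g]]$metabolites <- m
  }
  structure(list(groups = groups), class = "cohort_spec")
}

#' Default type 2 diabetic / healthy control cohort specification
#'
#' Transcribes the printed group statistics of the case study: 3-HB
#' 3.12 +/- 0.99 (SEM, n = 10) versus 0.24 +/- 0.06 (SEM, n = 14) mmol/L;
#' creatinine 20.86 +/- 10.56 versus 6.30 +/- 0.99 mmol/L; glucose
#' detectable in 6/10 diabetic samples with mean 155 +/- 56 mmol/L among
#' detectable samples. SEMs are converted to SDs with the group sizes
#' (SD = SEM * sqrt(n)). Metabolites whose group means are never printed
#' (citrate, acetate, hippurate, indoxyl sulphate, ...) carry plausible
#' literature-typical levels flagged `anchored = FALSE`; only their
#' direction of change between groups follows the reported biomarker
#' directions.
#'
#' @param n_diabetic,n_control Group sizes (defaults 10 and 14).
#' @return A [cohort_spec()].
#' @export
diabetes_cohort_spec <- function(n_diabetic = 10, n_control = 14) {
  met <- function(metabolite, mean_mM, sd_mM, detect = 1, anchored = TRUE)
    data.frame(metabolite = metabolite, mean_mM = mean_mM, sd_mM = sd_mM,
               detect = detect, anchored = anchored)
  # unanchored entries: means are literature-typical urine levels honouring
  # only the reported direction of change; within-group SDs are 0.6 x mean,
  # matching the between-subject variability implied by the printed
  # (anchored) group statistics (CVs 0.6-1.6)
  control <- rbind(
    met("hydroxybutyrate_3", 0.24, 0.06 * sqrt(14)),
    met("glucose", 0.30, 0.18, anchored = FALSE),
    met("creatinine", 6.30, 0.99 * sqrt(14)),
    met("citrate", 2.00, 1.20, anchored = FALSE),
    met("n_acetyl", 0.40, 0.24, anchored = FALSE),
    met("lactate", 0.15, 0.09, anchored = FALSE),
    met("alanine", 0.25, 0.15, anchored = FALSE),
    met("acetone", 0.05, 0.03, anchored = FALSE),
    met("acetate", 0.05, 0.03, anchored = FALSE),
    met("indoxyl_sulphate", 0.30, 0.18, anchored = FALSE),
    met("hippurate", 2.00, 1.20, anchored = FALSE),
    met("methylsuccinate", 0.02, 0.012, anchored = FALSE),
    met("formate", 0.12, 0.072, anchored = FALSE),
    met("urea", 200, 120, anchored = FALSE))
  diabetic <- rbind(
    met("hydroxybutyrate_3", 3.12, 0.99 * sqrt(10)),
    met("glucose", 155, 56 * sqrt(6), detect = 0.6),
    met("creatinine", 20.86, 10.56 * sqrt(10)),
    met("citrate", 4.00, 2.40, anchored = FALSE),
    met("n_acetyl", 1.00, 0.60, anchored = FALSE),
    met("lactate", 0.45, 0.27, anchored = FALSE),
    met("alanine", 0.60, 0.36, anchored = FALSE),
    met("acetone", 0.60, 0.36, anchored = FALSE),
    met("acetate", 0.15, 0.09, anchored = FALSE),
    met("indoxyl_sulphate", 0.12, 0.072, anchored = FALSE),
    met("hippurate", 0.80, 0.48, anchored = FALSE),
    met("methylsuccinate", 0.08, 0.048, anchored = FALSE),
    met("formate", 0.05, 0.03, anchored = FALSE),
    met("urea", 200, 120, anchored = FALSE))
  # background urine metabolites, identical in both groups, so the bulk
  # 3.14-3.99 ppm region and filler buckets are non-empty in every sample
  background <- rbind(
    met("choline", 0.25, 0.15, anchored = FALSE),
    met("betaine", 0.30, 0.18, anchored = FALSE),
    met("tmao", 0.60, 0.36, anchored = FALSE),
    met("taurine", 1.00, 0.60, anchored = FALSE),
    met("glycine", 1.50, 0.90, anchored = FALSE),
    met("creatine", 0.50, 0.30, anchored = FALSE),
    met("succinate", 0.15, 0.09, anchored = FALSE),
    met("glycolate", 0.30, 0.18, anchored = FALSE))
  cohort_spec(list(
    control = list(n = n_control,
                   metabolites = rbind(control, background)),
    diabetic = list(n = n_diabetic,
                    metabolites = rbind(diabetic, background))))
}

draw_one <- function(n, mean_mM, sd_mM, detect, dist) {
  x <- if (sd_mM == 0) {
    rep(mean_mM, n)
  } else if (dist == "lognormal") {
    mu <- log(mean_mM^2 / sqrt(mean_mM^2 + sd_mM^2))
    sig <- sqrt(log(1 + (sd_mM / mean_mM)^2))
    stats::rlnorm(n, mu, sig)
  } else if (dist == "truncnorm") {
    pmax(stats::rnorm(n, mean_mM, sd_mM), 0)
  } else {
    stop_lfnmr("unknown distribution '", dist, "'",
               class = "lfnmr_validation_error")
  }
  if (detect < 1) x <- x * stats::rbinom(n, 1, detect)
  x
}

#' Draw per-sample metabolite concentrations for a cohort
#'
#' Samples the concentration truth table only (no spectra); useful for
#' large-n distributional checks. Zero-inflation is applied after the
#' positive draw, so undetectable samples are exact zeros.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional seed.
#' @param n_override Optional named vector of group sizes replacing the
#'   spec's.
#' @return Data frame with columns `sample`, `group` and one column per
#'   metabolite (mmol/L).
#' @export
draw_cohort_concentrations <- function(spec, seed = NULL,
                                       n_override = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    out <- list()
    for (g in names(spec$groups)) {
      gr <- spec$groups[[g]]
      n <- if (!is.null(n_override)) n_override[[g]] else gr$n
      m <- gr$metabolites
      df <- data.frame(sample = sprintf("%s_%02d", g, seq_len(n)),
                       group = g)
      for (i in seq_len(nrow(m)))
        df[[m$metabolite[i]]] <- draw_one(n, m$mean_mM[i], m$sd_mM[i],
                                          m$detect[i], m$dist[i])
      out[[g]] <- df
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}

#' Generate a synthetic urine cohort
#'
#' Draws per-sample concentrations from a [cohort_spec()] and renders each
#' sample to a noisy 1D spectrum under the acquisition configuration
#' (presaturation, T1 saturation, residual water, TSP internal standard).
#' The concentration truth table is returned for recovery testing.
#'
#' @inheritParams draw_cohort_concentrations
#' @param config An [acquisition_config()].
#' @param recipe A [preparation_recipe()] (default [biofluid_recipe()]).
#' @param library Optional metabolite library.
#' @return List with `spectra` (list of `nmr_spectrum`), `truth` (the
#'   concentration table), `groups` (character vector), `config`, `recipe`.
#' @export
generate_cohort <- function(spec, config = acquisition_config(),
                            recipe = biofluid_recipe(), seed = NULL,
                            library = NULL) {
  seeds <- derive_seeds(seed, 2L)
  truth <- draw_cohort_concentrations(spec, seed = seeds[[1]])
  met_cols <- setdiff(names(truth), c("sample", "group"))
  spectra <- with_seed(seeds[[2]], lapply(seq_len(nrow(truth)), function(i) {
    conc <- unlist(truth[i, met_cols, drop = FALSE])
    simulate_mixture_spectrum(conc, config, recipe, library, noise = TRUE)
  }))
  names(spectra) <- truth$sample
  list(spectra = spectra, truth = truth, groups = truth$group,
       config = config, recipe = recipe)
}

#' Four-method measurement table specification and generator
#'
#' Emulates a multi-method agreement study: each participant has one true
#' concentration drawn from a log-normal distribution, and every analytical
#' method reports `truth * bias * (1 + e)` with `e ~ N(0, cv)`. The default
#' mirrors a four-method urinary glucose comparison (benchtop 60 MHz NMR,
#' 400 MHz NMR, an enzymatic spectrophotometric assay and a colourimetric
#' dipstick) with method means in the ratio 92.9 : 82.0 : 98.8 : 128.7.
#'
#' @param participant_mean,participant_sd Mean and SD of the true
#'   concentration distribution (mmol/L).
#' @param n_participants Number of participants.
#' @param methods Data frame with columns `method`, `bias` (> 0) and `cv`
#'   (>= 0).
#' @return An object of class `method_comparison_spec`.
#' @export
method_comparison_spec <- function(participant_mean = 92.9,
                                   participant_sd = 60,
                                   n_participants = 24,
                                   methods = data.frame(
                                     method = c("nmr_60", "nmr_400",
                                                "godpap", "dipstick"),
                                     bias = c(1.000, 82.0 / 92.9,
                                              98.8 / 92.9, 128.7 / 92.9),
                                     cv = 0.08)) {
  check_number(participant_mean, "participant_mean", positive = TRUE)
  check_number(participant_sd, "participant_sd", nonnegative = TRUE)
  if (n_participants < 2)
    stop_lfnmr("need >= 2 participants", class = "lfnmr_validation_error")
  if (any(methods$bias <= 0))
    stop_lfnmr("method biases must be > 0",
               class = "lfnmr_validation_error")
  if (any(methods$cv < 0))
    stop_lfnmr("method CVs must be >= 0", class = "lfnmr_validation_error")
  structure(list(participant_mean = participant_mean,
                 participant_sd = participant_sd,
                 n_participants = as.integer(n_participants),
                 methods = methods),
            class = "method_comparison_spec")
}

#' @rdname method_comparison_spec
#' @param spec A `method_comparison_spec`.
#' @param seed Optional seed.
#' @return `generate_method_comparison()` returns a long-format data frame
#'   with columns `participant`, `method`, `concentration` and the hidden
#'   truth column `truth`.
#' @export
generate_method_comparison <- function(spec = method_comparison_spec(),
                                       seed = NULL) {
  stopifnot(inherits(spec, "method_comparison_spec"))
  with_seed(seed, {
    truth <- draw_one(spec$n_participants, spec$participant_mean,
                      spec$participant_sd, 1, "lognormal")
    out <- list()
    for (i in seq_len(nrow(spec$methods))) {
      m <- spec$methods[i, ]
      y <- truth * m$bias * (1 + stats::rnorm(spec$n_participants, 0, m$cv))
      out[[i]] <- data.frame(
        participant = sprintf("p%02d", seq_len(spec$n_participants)),
        method = m$method, concentration = pmax(y, 0), truth = truth)
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}
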