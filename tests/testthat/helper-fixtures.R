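# Shared fixtures: small spin systems and fast acquisition settings.

fix_single_spin <- function(ppm = 1.00) spin_system("H", ppm, 1)

fix_ethanol <- function() {
  spin_system(c("CH3", "CH2"), c(1.19, 3.65), c(3, 2),
              matrix(c(0, 7.07, 7.07, 0), 2))
}

fix_ab <- function(center_hz, delta_hz, J, field = 60) {
  spin_system(c("A", "B"),
              c(center_hz + delta_hz / 2, center_hz - delta_hz / 2) / field,
              c(1, 1), matrix(c(0, J, J, 0), 2))
}

# closed-form AB pattern: four lines, total intensity 2
ab_closed_form <- function(center_hz, delta_hz, J) {
  C <- sqrt(delta_hz^2 + J^2)
  data.frame(
    frequency_Hz = center_hz + c(-(C + J), -(C - J), C - J, C + J) / 2,
    intensity = c(1 - J / C, 1 + J / C, 1 + J / C, 1 - J / C) / 2)
}

# coarser axis / fewer points for fast rendering in tests
fix_config <- function(...) acquisition_config(...)

fix_small_cohort_spec <- function() {
  cohort_spec(list(
    control = list(n = 4, metabolites = data.frame(
      metabolite = c("hydroxybutyrate_3", "creatinine"),
      mean_mM = c(0.24, 6.3), sd_mM = c(0.1, 1.5))),
    diabetic = list(n = 4, metabolites = data.frame(
      metabolite = c("hydroxybutyrate_3", "creatinine"),
      mean_mM = c(3.12, 20.9), sd_mM = c(1.2, 5)))))
}
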