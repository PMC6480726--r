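# Metabolite spin-system library: a human-editable YAML file shipping the
# shifts, couplings, proton counts and relaxation times used by the
# synthetic-sample generators.

.lfnmr_cache <- new.env(parent = emptyenv())

#' Load the metabolite spin-system library
#'
#' Reads the structured text (YAML) library of urine metabolites. Each entry
#' carries one or more components (e.g. glucose anomers with their
#' equilibrium abundances), each holding coupled spin subsystems with a
#' per-value source note.
#'
#' @param path Path to a library file; default is the library shipped with
#'   the package.
#' @return A named list of metabolite entries (class `metabolite_library`).
#' @export
metabolite_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "metabolite_library.yaml",
                        package = "lfnmr")
    if (!is.null(.lfnmr_cache$library))
      return(.lfnmr_cache$library)
  }
  lib <- yaml::read_yaml(path)
  for (nm in names(lib)) {
    for (ci in seq_along(lib[[nm]]$components)) {
      comp <- lib[[nm]]$components[[ci]]
      lib[[nm]]$components[[ci]]$subsystems <-
        lapply(comp$subsystems, parse_subsystem)
    }
  }
  class(lib) <- "metabolite_library"
  if (grepl("metabolite_library.yaml$", path) &&
      identical(path, system.file("extdata", "metabolite_library.yaml",
                                  package = "lfnmr")))
    .lfnmr_cache$library <- lib
  lib
}

parse_subsystem <- function(sub) {
  n <- length(sub$labels)
  J <- matrix(0, n, n, dimnames = list(sub$labels, sub$labels))
  for (cp in sub$couplings) {
    J[cp[[1]], cp[[2]]] <- as.numeric(cp[[3]])
    J[cp[[2]], cp[[1]]] <- as.numeric(cp[[3]])
  }
  spin_system(sub$labels, as.numeric(sub$shifts_ppm),
              as.numeric(sub$protons), J,
              t1_s = as.numeric(sub$t1_s), t2_s = as.numeric(sub$t2_s))
}

#' Transition lines of a library metabolite
#'
#' Computes (and caches) the exact transition list of every subsystem of a
#' metabolite at the requested field, scaled by component abundances so that
#' total intensity equals the abundance-weighted proton count per unit
#' concentration. Each line carries the T1 of the spin group it is closest
#' to in frequency, used for repetition-time saturation corrections.
#'
#' @param name Metabolite name (a key of [metabolite_library()]).
#' @param field_MHz Spectrometer frequency.
#' @param library Optional library object.
#' @return Data frame with columns `frequency_Hz`, `intensity`, `t1_s`.
#' @export
metabolite_lines <- function(name, field_MHz, library = NULL) {
  lib <- if (is.null(library)) metabolite_library() else library
  if (!name %in% names(lib))
    stop_lfnmr("unknown metabolite '", name, "'; library entries: ",
               paste(names(lib), collapse = ", "),
               class = "lfnmr_unknown_analyte_error")
  key <- paste0(name, "@", field_MHz)
  use_cache <- is.null(library)
  if (use_cache && !is.null(.lfnmr_cache[[key]]))
    return(.lfnmr_cache[[key]])
  out <- list()
  for (comp in lib[[name]]$components) {
    for (sub in comp$subsystems) {
      tr <- compute_transitions(sub, field_MHz)
      shifts_hz <- sub$shifts_ppm * field_MHz
      grp <- vapply(tr$frequency_Hz,
                    function(f) which.min(abs(shifts_hz - f)), 1L)
      out[[length(out) + 1L]] <- data.frame(
        frequency_Hz = tr$frequency_Hz,
        intensity = tr$intensity * comp$abundance,
        t1_s = sub$t1_s[grp])
    }
  }
  lines <- do.call(rbind, out)
  if (use_cache) .lfnmr_cache[[key]] <- lines
  lines
}

#' First-order multiplet span
#'
#' Width in ppm wholly encompassed by a first-order multiplet: a group
#' coupled to `n_partners` equivalent protons splits into `n_partners + 1`
#' lines spaced `J_Hz`, spanning `n_partners * J_Hz` Hz, i.e.
#' `n_partners * J_Hz / field_MHz` ppm. Multiplets therefore occupy
#' field-ratio-fold more of the ppm axis at low field (e.g. the ethanol CH3
#' triplet, J = 7.07 Hz: 2 x 7.07/60 = 0.236 ppm at 60 MHz against
#' 2 x 7.07/400 = 0.035 ppm at 400 MHz).
#'
#' @param J_Hz Scalar coupling in Hz.
#' @param n_partners Number of equivalent coupling partners.
#' @param field_MHz Spectrometer frequency.
#' @return Span in ppm.
#' @export
first_order_span_ppm <- function(J_Hz, n_partners, field_MHz) {
  check_number(J_Hz, "J_Hz", nonnegative = TRUE)
  check_number(n_partners, "n_partners", positive = TRUE)
  check_number(field_MHz, "field_MHz", positive = TRUE)
  n_partners * J_Hz / field_MHz
}
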