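#' Define a small proton spin system
#'
#' A spin system is a set of groups of magnetically equivalent protons, each
#' with a chemical shift, an equivalent-proton count, relaxation times, and a
#' symmetric scalar-coupling matrix between groups. It is the physics unit of
#' the 1D spectrum simulator: [compute_transitions()] diagonalises the
#' isotropic spin Hamiltonian of the system exactly, so second-order
#' (strong-coupling) effects at low field emerge naturally.
#'
#' Groups that are not scalar-coupled to any other group never need to enter
#' a joint Hamiltonian, so the size limit applies per coupled block: after
#' expanding equivalent protons into individual spins, every
#' coupling-connected block must contain at most 8 spins. Larger molecules
#' must be split into subsystems (glucose, for example, is modelled as two
#' anomeric C1-H/C2-H pairs plus an uncoupled bulk-ring envelope).
#'
#' @param labels Character vector of spin-group names.
#' @param shifts_ppm Numeric chemical shifts, one per group.
#' @param protons Positive integer equivalent-proton count per group.
#' @param couplings_Hz Symmetric matrix of scalar couplings between groups in
#'   Hz (zero diagonal). Defaults to no coupling.
#' @param t1_s,t2_s Per-group longitudinal / transverse relaxation times in
#'   seconds.
#' @return An object of class `spin_system`.
#' @examples
#' # ethanol CH3-CH2 fragment, J = 7.07 Hz
#' ethanol <- spin_system(
#'   labels = c("CH3", "CH2"), shifts_ppm = c(1.19, 3.65),
#'   protons = c(3, 2), couplings_Hz = matrix(c(0, 7.07, 7.07, 0), 2))
#' @export
spin_system <- function(labels, shifts_ppm, protons,
                        couplings_Hz = NULL, t1_s = NULL, t2_s = NULL) {
  n <- length(labels)
  if (n == 0L)
    stop_lfnmr("spin system needs at least one group",
               class = "lfnmr_validation_error")
  if (length(shifts_ppm) != n || length(protons) != n)
    stop_lfnmr("labels, shifts_ppm and protons must have equal length",
               class = "lfnmr_validation_error")
  if (!all(is.finite(shifts_ppm)))
    stop_lfnmr("all chemical shifts must be finite",
               class = "lfnmr_validation_error")
  if (any(protons < 1) || any(protons != round(protons)))
    stop_lfnmr("protons must be positive integers",
               class = "lfnmr_validation_error")
  if (is.null(couplings_Hz)) couplings_Hz <- matrix(0, n, n)
  couplings_Hz <- as.matrix(couplings_Hz)
  if (!identical(dim(couplings_Hz), c(n, n)) ||
      !isTRUE(all.equal(couplings_Hz, t(couplings_Hz), tolerance = 1e-12)) ||
      any(abs(diag(couplings_Hz)) > 0))
    stop_lfnmr("couplings_Hz must be a symmetric ", n, "x", n,
               " matrix with zero diagonal",
               class = "lfnmr_validation_error")
  if (is.null(t1_s)) t1_s <- rep(1.5, n)
  if (is.null(t2_s)) t2_s <- rep(0.6, n)
  if (any(t1_s <= 0) || any(t2_s <= 0))
    stop_lfnmr("relaxation times must be positive",
               class = "lfnmr_validation_error")
  structure(list(labels = as.character(labels),
                 shifts_ppm = as.numeric(shifts_ppm),
                 protons = as.integer(protons),
                 couplings_Hz = couplings_Hz,
                 t1_s = as.numeric(rep_len(t1_s, n)),
                 t2_s = as.numeric(rep_len(t2_s, n))),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %d group(s), %d protons\n",
              length(x$labels), sum(x$protons)))
  df <- data.frame(group = x$labels, shift_ppm = x$shifts_ppm,
                   protons = x$protons, t1_s = x$t1_s, t2_s = x$t2_s)
  print(df, row.names = FALSE)
  if (any(x$couplings_Hz != 0)) {
    cat("couplings (Hz):\n")
    print(x$couplings_Hz)
  }
  invisible(x)
}

# Connected components of the group-level coupling graph.
coupling_blocks <- function(J) {
  n <- nrow(J)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      g <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[g])) next
      comp[g] <- k
      queue <- c(queue, which(J[g, ] != 0 & is.na(comp)))
    }
  }
  split(seq_len(n), comp)
}

# Pauli-style single-spin operators (spin 1/2, units of hbar = 1).
.op_iz <- matrix(c(0.5, 0, 0, -0.5), 2, 2)
.op_ip <- matrix(c(0, 0, 1, 0), 2, 2)  # I+ (column-major)
.op_im <- t(.op_ip)
.op_ix <- (.op_ip + .op_im) / 2

# Embed single-spin operator `op` at position k among n spins.
embed_op <- function(op, k, n) {
  out <- 1
  for (i in seq_len(n)) {
    out <- kronecker(out, if (i == k) op else diag(2))
  }
  out
}

# Exact transitions of one coupled block of individual spins.
# shifts_hz: per-spin Larmor offsets; J: per-spin coupling matrix (Hz).
block_transitions <- function(shifts_hz, J) {
  n <- length(shifts_hz)
  if (n == 1L) {
    return(data.frame(frequency_Hz = shifts_hz, intensity_raw = 0.25))
  }
  dim2 <- 2L^n
  H <- matrix(0, dim2, dim2)
  Ix_tot <- matrix(0, dim2, dim2)
  iz <- vector("list", n); ip <- vector("list", n); im <- vector("list", n)
  for (k in seq_len(n)) {
    iz[[k]] <- embed_op(.op_iz, k, n)
    ip[[k]] <- embed_op(.op_ip, k, n)
    im[[k]] <- embed_op(.op_im, k, n)
    H <- H + shifts_hz[k] * iz[[k]]
    Ix_tot <- Ix_tot + embed_op(.op_ix, k, n)
  }
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      if (J[a, b] == 0) next
      H <- H + J[a, b] * (iz[[a]] %*% iz[[b]] +
                            (ip[[a]] %*% im[[b]] + im[[a]] %*% ip[[b]]) / 2)
    }
  }
  eig <- eigen(H, symmetric = TRUE)
  M <- crossprod(eig$vectors, Ix_tot %*% eig$vectors)
  idx <- which(upper.tri(M) & abs(M) > 1e-12, arr.ind = TRUE)
  freq <- abs(eig$values[idx[, 1]] - eig$values[idx[, 2]])
  data.frame(frequency_Hz = freq, intensity_raw = M[idx]^2)
}

#' Compute NMR transitions by exact Hamiltonian diagonalisation
#'
#' Builds the isotropic spin Hamiltonian
#' \eqn{H = \sum_i \nu_i I_{zi} + \sum_{i<j} J_{ij} \, I_i \cdot I_j}
#' (in Hz, with \eqn{\nu_i = \delta_i \times} `field_MHz` measured from the
#' 0 ppm reference), diagonalises it exactly within each coupling-connected
#' block, and returns line positions and intensities. Intensities are squared
#' matrix elements of total \eqn{I_x} between eigenstates, rescaled so that
#' the total intensity equals the total proton count of the system.
#' Degenerate lines are merged and lines below `prune` proton-equivalents are
#' dropped.
#'
#' @param system A [spin_system()].
#' @param field_MHz Spectrometer frequency in MHz.
#' @param prune Intensity threshold in proton-equivalents (default `1e-6`).
#' @return A data frame of class `transition_list` with columns
#'   `frequency_Hz` (relative to 0 ppm) and `intensity`.
#' @examples
#' s <- spin_system("CH", 1.00, 1)
#' compute_transitions(s, 60)  # a single line at 60 Hz, intensity 1
#' @export
compute_transitions <- function(system, field_MHz, prune = 1e-6) {
  if (!inherits(system, "spin_system"))
    stop_lfnmr("system must be a spin_system",
               class = "lfnmr_validation_error")
  check_number(field_MHz, "field_MHz", positive = TRUE)
  blocks <- coupling_blocks(system$couplings_Hz)
  total_protons <- sum(system$protons)
  out <- list()
  for (grp_idx in blocks) {
    n_spins <- sum(system$protons[grp_idx])
    if (length(grp_idx) == 1L) {
      # uncoupled group of equivalent protons: one line, no expansion needed
      out[[length(out) + 1L]] <- data.frame(
        frequency_Hz = system$shifts_ppm[grp_idx] * field_MHz,
        intensity = as.numeric(system$protons[grp_idx]))
      next
    }
    if (n_spins > 8L)
      stop_lfnmr("coupled block {", paste(system$labels[grp_idx],
                                          collapse = ", "),
                 "} expands to ", n_spins,
                 " spins; the exact-diagonalisation limit is 8. ",
                 "Split the molecule into smaller subsystems.",
                 class = "lfnmr_size_error")
    spin_group <- rep(grp_idx, system$protons[grp_idx])
    shifts_hz <- system$shifts_ppm[spin_group] * field_MHz
    Jspin <- system$couplings_Hz[spin_group, spin_group]
    # equivalent protons: couplings within a group do not affect the
    # spectrum, so zero them for numerical cleanliness
    same <- outer(spin_group, spin_group, "==")
    Jspin[same] <- 0
    tr <- block_transitions(shifts_hz, Jspin)
    # raw intensities within the block sum to n_spins * 2^n / 8
    tr$intensity <- tr$intensity_raw * n_spins / sum(tr$intensity_raw)
    out[[length(out) + 1L]] <- tr[, c("frequency_Hz", "intensity")]
  }
  tr <- do.call(rbind, out)
  # merge degenerate lines (1e-6 Hz resolution), prune negligible ones
  key <- round(tr$frequency_Hz / 1e-6)
  agg <- rowsum(cbind(f = tr$frequency_Hz * tr$intensity, i = tr$intensity),
                group = key)
  tr <- data.frame(frequency_Hz = agg[, "f"] / agg[, "i"],
                   intensity = agg[, "i"])
  tr <- tr[tr$intensity >= prune, , drop = FALSE]
  tr <- tr[order(tr$frequency_Hz), , drop = FALSE]
  rownames(tr) <- NULL
  # pruning removes at most prune * n_lines of intensity; restore the exact
  # proton-count normalisation
  tr$intensity <- tr$intensity * total_protons / sum(tr$intensity)
  class(tr) <- c("transition_list", "data.frame")
  attr(tr, "field_MHz") <- field_MHz
  attr(tr, "total_protons") <- total_protons
  tr
}
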