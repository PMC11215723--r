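# Dipolar relaxation rates under isotropic rotational diffusion.
#
# Convention (self-consistent; any global convention cancels in relative
# epitopes): unnormalized Lorentzian spectral density J(w) = tau_c /
# (1 + w^2 tau_c^2), with the 1/10 factor folded into the dipolar constant
#   q = (mu0/4pi)^2 gammaH^4 hbar^2 / 10  [m^6 s^-2 when multiplied by J].
# Cross-relaxation sigma = q r^-6 (6 J(2w0) - J(0)); auto-relaxation
# rho_i = sum_j q r_ij^-6 (6 J(2w0) + 3 J(w0) + J(0)). sigma < 0 in the
# slow-tumbling (spin-diffusion) regime that drives saturation transfer.

# CODATA: mu0/4pi (T m/A), proton gyromagnetic ratio (rad s^-1 T^-1),
# reduced Planck constant (J s)
.MU0_4PI <- 1e-7
.GAMMA_H <- 2.6752218744e8
.HBAR <- 1.054571817e-34
.DIPOLAR_Q <- (.MU0_4PI)^2 * .GAMMA_H^4 * .HBAR^2 / 10

.ANGSTROM <- 1e-10
.MIN_DISTANCE <- 0.5 # Angstrom; below this a pair is treated as a clash

#' Relaxation parameter set
#'
#' @param frequency_mhz Proton Larmor frequency in MHz (sanity range
#'   100-1500; a warning is emitted outside it).
#' @param tau_c_ns Rotational correlation time of the bound complex (ns).
#' @param tau_c_free_ns Correlation time of the free species (ns); used only
#'   by the full-matrix oracle.
#' @param cutoff Distance cutoff in Angstrom for protein-proton pruning.
#' @param methyl_averaging If `TRUE`, rates to/from the three protons of a
#'   methyl group are replaced by their arithmetic mean (equivalent to
#'   <r^-6> averaging, since sigma is linear in r^-6 at fixed tau_c).
#' @return A `relaxation_params` list.
#' @export
relaxation_params <- function(frequency_mhz, tau_c_ns, tau_c_free_ns = 0.5,
                              cutoff = 10, methyl_averaging = FALSE) {
  stopifnot(frequency_mhz > 0, tau_c_ns > 0, tau_c_free_ns > 0, cutoff > 0)
  if (frequency_mhz < 100 || frequency_mhz > 1500) {
    warning(sprintf("frequency_mhz = %g is outside the usual 100-1500 MHz range",
                    frequency_mhz))
  }
  structure(
    list(frequency_mhz = frequency_mhz, tau_c_ns = tau_c_ns,
         tau_c_free_ns = tau_c_free_ns, cutoff = cutoff,
         methyl_averaging = isTRUE(methyl_averaging)),
    class = "relaxation_params"
  )
}

#' Lorentzian spectral density
#'
#' `J(w) = tau_c / (1 + w^2 tau_c^2)` (unnormalized convention; units s).
#'
#' @param omega Angular frequency (rad/s), vectorized.
#' @param tau_c Correlation time (s, > 0).
#' @export
spectral_density <- function(omega, tau_c) {
  stopifnot(tau_c > 0)
  tau_c / (1 + (omega * tau_c)^2)
}

omega0 <- function(params) 2 * pi * params$frequency_mhz * 1e6

#' Pairwise dipolar cross-relaxation rate
#'
#' `sigma = q r^-6 (6 J(2 w0) - J(0))` in s^-1, with r in Angstrom
#' (converted to metres internally). Negative for slowly tumbling species.
#'
#' @param r Internuclear distance(s), Angstrom (> 0.5 A clash guard).
#' @param params A [relaxation_params()] object.
#' @param tau_c Correlation time in seconds (defaults to the bound-state
#'   `tau_c_ns` of `params`).
#' @param pair_label Optional label used in the clash-guard error message.
#' @export
cross_relaxation_rate <- function(r, params, tau_c = params$tau_c_ns * 1e-9,
                                  pair_label = NULL) {
  if (any(r <= .MIN_DISTANCE)) {
    bad <- which(r <= .MIN_DISTANCE)[1]
    stop(sprintf(
      "internuclear distance %.3f A below the %.1f A clash guard%s",
      r[bad], .MIN_DISTANCE,
      if (is.null(pair_label)) "" else paste0(" for pair ", pair_label[bad])))
  }
  w0 <- omega0(params)
  .DIPOLAR_Q * (r * .ANGSTROM)^-6 *
    (6 * spectral_density(2 * w0, tau_c) - spectral_density(0, tau_c))
}

#' Dipolar auto-relaxation rate of one proton
#'
#' `rho_i = sum_j q r_ij^-6 (6 J(2 w0) + 3 J(w0) + J(0)) + leak`.
#'
#' @param r Distances (Angstrom) from proton i to each neighbour.
#' @param params A [relaxation_params()] object.
#' @param tau_c Correlation time in seconds.
#' @param leak External-relaxation leakage rate, s^-1 (default 0).
#' @export
auto_relaxation_rate <- function(r, params, tau_c = params$tau_c_ns * 1e-9,
                                 leak = 0) {
  stopifnot(length(r) >= 1L)
  if (any(r <= .MIN_DISTANCE)) {
    stop(sprintf("neighbour distance %.3f A below the %.1f A clash guard",
                 min(r), .MIN_DISTANCE))
  }
  w0 <- omega0(params)
  jsum <- 6 * spectral_density(2 * w0, tau_c) +
    3 * spectral_density(w0, tau_c) + spectral_density(0, tau_c)
  sum(.DIPOLAR_Q * (r * .ANGSTROM)^-6 * jsum) + leak
}

pairwise_distances <- function(a_xyz, b_xyz) {
  # |A| x |B| Euclidean distance matrix, Angstrom
  a2 <- rowSums(a_xyz^2)
  b2 <- rowSums(b_xyz^2)
  d2 <- outer(a2, b2, "+") - 2 * a_xyz %*% t(b_xyz)
  sqrt(pmax(d2, 0))
}

#' Cross-relaxation block between two proton sets
#'
#' Builds the |A| x |B| matrix of sigma rates from current coordinates.
#' With `params$methyl_averaging`, entries belonging to a 3-proton methyl
#' group (along either axis) are replaced by the group mean, which
#' conserves the summed cross-relaxation of the trio.
#'
#' @param protons_a,protons_b Disjoint proton data.frames (as in a
#'   `spin_system`), each with `x`, `y`, `z` and optional `methyl_id`.
#' @param params A [relaxation_params()] object.
#' @param tau_c Correlation time (s).
#' @return A numeric matrix of rates, s^-1, with dimnames from
#'   `residue_id:atom_name`.
#' @export
build_block <- function(protons_a, protons_b, params,
                        tau_c = params$tau_c_ns * 1e-9) {
  a_xyz <- as.matrix(protons_a[, c("x", "y", "z")])
  b_xyz <- as.matrix(protons_b[, c("x", "y", "z")])
  d <- pairwise_distances(a_xyz, b_xyz)
  if (any(d <= .MIN_DISTANCE)) {
    idx <- which(d <= .MIN_DISTANCE, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "distance %.3f A between %s:%s and %s:%s is below the %.1f A clash guard (overlapping atoms?)",
      d[idx[1], idx[2]],
      protons_a$residue_id[idx[1]], protons_a$atom_name[idx[1]],
      protons_b$residue_id[idx[2]], protons_b$atom_name[idx[2]],
      .MIN_DISTANCE))
  }
  w0 <- omega0(params)
  jdiff <- 6 * spectral_density(2 * w0, tau_c) - spectral_density(0, tau_c)
  sig <- .DIPOLAR_Q * (d * .ANGSTROM)^-6 * jdiff
  dimnames(sig) <- list(
    paste0(protons_a$residue_id, ":", protons_a$atom_name),
    paste0(protons_b$residue_id, ":", protons_b$atom_name)
  )
  if (params$methyl_averaging) {
    sig <- average_methyl(sig, protons_a$methyl_id, margin = 1L)
    sig <- average_methyl(sig, protons_b$methyl_id, margin = 2L)
  }
  sig
}

average_methyl <- function(mat, methyl_id, margin) {
  if (is.null(methyl_id)) return(mat)
  for (id in unique(methyl_id[!is.na(methyl_id)])) {
    idx <- which(!is.na(methyl_id) & methyl_id == id)
    if (length(idx) < 2L) next
    if (margin == 1L) {
      mat[idx, ] <- rep(colMeans(mat[idx, , drop = FALSE]),
                        each = length(idx))
    } else {
      mat[, idx] <- rowMeans(mat[, idx, drop = FALSE])
    }
  }
  mat
}

#' Correlation time at which cross-relaxation changes sign
#'
#' Solves `6 J(2 w0) = J(0)` for tau_c at a given spectrometer frequency:
#' the closed-form root is `tau_c = sqrt(5)/(2 w0)`.
#'
#' @param frequency_mhz Proton frequency in MHz.
#' @return tau_c in seconds.
#' @export
sigma_zero_crossing_tau <- function(frequency_mhz) {
  sqrt(5) / (2 * 2 * pi * frequency_mhz * 1e6)
}
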