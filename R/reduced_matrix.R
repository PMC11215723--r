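# The reduced matrix M and calculated initial slopes.
#
# M stacks three row-blocks, each a cross-relaxation block into the directly
# saturated protein protons multiplied by the thermal-equilibrium intensity
# of those saturated spins:
#   E1  rows: R_E1E2   . I_E2,0   (free protein; computed but inert for the
#                                  ligand epitope)
#   L'  rows: R_L'E2'  . I_E2',0  (bound ligand -- these rows ARE the
#                                  calculated initial slopes)
#   E1' rows: R_E1'E2' . I_E2',0  (bound, unsaturated protein)
# Thermal-equilibrium intensities are proportional to species
# concentrations: I_E2',0 ~ [PL], I_E2,0 ~ [P]_free. The overall intensity
# scale is arbitrary because epitopes are reported relative (max = 100%).
#
# STD0 for ligand proton k is the t -> 0 slope of its STD factor: with the
# saturated spins clamped at zero, dI_k/dt|0 = -sum_j sigma_kj (0 - I_E2',0)
# and STD0_k = -(dI_k/dt)/I_k,0. Normalizing by the total ligand intensity
# (the observed resonance pools free + bound under fast exchange) gives
#   STD0_k = -[PL]/[L]_tot * sum_j sigma_kj ,
# positive in the slow-tumbling sigma < 0 regime. Relayed (protein-mediated)
# pathways are second order in time and absent from the slope by
# construction: that is the key approximation of the reduced approach.

#' Assemble the reduced matrix M
#'
#' @param system A scorable, pruned `spin_system` (run [select_saturated()]
#'   and [apply_cutoff()] first).
#' @param params A [relaxation_params()] object; the bound-state `tau_c_ns`
#'   is used for every block.
#' @param binding A [solve_binding()] result.
#' @return A `reduced_m` object with row-blocks `L_block` (ligand rows),
#'   `E1_block`, `E1p_block`, the proton tables of each partition, and the
#'   intensity scalars used.
#' @export
assemble_M <- function(system, params, binding) {
  stopifnot(inherits(system, "spin_system"),
            inherits(params, "relaxation_params"),
            inherits(binding, "binding_state"))
  if (!system$scorable) {
    stop("spin system is un-scorable: needs >= 1 ligand proton and >= 1 ",
         "saturated protein proton after cutoff pruning")
  }
  pr <- system$protons
  lig <- pr[pr$group == "LIGAND", , drop = FALSE]
  sat <- pr[pr$group == "SATURATED_PROTEIN", , drop = FALSE]
  uns <- pr[pr$group == "UNSATURATED_PROTEIN", , drop = FALSE]

  tau_b <- params$tau_c_ns * 1e-9
  i_e2p0 <- binding$complex_conc   # bound saturated protons ~ [PL]
  i_e20 <- binding$free_protein    # free saturated protons ~ [P]_free

  sig_L <- build_block(lig, sat, params, tau_b)
  L_block <- sig_L * i_e2p0
  if (nrow(uns)) {
    sig_E <- build_block(uns, sat, params, tau_b)
    E1_block <- sig_E * i_e20    # free-state term of Scheme-style M; inert
    E1p_block <- sig_E * i_e2p0  # bound-state protein rows
  } else {
    E1_block <- E1p_block <- matrix(0, 0, nrow(sat))
  }
  structure(
    list(L_block = L_block, E1_block = E1_block, E1p_block = E1p_block,
         ligand = lig, saturated = sat, unsaturated = uns,
         i_e2p0 = i_e2p0, i_e20 = i_e20,
         params = params, binding = binding),
    class = "reduced_m"
  )
}

#' Calculated initial slopes from the reduced matrix
#'
#' Per ligand proton k: `STD0_k = -(rowsum of the L' block)_k / I_k0` with
#' `I_k0` the total ligand intensity (`[L]_tot`), then normalized so the
#' largest value is exactly 100%.
#'
#' @param M A `reduced_m` from [assemble_M()].
#' @return A `calculated_epitope` data.frame with columns `epitope_key`
#'   (NA for protons excluded from comparison, e.g. exchangeables),
#'   `atom_name`, `std0_abs` (s^-1, arbitrary global scale) and
#'   `rel` (percent, max = 100).
#' @export
std0_calc <- function(M) {
  stopifnot(inherits(M, "reduced_m"))
  if (all(M$L_block == 0)) {
    stop("no saturation pathway: the ligand/saturated-proton block is all zero")
  }
  std0 <- -rowSums(M$L_block) / M$binding$ligand_total
  mx <- max(std0)
  if (mx <= 0) {
    stop("no saturation transfer: all calculated STD0 are <= 0 ",
         "(fast-tumbling sigma > 0 regime)")
  }
  out <- data.frame(
    epitope_key = M$ligand$epitope_key,
    atom_name = M$ligand$atom_name,
    std0_abs = std0,
    rel = 100 * std0 / mx,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("calculated_epitope", "data.frame")
  out
}

#' Aggregate calculated STD0 over shared epitope keys
#'
#' Protons sharing an `epitope_key` (methyl trios, degenerate pairs) report
#' a single experimental value; their absolute calculated STD0 are averaged
#' (arithmetic mean) before renormalization to max = 100%.
#'
#' @param epitope A `calculated_epitope` from [std0_calc()].
#' @param keys Optional named character vector mapping `atom_name` to a new
#'   epitope key (e.g. `c(H61 = "H6", H62 = "H6")`); atoms not named keep
#'   their current key. Keys matching no proton are an error.
#' @return Aggregated `calculated_epitope` (one row per key; keyless
#'   protons are dropped).
#' @export
aggregate_by_key <- function(epitope, keys = NULL) {
  stopifnot(inherits(epitope, "calculated_epitope"))
  key <- epitope$epitope_key
  if (!is.null(keys)) {
    if (is.null(names(keys)) || any(!nzchar(names(keys)))) {
      stop("`keys` must be a named character vector (atom_name -> key)")
    }
    missing <- setdiff(names(keys), epitope$atom_name)
    if (length(missing)) {
      stop("epitope keys reference protons absent from the epitope: ",
           paste(missing, collapse = ", "))
    }
    hit <- match(epitope$atom_name, names(keys))
    key[!is.na(hit)] <- keys[hit[!is.na(hit)]]
  }
  keep <- !is.na(key)
  if (!any(keep)) stop("no protons carry an epitope key after mapping")
  agg <- tapply(epitope$std0_abs[keep], key[keep], mean)
  out <- data.frame(
    epitope_key = names(agg),
    atom_name = names(agg),
    std0_abs = as.numeric(agg),
    rel = 100 * as.numeric(agg) / max(agg),
    stringsAsFactors = FALSE
  )
  # preserve first-appearance order of keys
  ord <- order(match(out$epitope_key, key[keep]))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("calculated_epitope", "data.frame")
  out
}

#' One-call calculated epitope for a prepared spin system
#'
#' Convenience wrapper: [assemble_M()], [std0_calc()], [aggregate_by_key()].
#'
#' @inheritParams assemble_M
#' @param keys Optional key map passed to [aggregate_by_key()].
#' @export
calculated_epitope <- function(system, params, binding, keys = NULL) {
  aggregate_by_key(std0_calc(assemble_M(system, params, binding)), keys)
}
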