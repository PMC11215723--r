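# 1:1 binding equilibrium. Concentrations in micromolar throughout; the
# complex concentration sets the thermal-equilibrium intensity scale of the
# bound-state spins in the reduced matrix.

#' Solve the 1:1 binding equilibrium
#'
#' Physical root of the binding quadratic for `P + L <-> PL` with
#' dissociation constant `Kd`:
#' `[PL] = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / 2`.
#'
#' @param protein_total Total protein concentration (uM, > 0).
#' @param ligand_total Total ligand concentration (uM, > 0).
#' @param kd Dissociation constant (uM, > 0).
#' @return A `binding_state` list: `protein_total`, `ligand_total`, `kd`,
#'   `complex_conc`, `free_protein`, `free_ligand`,
#'   `bound_fraction_ligand`, all uM except the dimensionless fraction.
#' @examples
#' solve_binding(20, 1000, 2000)$complex_conc  # ~6.64 uM
#' @export
solve_binding <- function(protein_total, ligand_total, kd) {
  vals <- c(protein_total = protein_total, ligand_total = ligand_total,
            kd = kd)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("protein_total, ligand_total and kd must all be finite and > 0 ",
         "(uM); got ", paste(sprintf("%s=%g", names(vals), vals),
                             collapse = ", "))
  }
  s <- protein_total + ligand_total + kd
  disc <- s^2 - 4 * protein_total * ligand_total
  # disc >= (P - L)^2 + Kd^2 > 0 analytically; clamp tiny negative rounding
  complex_conc <- (s - sqrt(max(disc, 0))) / 2
  complex_conc <- min(max(complex_conc, 0), protein_total, ligand_total)
  structure(
    list(
      protein_total = protein_total,
      ligand_total = ligand_total,
      kd = kd,
      complex_conc = complex_conc,
      free_protein = protein_total - complex_conc,
      free_ligand = ligand_total - complex_conc,
      bound_fraction_ligand = complex_conc / ligand_total
    ),
    class = "binding_state"
  )
}

#' @export
print.binding_state <- function(x, ...) {
  cat(sprintf(
    "<binding_state> P=%g uM, L=%g uM, Kd=%g uM -> [PL]=%.4g uM (ligand bound fraction %.3g)\n",
    x$protein_total, x$ligand_total, x$kd, x$complex_conc,
    x$bound_fraction_ligand))
  invisible(x)
}
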