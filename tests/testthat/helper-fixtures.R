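# Shared builders for the test suite. The sigma_ref/j_ref oracles are
# deliberately re-typed one-line evaluations, independent of the package's
# relaxation code path.

default_params <- function(cutoff = 12, ...) {
  relaxation_params(600, 34.5, tau_c_free_ns = 0.3, cutoff = cutoff, ...)
}

default_binding <- function() solve_binding(20, 1000, 2000)

# independent scalar oracles (constants re-typed on purpose)
j_ref <- function(omega, tau) tau / (1 + omega^2 * tau^2)

sigma_ref <- function(r_angstrom, freq_mhz, tau_s) {
  q <- (1e-7)^2 * (2.6752218744e8)^4 * (1.054571817e-34)^2 / 10
  w0 <- 2 * pi * freq_mhz * 1e6
  q * (r_angstrom * 1e-10)^-6 * (6 * j_ref(2 * w0, tau_s) - j_ref(0, tau_s))
}

rho_ref <- function(r_angstrom, freq_mhz, tau_s) {
  q <- (1e-7)^2 * (2.6752218744e8)^4 * (1.054571817e-34)^2 / 10
  w0 <- 2 * pi * freq_mhz * 1e6
  sum(q * (r_angstrom * 1e-10)^-6 *
        (6 * j_ref(2 * w0, tau_s) + 3 * j_ref(w0, tau_s) + j_ref(0, tau_s)))
}

# protein of single-HA GLY residues at x = dists, ligand H1 at the origin;
# returns a parsed, saturated spin_system plus the file paths
line_complex <- function(dists, saturate = seq_along(dists), dir = tempdir()) {
  prot <- do.call(rbind, lapply(seq_along(dists), function(i) {
    rbind(
      data.frame(atom_name = "CA", residue_name = "GLY", residue_id = i,
                 x = dists[i], y = 0, z = 1.09, element = "C",
                 is_hydrogen = FALSE),
      data.frame(atom_name = "HA", residue_name = "GLY", residue_id = i,
                 x = dists[i], y = 0, z = 0, element = "H",
                 is_hydrogen = TRUE)
    )
  }))
  lig <- rbind(
    data.frame(atom_name = "C1", residue_name = "LIG", residue_id = 1,
               x = 0, y = 0, z = -1.09, element = "C", is_hydrogen = FALSE),
    data.frame(atom_name = "H1", residue_name = "LIG", residue_id = 1,
               x = 0, y = 0, z = 0, element = "H", is_hydrogen = TRUE)
  )
  pf <- tempfile("prot", tmpdir = dir, fileext = ".pdb")
  lf <- tempfile("lig", tmpdir = dir, fileext = ".pdb")
  write_pdb_frames(prot, as.matrix(prot[, c("x", "y", "z")]), pf)
  write_pdb_frames(lig, as.matrix(lig[, c("x", "y", "z")]), lf)
  sys <- parse_complex(pf, lf)
  sys <- select_saturated(sys, paste0(saturate, ":HA"))
  list(system = sys, protein_pdb = pf, ligand_pdb = lf)
}

# acceptance-surface fixture ladder used by the oracle-equivalence checks
oracle_fixture_set <- function() {
  list(
    two_spin_3.0 = make_spin_fixture("two_spin", r = 3.0),
    two_spin_2.2 = make_spin_fixture("two_spin", r = 2.2),
    three_spin = make_spin_fixture("three_spin"),
    methyl_probe_1 = make_spin_fixture("methyl_probe", n_ligand = 1),
    methyl_probe_2 = make_spin_fixture("methyl_probe", n_ligand = 2),
    random_cloud = make_spin_fixture("random_cloud", seed = 7,
                                     n_ligand = 3, n_sat = 3, n_unsat = 2)
  )
}
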