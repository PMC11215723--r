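# Deterministic synthetic fixtures: toy spin systems, a miniature
# protein-ligand complex, build-up curves and scripted trajectories.
#
# Ground-truth sidecars are computed here with straight-line arithmetic
# loops (distances, r^-6 sums) that deliberately do not call the
# relaxation/reduced-matrix code they are used to test. All randomness sits
# behind an explicit seed; identical spec + seed => identical output.

# -- geometry helpers --------------------------------------------------------

unit <- function(v) v / sqrt(sum(v^2))

# three tetrahedral hydrogens (1.09 A) around carbon c, axis pointing away
# from the atom the methyl is bonded to
methyl_h_coords <- function(c_pos, axis, phase = 0) {
  u <- unit(axis)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- unit(ref - sum(ref * u) * u)
  v2 <- c(u[2] * v1[3] - u[3] * v1[2],
          u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  ang <- 70.5 * pi / 180
  t(vapply(0:2, function(k) {
    th <- phase + 2 * pi * k / 3
    c_pos + 1.09 * (cos(ang) * u + sin(ang) * (cos(th) * v1 + sin(th) * v2))
  }, numeric(3)))
}

atom_row <- function(name, resname, resid, xyz) {
  data.frame(atom_name = name, residue_name = resname, residue_id = resid,
             x = xyz[1], y = xyz[2], z = xyz[3],
             element = if (substring(sub("^[0-9]*", "", name), 1, 1) == "H")
               "H" else substring(sub("^[0-9]*", "", name), 1, 1),
             is_hydrogen = substring(sub("^[0-9]*", "", name), 1, 1) == "H",
             stringsAsFactors = FALSE)
}

atoms_df <- function(...) do.call(rbind, list(...))

# minimal residue builders; origin = CA position
residue_gly <- function(resid, origin) {
  o <- origin
  atoms_df(
    atom_row("N", "GLY", resid, o + c(-1.20, 0.80, 0.00)),
    atom_row("CA", "GLY", resid, o),
    atom_row("C", "GLY", resid, o + c(1.30, 0.60, 0.00)),
    atom_row("O", "GLY", resid, o + c(1.40, 1.83, 0.00)),
    atom_row("HA2", "GLY", resid, o + c(-0.35, -0.70, 0.85)),
    atom_row("HA3", "GLY", resid, o + c(-0.35, -0.70, -0.85))
  )
}

residue_ala <- function(resid, origin) {
  o <- origin
  cb <- o + c(0.20, -0.95, -1.15)
  hb <- methyl_h_coords(cb, cb - o)
  atoms_df(
    atom_row("N", "ALA", resid, o + c(-1.20, 0.80, 0.00)),
    atom_row("CA", "ALA", resid, o),
    atom_row("C", "ALA", resid, o + c(1.30, 0.60, 0.00)),
    atom_row("O", "ALA", resid, o + c(1.40, 1.83, 0.00)),
    atom_row("HA", "ALA", resid, o + c(-0.60, -0.45, 0.85)),
    atom_row("CB", "ALA", resid, cb),
    atom_row("HB1", "ALA", resid, hb[1, ]),
    atom_row("HB2", "ALA", resid, hb[2, ]),
    atom_row("HB3", "ALA", resid, hb[3, ])
  )
}

residue_val <- function(resid, origin) {
  o <- origin
  cb <- o + c(0.20, -0.95, -1.15)
  cg1 <- cb + c(1.05, -0.85, -0.45)
  cg2 <- cb + c(-1.25, -0.75, -0.55)
  hg1 <- methyl_h_coords(cg1, cg1 - cb)
  hg2 <- methyl_h_coords(cg2, cg2 - cb, phase = pi / 3)
  atoms_df(
    atom_row("N", "VAL", resid, o + c(-1.20, 0.80, 0.00)),
    atom_row("CA", "VAL", resid, o),
    atom_row("C", "VAL", resid, o + c(1.30, 0.60, 0.00)),
    atom_row("O", "VAL", resid, o + c(1.40, 1.83, 0.00)),
    atom_row("HA", "VAL", resid, o + c(-0.60, -0.45, 0.85)),
    atom_row("CB", "VAL", resid, cb),
    atom_row("HB", "VAL", resid, cb + c(0.15, 0.35, -1.00)),
    atom_row("CG1", "VAL", resid, cg1),
    atom_row("HG11", "VAL", resid, hg1[1, ]),
    atom_row("HG12", "VAL", resid, hg1[2, ]),
    atom_row("HG13", "VAL", resid, hg1[3, ]),
    atom_row("CG2", "VAL", resid, cg2),
    atom_row("HG21", "VAL", resid, hg2[1, ]),
    atom_row("HG22", "VAL", resid, hg2[2, ]),
    atom_row("HG23", "VAL", resid, hg2[3, ])
  )
}

# 4-proton rigid ligand: four sp3 carbons in a zig-zag, one H each,
# centered at `center`
ligand_four_proton <- function(center, resid = 1L) {
  base <- rbind(c(-2.0, 0.0, 0.0), c(-0.7, 0.8, 0.0),
                c(0.7, 0.0, 0.0), c(2.0, 0.8, 0.0))
  rows <- list()
  for (i in 1:4) {
    cpos <- center + base[i, ]
    hpos <- cpos + c(0, -0.55, 0.95)
    rows[[length(rows) + 1L]] <- atom_row(paste0("C", i), "LIG", resid, cpos)
    rows[[length(rows) + 1L]] <- atom_row(paste0("H", i), "LIG", resid, hpos)
  }
  do.call(rbind, rows)
}

# -- independent brute-force ground truth ------------------------------------

brute_distance_table <- function(lig_atoms, sat_atoms) {
  out <- NULL
  for (i in seq_len(nrow(lig_atoms))) {
    for (j in seq_len(nrow(sat_atoms))) {
      dx <- lig_atoms$x[i] - sat_atoms$x[j]
      dy <- lig_atoms$y[i] - sat_atoms$y[j]
      dz <- lig_atoms$z[i] - sat_atoms$z[j]
      out <- rbind(out, data.frame(
        ligand = lig_atoms$atom_name[i],
        saturated = paste0(sat_atoms$residue_id[j], ":", sat_atoms$atom_name[j]),
        r = sqrt(dx * dx + dy * dy + dz * dz)))
    }
  }
  out
}

# expected relative epitope from plain r^-6 sums (exact for the reduced
# matrix at fixed tau_c since sigma = const * r^-6)
brute_expected_rel <- function(dist_tab) {
  ligs <- unique(dist_tab$ligand)
  s <- numeric(length(ligs))
  for (k in seq_along(ligs)) {
    rows <- dist_tab[dist_tab$ligand == ligs[k], ]
    acc <- 0
    for (r in rows$r) acc <- acc + r^-6
    s[k] <- acc
  }
  data.frame(ligand = ligs, rel = 100 * s / max(s),
             stringsAsFactors = FALSE)
}

# -- fixture generators ------------------------------------------------------

#' Generate a deterministic spin-system fixture
#'
#' Templates:
#' \describe{
#'   \item{two_spin}{1 saturated protein proton (GLY HA) + 1 ligand proton
#'     at distance `r` (default 3.0 A). Saturation spec: `"1:HA"`.}
#'   \item{three_spin}{1 saturated protein proton + 2 ligand protons at
#'     `r1`, `r2` (defaults 2.5 and 5.0 A) in orthogonal directions.}
#'   \item{methyl_probe}{one VAL residue + `n_ligand` (default 1) ligand
#'     protons near the CG1 methyl. Saturation: `"methyls"`.}
#'   \item{mini_complex}{ALA-VAL-GLY tripeptide + 4-proton ligand docked
#'     against the VAL methyls (9 methyl protons: ALA 3 + VAL 6).}
#'   \item{random_cloud}{seeded random proton cloud: `n_ligand`, `n_sat`,
#'     `n_unsat` protons with >= 1.6 A separation in a 12 A box.}
#' }
#'
#' @param template Template name.
#' @param dir Directory for the emitted PDB files and sidecar
#'   (default `tempdir()`).
#' @param seed Seed for the random templates (default 1).
#' @param ... Template parameters (`r`, `r1`, `r2`, `n_ligand`, `n_sat`,
#'   `n_unsat`).
#' @return List: `system` (a prepared, saturated `spin_system`),
#'   `protein_pdb`, `ligand_pdb` (paths), `saturation` (spec used),
#'   `ground_truth` (distance table + expected relative epitope from
#'   independent brute-force arithmetic), `seed`.
#' @export
make_spin_fixture <- function(template = c("two_spin", "three_spin",
                                           "methyl_probe", "mini_complex",
                                           "random_cloud"),
                              dir = tempdir(), seed = 1L, ...) {
  template <- match.arg(template)
  args <- list(...)
  getarg <- function(nm, default) if (!is.null(args[[nm]])) args[[nm]] else default

  if (template == "two_spin") {
    r <- getarg("r", 3.0)
    prot <- atoms_df(
      atom_row("CA", "GLY", 1L, c(0, 0, -1.09)),
      atom_row("HA", "GLY", 1L, c(0, 0, 0))
    )
    lig <- atoms_df(
      atom_row("C1", "LIG", 1L, c(r, 0, 1.09)),
      atom_row("H1", "LIG", 1L, c(r, 0, 0))
    )
    saturation <- "1:HA"
  } else if (template == "three_spin") {
    r1 <- getarg("r1", 2.5); r2 <- getarg("r2", 5.0)
    prot <- atoms_df(
      atom_row("CA", "GLY", 1L, c(0, 0, -1.09)),
      atom_row("HA", "GLY", 1L, c(0, 0, 0))
    )
    lig <- atoms_df(
      atom_row("C1", "LIG", 1L, c(r1, 0, 1.09)),
      atom_row("H1", "LIG", 1L, c(r1, 0, 0)),
      atom_row("C2", "LIG", 1L, c(0, r2, 1.09)),
      atom_row("H2", "LIG", 1L, c(0, r2, 0))
    )
    saturation <- "1:HA"
  } else if (template == "methyl_probe") {
    n_ligand <- getarg("n_ligand", 1L)
    prot <- residue_val(1L, c(0, 0, 0))
    cg1 <- unlist(prot[prot$atom_name == "CG1", c("x", "y", "z")])
    rows <- list()
    for (i in seq_len(n_ligand)) {
      cpos <- cg1 + c(3.5, -1.5 * (i - 1), 1.0 + 0.8 * (i - 1))
      rows[[2 * i - 1]] <- atom_row(paste0("C", i), "LIG", 1L, cpos)
      rows[[2 * i]] <- atom_row(paste0("H", i), "LIG", 1L,
                                cpos + c(-0.85, 0, -0.68))
    }
    lig <- do.call(rbind, rows)
    saturation <- "methyls"
  } else if (template == "mini_complex") {
    prot <- rbind(residue_ala(1L, c(0, 0, 0)),
                  residue_val(2L, c(3.8, 0, 0)),
                  residue_gly(3L, c(7.6, 0, 0)))
    # dock the ligand under the VAL side chain
    lig <- ligand_four_proton(c(3.9, -4.6, -2.6), resid = 1L)
    saturation <- "methyls"
  } else { # random_cloud
    n_ligand <- getarg("n_ligand", 3L)
    n_sat <- getarg("n_sat", 3L)
    n_unsat <- getarg("n_unsat", 2L)
    n <- n_ligand + n_sat + n_unsat
    pts <- matrix(NA_real_, n, 3)
    set.seed(seed)
    placed <- 0L
    while (placed < n) {
      cand <- stats::runif(3, -6, 6)
      ok <- TRUE
      if (placed > 0L) {
        for (j in seq_len(placed)) {
          if (sqrt(sum((pts[j, ] - cand)^2)) < 1.6) { ok <- FALSE; break }
        }
      }
      if (ok) { placed <- placed + 1L; pts[placed, ] <- cand }
    }
    lig_rows <- lapply(seq_len(n_ligand), function(i)
      atom_row(paste0("H", i), "LIG", 1L, pts[i, ]))
    lig_c <- atom_row("C1", "LIG", 1L, pts[1, ] + c(0, 0, 1.09))
    lig <- do.call(rbind, c(lig_rows, list(lig_c)))
    prot_rows <- lapply(seq_len(n_sat + n_unsat), function(i)
      atom_row("HA", "GLY", i, pts[n_ligand + i, ]))
    prot_c <- atom_row("CA", "GLY", 1L, pts[n_ligand + 1, ] + c(0, 0, 1.09))
    prot <- do.call(rbind, c(prot_rows, list(prot_c)))
    saturation <- paste0(seq_len(n_sat), ":HA")
  }

  protein_pdb <- file.path(dir, paste0("fixture_", template, "_protein.pdb"))
  ligand_pdb <- file.path(dir, paste0("fixture_", template, "_ligand.pdb"))
  write_pdb_frames(prot, as.matrix(prot[, c("x", "y", "z")]), protein_pdb)
  write_pdb_frames(lig, as.matrix(lig[, c("x", "y", "z")]), ligand_pdb)

  system <- build_spin_system(prot, lig, paste0("fixture:", template))
  system <- select_saturated(system, saturation)

  satp <- system$protons[system$protons$group == "SATURATED_PROTEIN", ]
  ligp <- system$protons[system$protons$group == "LIGAND", ]
  dist_tab <- brute_distance_table(ligp, satp)
  gt <- list(distances = dist_tab,
             expected_rel = brute_expected_rel(dist_tab))
  sidecar <- file.path(dir, paste0("fixture_", template, "_truth.tsv"))
  utils::write.table(cbind(dist_tab, seed = seed), sidecar, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  list(system = system, protein_pdb = protein_pdb, ligand_pdb = ligand_pdb,
       saturation = saturation, ground_truth = gt, sidecar = sidecar,
       seed = seed)
}

#' Generate a synthetic mono-exponential build-up curve
#'
#' `STD(t) = STDmax (1 - exp(-ksat t))` plus optional Gaussian noise.
#'
#' @param stdmax Asymptotic STD factor (> 0).
#' @param ksat Saturation rate constant, s^-1 (> 0).
#' @param t_grid Saturation times (s).
#' @param noise_sd Gaussian noise standard deviation (absolute STD units).
#' @param seed Seed used when `noise_sd > 0`.
#' @return data.frame with `t_sat`, `std`.
#' @export
make_buildup_fixture <- function(stdmax, ksat, t_grid, noise_sd = 0,
                                 seed = 1L) {
  stopifnot(stdmax > 0, ksat > 0, noise_sd >= 0)
  std <- stdmax * (1 - exp(-ksat * t_grid))
  if (noise_sd > 0) {
    set.seed(seed)
    std <- std + stats::rnorm(length(t_grid), sd = noise_sd)
  }
  data.frame(t_sat = t_grid, std = std)
}

#' Generate a scripted trajectory of the miniature complex
#'
#' The mini_complex fixture replicated over `n_frames` frames; frames in
#' `dissociated_frames` have the ligand rigidly translated `translate` A
#' away (+x); frames in `reoriented_frames` have it rotated by
#' `reorient_deg` about the z-axis through its centroid. Protein
#' coordinates never move, so the brute-force ligand RMSD in the sidecar
#' needs no superposition.
#'
#' @param n_frames Number of frames (default 10).
#' @param dissociated_frames Frame indices translated away (default 4:6).
#' @param reoriented_frames Frame indices rotated in place (default none).
#' @param translate Dissociation translation, Angstrom (default 50).
#' @param reorient_deg Rotation angle, degrees (default 25).
#' @param dt_ns Frame spacing, ns (default 0.1).
#' @param dir Directory for the prmtop/mdcrd/PDB files.
#' @return List: `traj` (a [trajectory()]), `topology`, `mdcrd`, `pdb`
#'   (paths), `ligand_select` (`"LIG"`), `sidecar` (list with
#'   `dissociated`, `ligand_rmsd` per frame by brute force).
#' @export
make_trajectory_fixture <- function(n_frames = 10L, dissociated_frames = 4:6,
                                    reoriented_frames = integer(0),
                                    translate = 50, reorient_deg = 25,
                                    dt_ns = 0.1, dir = tempdir()) {
  prot <- rbind(residue_ala(1L, c(0, 0, 0)),
                residue_val(2L, c(3.8, 0, 0)),
                residue_gly(3L, c(7.6, 0, 0)))
  lig <- ligand_four_proton(c(3.9, -4.6, -2.6), resid = 4L)
  atoms <- rbind(prot, lig)
  natom <- nrow(atoms)
  lig_idx <- which(atoms$residue_name == "LIG")
  base <- as.matrix(atoms[, c("x", "y", "z")])
  coords <- array(rep(base, n_frames), c(natom, 3L, n_frames))
  rmsd_truth <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- base
    if (f %in% reoriented_frames) {
      th <- reorient_deg * pi / 180
      Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
      cen <- colMeans(xyz[lig_idx, , drop = FALSE])
      xyz[lig_idx, ] <- sweep(sweep(xyz[lig_idx, , drop = FALSE], 2, cen) %*%
                                t(Rz), 2, cen, "+")
    }
    if (f %in% dissociated_frames) {
      xyz[lig_idx, 1] <- xyz[lig_idx, 1] + translate
    }
    coords[, , f] <- xyz
    # brute-force heavy-atom ligand RMSD vs frame geometry of the base
    hv <- lig_idx[!atoms$is_hydrogen[lig_idx]]
    acc <- 0
    for (i in hv) acc <- acc + sum((xyz[i, ] - base[i, ])^2)
    rmsd_truth[f] <- sqrt(acc / length(hv))
  }
  traj <- trajectory(atoms, coords, dt_ns = dt_ns, source = "fixture:mini_traj")

  topology <- file.path(dir, "fixture_mini.prmtop")
  mdcrd <- file.path(dir, "fixture_mini.mdcrd")
  pdb <- file.path(dir, "fixture_mini_traj.pdb")
  write_prmtop(atoms, topology)
  write_mdcrd(coords, mdcrd)
  write_pdb_frames(atoms, coords, pdb)

  list(traj = traj, topology = topology, mdcrd = mdcrd, pdb = pdb,
       ligand_select = "LIG",
       sidecar = list(dissociated = as.integer(dissociated_frames),
                      reoriented = as.integer(reoriented_frames),
                      ligand_rmsd = rmsd_truth))
}

#' Write a minimal AMBER-dialect ASCII topology
#'
#' Emits `POINTERS`, `ATOM_NAME`, `RESIDUE_LABEL` and `RESIDUE_POINTER` --
#' the sections [read_prmtop()] consumes.
#'
#' @param atoms Atom table ordered by residue.
#' @param path Output path.
#' @export
write_prmtop <- function(atoms, path) {
  natom <- nrow(atoms)
  res_change <- c(TRUE, atoms$residue_id[-1] != atoms$residue_id[-natom])
  res_ptr <- which(res_change)
  res_lab <- atoms$residue_name[res_ptr]
  pointers <- integer(31)
  pointers[1] <- natom
  pointers[12] <- length(res_lab)
  fmt10i8 <- function(x) {
    vapply(split(x, ceiling(seq_along(x) / 10)),
           function(chunk) paste(sprintf("%8d", chunk), collapse = ""),
           character(1))
  }
  fmt20a4 <- function(x) {
    vapply(split(x, ceiling(seq_along(x) / 20)),
           function(chunk) paste(sprintf("%-4s", chunk), collapse = ""),
           character(1))
  }
  ln <- c(
    "%VERSION  VERSION_STAMP = V0001.000",
    "%FLAG TITLE", "%FORMAT(20a4)", "synthetic fixture topology",
    "%FLAG POINTERS", "%FORMAT(10I8)", fmt10i8(pointers),
    "%FLAG ATOM_NAME", "%FORMAT(20a4)", fmt20a4(atoms$atom_name),
    "%FLAG RESIDUE_LABEL", "%FORMAT(20a4)", fmt20a4(res_lab),
    "%FLAG RESIDUE_POINTER", "%FORMAT(10I8)", fmt10i8(res_ptr)
  )
  writeLines(ln, path)
  invisible(path)
}

#' Write an AMBER ASCII coordinate trajectory (mdcrd, 10F8.3)
#'
#' @param coords `natom x 3 x nframes` array.
#' @param path Output path.
#' @export
write_mdcrd <- function(coords, path) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  nf <- dim(coords)[3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("synthetic fixture trajectory", con)
  for (f in seq_len(nf)) {
    stream <- as.numeric(t(coords[, , f]))
    lines <- vapply(split(stream, ceiling(seq_along(stream) / 10)),
                    function(chunk) paste(sprintf("%8.3f", chunk),
                                          collapse = ""),
                    character(1))
    writeLines(lines, con)
  }
  invisible(path)
}
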