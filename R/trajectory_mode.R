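# Frame-by-frame reduced-matrix scoring of MD trajectories.
#
# A trajectory is a light container: an atom table (names, residues) plus a
# natoms x 3 x nframes coordinate array in Angstrom. Readers cover
# AMBER-dialect ASCII inputs (prmtop + mdcrd) and multi-model PDB.
# Coordinates are used as stored: frames must be pre-imaged/unwrapped.

#' Construct a trajectory container
#'
#' @param atoms data.frame with `atom_name`, `residue_name`, `residue_id`
#'   (and optionally `element`, `is_hydrogen`; perceived from names if
#'   absent).
#' @param coords numeric array `natoms x 3 x nframes` (Angstrom).
#' @param time_ns per-frame times (default `(frame - 1) * dt_ns`).
#' @param dt_ns frame spacing used when `time_ns` is absent.
#' @param source label for provenance.
#' @export
trajectory <- function(atoms, coords, time_ns = NULL, dt_ns = 1,
                       source = "in-memory") {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[1] == nrow(atoms))
  nf <- dim(coords)[3]
  if (is.null(time_ns)) time_ns <- (seq_len(nf) - 1) * dt_ns
  stopifnot(length(time_ns) == nf, !is.unsorted(time_ns, strictly = nf > 1))
  if (is.null(atoms$element)) {
    nm <- sub("^[0-9]*", "", normalize_atom_name(atoms$atom_name))
    atoms$element <- substring(nm, 1, 1)
  }
  if (is.null(atoms$is_hydrogen)) atoms$is_hydrogen <- atoms$element == "H"
  structure(list(atoms = atoms, coords = coords, time_ns = time_ns,
                 source = source),
            class = "std_trajectory")
}

#' @export
print.std_trajectory <- function(x, ...) {
  cat(sprintf("<std_trajectory> %d atoms, %d frames (%s)\n",
              nrow(x$atoms), dim(x$coords)[3], x$source))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

#' Read an AMBER-dialect ASCII topology (prmtop)
#'
#' Parses the `POINTERS`, `ATOM_NAME`, `RESIDUE_LABEL` and
#' `RESIDUE_POINTER` flags; everything else is ignored.
#'
#' @param path prmtop file path.
#' @return data.frame with `atom_name`, `residue_name`, `residue_id`.
#' @export
read_prmtop <- function(path) {
  ln <- readLines(path, warn = FALSE)
  flag_at <- grep("^%FLAG", ln)
  if (!length(flag_at)) stop("not a prmtop file (no %FLAG records): ", path)
  section <- function(name) {
    i <- flag_at[trimws(sub("^%FLAG", "", ln[flag_at])) == name]
    if (!length(i)) return(NULL)
    j <- flag_at[flag_at > i[1]]
    end <- if (length(j)) j[1] - 1L else length(ln)
    body <- ln[(i[1] + 1L):end]
    body[!grepl("^%", body)]
  }
  fixed4 <- function(body) {
    out <- unlist(lapply(body, function(l) {
      starts <- seq(1, max(nchar(l), 1), by = 4)
      trimws(substring(l, starts, starts + 3))
    }))
    out[nzchar(out)]
  }
  pointers <- as.integer(unlist(strsplit(trimws(
    paste(section("POINTERS"), collapse = " ")), "[[:space:]]+")))
  natom <- pointers[1]
  names <- normalize_atom_name(fixed4(section("ATOM_NAME")))
  if (length(names) != natom) {
    stop(sprintf("prmtop ATOM_NAME count (%d) disagrees with POINTERS NATOM (%d)",
                 length(names), natom))
  }
  res_lab <- fixed4(section("RESIDUE_LABEL"))
  res_ptr <- as.integer(unlist(strsplit(trimws(
    paste(section("RESIDUE_POINTER"), collapse = " ")), "[[:space:]]+")))
  if (length(res_lab) != length(res_ptr)) {
    stop("prmtop RESIDUE_LABEL / RESIDUE_POINTER length mismatch")
  }
  bounds <- c(res_ptr, natom + 1L)
  resid <- rep(seq_along(res_lab), diff(bounds))
  data.frame(atom_name = names,
             residue_name = res_lab[resid],
             residue_id = resid,
             stringsAsFactors = FALSE)
}

#' Read an AMBER ASCII coordinate trajectory (mdcrd)
#'
#' Title line followed by a 10F8.3 stream of x,y,z triplets per frame;
#' optional box line per frame.
#'
#' @param path mdcrd file path.
#' @param natom Atom count (from the topology).
#' @param has_box If `TRUE`, three box lengths trail each frame.
#' @return numeric array `natom x 3 x nframes`.
#' @export
read_mdcrd <- function(path, natom, has_box = FALSE) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) < 2L) stop("mdcrd file too short: ", path)
  nums <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(ln[-1]), "[[:space:]]+"))))
  nums <- nums[!is.na(nums)]
  per_frame <- 3L * natom + if (has_box) 3L else 0L
  if (length(nums) %% per_frame != 0L) {
    stop(sprintf(
      "mdcrd stream of %d numbers is not a whole number of frames for %d atoms%s",
      length(nums), natom, if (has_box) " (+box)" else ""))
  }
  nf <- length(nums) %/% per_frame
  coords <- array(NA_real_, c(natom, 3L, nf))
  for (f in seq_len(nf)) {
    off <- (f - 1L) * per_frame
    xyz <- nums[off + seq_len(3L * natom)]
    coords[, , f] <- matrix(xyz, ncol = 3L, byrow = TRUE)
  }
  coords
}

#' Read a trajectory from topology + coordinates, or multi-model PDB
#'
#' `trajectory_file` ending in `.pdb` is read as multi-model PDB (topology
#' optional, used for an atom-count cross-check); otherwise it is treated
#' as ASCII mdcrd and `topology` (prmtop) is required.
#'
#' @param trajectory_file Coordinate file path.
#' @param topology prmtop path (or `NULL` for PDB input).
#' @param dt_ns Frame spacing in ns when the format has no time metadata.
#' @param has_box Passed to [read_mdcrd()].
#' @return A [trajectory()] object.
#' @export
read_trajectory <- function(trajectory_file, topology = NULL, dt_ns = 1,
                            has_box = FALSE) {
  if (grepl("\\.pdb$", trajectory_file, ignore.case = TRUE)) {
    models <- read_pdb(trajectory_file)
    n <- nrow(models[[1]])
    if (!all(vapply(models, nrow, integer(1)) == n)) {
      stop("multi-model PDB has varying atom counts across MODEL blocks")
    }
    if (!is.null(topology)) {
      top <- read_prmtop(topology)
      if (nrow(top) != n) {
        stop(sprintf("topology has %d atoms but trajectory frames have %d",
                     nrow(top), n))
      }
    }
    coords <- array(NA_real_, c(n, 3L, length(models)))
    for (f in seq_along(models)) {
      coords[, , f] <- as.matrix(models[[f]][, c("x", "y", "z")])
    }
    trajectory(models[[1]][, c("atom_name", "residue_name", "residue_id",
                               "element", "is_hydrogen")],
               coords, dt_ns = dt_ns, source = trajectory_file)
  } else {
    if (is.null(topology)) stop("mdcrd input requires a prmtop topology")
    atoms <- read_prmtop(topology)
    coords <- read_mdcrd(trajectory_file, nrow(atoms), has_box = has_box)
    trajectory(atoms, coords, dt_ns = dt_ns,
               source = paste(topology, "+", trajectory_file))
  }
}

# Split one frame into protein/ligand atom tables and build a spin system.
frame_spin_system <- function(traj, frame, ligand_select) {
  at <- traj$atoms
  lig_mask <- ligand_mask(at, ligand_select)
  xyz <- traj$coords[, , frame]
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  build_spin_system(
    protein_atoms = at[!lig_mask, , drop = FALSE],
    ligand_atoms = at[lig_mask, , drop = FALSE],
    source_label = sprintf("%s [frame %d]", traj$source, frame)
  )
}

ligand_mask <- function(atoms, ligand_select) {
  if (is.character(ligand_select)) {
    mask <- atoms$residue_name %in% ligand_select
  } else if (is.numeric(ligand_select)) {
    mask <- seq_len(nrow(atoms)) %in% as.integer(ligand_select)
  } else {
    stop("ligand_select must be residue name(s) or an atom index vector")
  }
  if (!any(mask)) {
    stop("ligand selection matches no atoms (selection: ",
         paste(ligand_select, collapse = ","), ")")
  }
  if (all(mask)) stop("ligand selection matches every atom")
  mask
}

#' Is a frame's spin system dissociated?
#'
#' A frame is dissociated when zero saturated protein protons survive the
#' cutoff pruning -- exactly the condition under which STD0 is undefined.
#'
#' @param system A saturated `spin_system` for the frame (pre-pruning).
#' @param cutoff Cutoff distance, Angstrom.
#' @export
detect_dissociation <- function(system, cutoff) {
  pruned <- apply_cutoff(system, cutoff)
  !any(pruned$protons$group == "SATURATED_PROTEIN")
}

#' Score a trajectory frame-by-frame
#'
#' Per kept frame: build the spin system, tag saturated protons, prune by
#' cutoff, compute the reduced-matrix epitope and its NOE R-factor against
#' the experimental epitope. Frames with no surviving saturated proton are
#' flagged dissociated (no R-factor).
#'
#' @param traj A [trajectory()] object.
#' @param exp_epitope Experimental [epitope()].
#' @param params A [relaxation_params()] object (supplies the cutoff).
#' @param binding A [solve_binding()] result.
#' @param ligand_select Ligand residue name(s) or atom index vector.
#' @param saturation Saturation spec for [select_saturated()].
#' @param stride Keep every `stride`-th frame (starting at frame 1).
#' @param keys Optional epitope key map (see [aggregate_by_key()]).
#' @param keep_epitopes If `TRUE`, attach each frame's calculated epitope.
#' @return A `trajectory_score`: data.frame `frames` with `frame`,
#'   `time_ns`, `dissociated`, `r_factor` (NA when dissociated),
#'   `n_matched`; plus attributes used by [extract_frames()].
#' @export
score_trajectory <- function(traj, exp_epitope, params, binding,
                             ligand_select, saturation = "methyls",
                             stride = 1L, keys = NULL,
                             keep_epitopes = FALSE) {
  stopifnot(inherits(traj, "std_trajectory"), stride >= 1L)
  kept <- seq(1L, n_frames(traj), by = as.integer(stride))
  res <- data.frame(frame = kept, time_ns = traj$time_ns[kept],
                    dissociated = FALSE, r_factor = NA_real_,
                    n_matched = NA_integer_)
  epitopes <- if (keep_epitopes) vector("list", length(kept)) else NULL
  for (i in seq_along(kept)) {
    sys <- frame_spin_system(traj, kept[i], ligand_select)
    sys <- select_saturated(sys, saturation)
    sys <- apply_cutoff(sys, params$cutoff)
    if (!sys$scorable) {
      res$dissociated[i] <- TRUE
      next
    }
    ep <- calculated_epitope(sys, params, binding, keys = keys)
    sc <- suppressWarnings(noe_r_factor(exp_epitope, ep))
    res$r_factor[i] <- sc$r_factor
    res$n_matched[i] <- sc$n_matched
    if (keep_epitopes) epitopes[[i]] <- ep
  }
  structure(res,
            epitopes = epitopes,
            traj_source = traj$source,
            class = c("trajectory_score", "data.frame"))
}

#' Extract well-scoring frames
#'
#' Frames with an R-factor strictly below `threshold` (dissociated frames
#' never qualify). If `traj` and `path` are given, the frames are written
#' as a multi-model PDB.
#'
#' @param score A `trajectory_score`.
#' @param threshold R-factor threshold (default 0.3).
#' @param traj The scored [trajectory()] (needed to write coordinates).
#' @param path Optional output PDB path.
#' @return Integer vector of qualifying frame indices (invisible warning
#'   when empty).
#' @export
extract_frames <- function(score, threshold = 0.3, traj = NULL, path = NULL) {
  stopifnot(inherits(score, "trajectory_score"))
  sel <- score$frame[!score$dissociated & !is.na(score$r_factor) &
                       score$r_factor < threshold]
  if (!length(sel)) {
    warning(sprintf("no frames with R-factor below %.3g", threshold))
    return(invisible(integer(0)))
  }
  if (!is.null(traj) && !is.null(path)) {
    write_pdb_frames(traj$atoms, traj$coords[, , sel, drop = FALSE], path)
  }
  sel
}

#' Ligand heavy-atom RMSD after binding-site superposition
#'
#' The frame is superposed onto the reference using the heavy atoms of
#' protein residues having any heavy atom within `site_cutoff` of a ligand
#' heavy atom in the reference (Kabsch fit), then the RMSD over ligand
#' heavy atoms is reported.
#'
#' @param traj A [trajectory()] object.
#' @param frame Frame index to evaluate.
#' @param reference Reference frame index (default 1) or an
#'   `natoms x 3` coordinate matrix.
#' @param ligand_select Ligand selection as in [score_trajectory()].
#' @param site_cutoff Binding-site shell radius, Angstrom (default 6).
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(traj, frame, reference = 1L, ligand_select,
                        site_cutoff = 6) {
  at <- traj$atoms
  lig <- ligand_mask(at, ligand_select)
  heavy <- !at$is_hydrogen
  ref_xyz <- if (is.matrix(reference)) reference else traj$coords[, , reference]
  mob_xyz <- traj$coords[, , frame]
  lig_h <- which(lig & heavy)
  prot_h <- which(!lig & heavy)
  if (!length(lig_h)) stop("no ligand heavy atoms in selection")
  # binding-site shell from the reference geometry
  d <- pairwise_distances(ref_xyz[prot_h, , drop = FALSE],
                          ref_xyz[lig_h, , drop = FALSE])
  near <- prot_h[apply(d, 1, min) <= site_cutoff]
  site_res <- unique(at$residue_id[near])
  site <- which(!lig & heavy & at$residue_id %in% site_res)
  if (length(site) < 3L) stop("binding-site selection has fewer than 3 atoms")
  fit <- kabsch(mob_xyz[site, , drop = FALSE], ref_xyz[site, , drop = FALSE])
  moved <- sweep(mob_xyz[lig_h, , drop = FALSE], 2, fit$center_mobile) %*%
    fit$rotation
  moved <- sweep(moved, 2, fit$center_ref, "+")
  sqrt(mean(rowSums((moved - ref_xyz[lig_h, , drop = FALSE])^2)))
}

# Kabsch superposition of mobile onto ref (both n x 3)
kabsch <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref))
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm)
  B <- sweep(ref, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  list(rotation = sv$u %*% D %*% t(sv$v), center_mobile = cm, center_ref = cr)
}

#' Write atoms/coordinates as (multi-model) PDB text
#'
#' @param atoms Atom table (`atom_name`, `residue_name`, `residue_id`,
#'   optional `element`).
#' @param coords `natoms x 3` matrix or `natoms x 3 x nframes` array.
#' @param path Output path.
#' @export
write_pdb_frames <- function(atoms, coords, path) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  nf <- dim(coords)[3]
  elem <- if (!is.null(atoms$element)) atoms$element else
    substring(sub("^[0-9]*", "", atoms$atom_name), 1, 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    for (i in seq_len(nrow(atoms))) {
      nm <- atoms$atom_name[i]
      nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      writeLines(sprintf(
        "ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, nm_fmt, atoms$residue_name[i], atoms$residue_id[i],
        coords[i, 1, f], coords[i, 2, f], coords[i, 3, f], elem[i]), con)
    }
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
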