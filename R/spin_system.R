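# Proton-level representation of a protein-ligand complex.
#
# A spin system partitions all hydrogens of a two-file (protein + ligand)
# complex into three groups: LIGAND (bound ligand protons), SATURATED_PROTEIN
# (protein protons directly hit by the on-resonance saturation train) and
# UNSATURATED_PROTEIN (all remaining protein protons). Heavy atoms are kept
# only as metadata: they never become spins, but they identify methyl groups
# and exchangeable (N/O/S-attached) protons.

PROTON_GROUPS <- c("LIGAND", "SATURATED_PROTEIN", "UNSATURATED_PROTEIN")

# Methyl hydrogens by residue, standard AMBER/PDBv3 names. THR HG1 is a
# hydroxyl proton and deliberately absent: only CH3 protons count.
METHYL_HYDROGENS <- list(
  ALA = list(HB  = c("HB1", "HB2", "HB3")),
  VAL = list(HG1 = c("HG11", "HG12", "HG13"),
             HG2 = c("HG21", "HG22", "HG23")),
  LEU = list(HD1 = c("HD11", "HD12", "HD13"),
             HD2 = c("HD21", "HD22", "HD23")),
  ILE = list(HG2 = c("HG21", "HG22", "HG23"),
             HD1 = c("HD11", "HD12", "HD13")),
  THR = list(HG2 = c("HG21", "HG22", "HG23")),
  MET = list(HE  = c("HE1", "HE2", "HE3")),
  ACE = list(HH3 = c("HH31", "HH32", "HH33")),
  NME = list(HH3 = c("HH31", "HH32", "HH33"))
)

# PDBv2 hydrogen names put the branch digit first ("1HB1" -> "HB11",
# "2HG2" -> "HG22"); rotate it to the end so the dictionary applies.
normalize_atom_name <- function(name) {
  name <- trimws(name)
  lead <- grepl("^[0-9]", name) & grepl("^[0-9][A-Za-z]", name)
  name[lead] <- paste0(substring(name[lead], 2), substring(name[lead], 1, 1))
  name
}

#' Parse a PDB file into per-model atom tables
#'
#' Minimal column-oriented reader for ATOM/HETATM/MODEL/ENDMDL records
#' (fixed columns per PDB v3: name 13-16, resName 18-20, resSeq 23-26,
#' x/y/z 31-54, element 77-78). Residue ids are taken as printed (1-based).
#'
#' @param path Path to a PDB file, or a character vector of PDB lines.
#' @return List of models; each model is a data.frame with columns
#'   `atom_name`, `residue_name`, `residue_id`, `x`, `y`, `z`, `element`,
#'   `is_hydrogen`.
#' @export
read_pdb <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else if (length(path) == 1L && grepl("\n", path)) {
    strsplit(path, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(path)
  }
  rec <- substring(lines, 1, 6)
  models <- list()
  current <- integer(0)
  in_model <- FALSE
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  flush <- function(models, current) {
    if (length(current)) models[[length(models) + 1L]] <- current
    models
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      models <- flush(models, current); current <- integer(0); in_model <- TRUE
    } else if (r == "ENDMDL") {
      models <- flush(models, current); current <- integer(0); in_model <- FALSE
    } else if (r == "ATOM  " || r == "HETATM") {
      current <- c(current, i)
    }
  }
  models <- flush(models, current)
  if (!length(models)) stop("no ATOM/HETATM records found in PDB input")

  parse_block <- function(idx) {
    ln <- lines[idx]
    xs <- suppressWarnings(as.numeric(substring(ln, 31, 38)))
    ys <- suppressWarnings(as.numeric(substring(ln, 39, 46)))
    zs <- suppressWarnings(as.numeric(substring(ln, 47, 54)))
    bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(zs))
    if (length(bad)) {
      stop(sprintf("unparseable coordinate field at line %d: %s",
                   idx[bad[1]], ln[bad[1]]))
    }
    resid <- suppressWarnings(as.integer(substring(ln, 23, 26)))
    if (anyNA(resid)) {
      bad <- idx[which(is.na(resid))[1]]
      stop(sprintf("unparseable residue id at line %d", bad))
    }
    name <- normalize_atom_name(substring(ln, 13, 16))
    elem <- toupper(trimws(substring(ln, 77, 78)))
    # fall back to name-based element perception when column 77-78 is blank
    guess <- sub("^[0-9]*", "", name)
    elem_guess <- substring(guess, 1, 1)
    two_letter <- c("CL", "BR", "NA", "MG", "ZN", "FE", "CA", "MN", "SE")
    g2 <- toupper(substring(guess, 1, 2))
    elem_guess[g2 %in% two_letter & nchar(guess) >= 2] <-
      g2[g2 %in% two_letter & nchar(guess) >= 2]
    elem[elem == ""] <- elem_guess[elem == ""]
    data.frame(
      atom_name = name,
      residue_name = trimws(substring(ln, 18, 20)),
      residue_id = resid,
      x = xs, y = ys, z = zs,
      element = elem,
      is_hydrogen = elem == "H",
      stringsAsFactors = FALSE
    )
  }
  lapply(models, parse_block)
}

methyl_ids <- function(atoms) {
  ids <- rep(NA_character_, nrow(atoms))
  for (res in names(METHYL_HYDROGENS)) {
    groups <- METHYL_HYDROGENS[[res]]
    for (stem in names(groups)) {
      hit <- atoms$residue_name == res & atoms$atom_name %in% groups[[stem]]
      ids[hit] <- paste0(atoms$residue_id[hit], ":", res, ":", stem)
    }
  }
  ids
}

# A proton is exchangeable when its nearest heavy atom (the one it is bonded
# to, within 1.25 A) is N, O or S.
flag_exchangeable <- function(protons, heavy) {
  if (!nrow(protons)) return(logical(0))
  if (!nrow(heavy)) return(rep(FALSE, nrow(protons)))
  hxyz <- as.matrix(heavy[, c("x", "y", "z")])
  vapply(seq_len(nrow(protons)), function(i) {
    d2 <- (hxyz[, 1] - protons$x[i])^2 + (hxyz[, 2] - protons$y[i])^2 +
      (hxyz[, 3] - protons$z[i])^2
    j <- which.min(d2)
    d2[j] <= 1.25^2 && heavy$element[j] %in% c("N", "O", "S")
  }, logical(1))
}

new_spin_system <- function(protons, heavy, source_label) {
  stopifnot(all(protons$group %in% PROTON_GROUPS))
  scorable <- any(protons$group == "LIGAND") &&
    any(protons$group == "SATURATED_PROTEIN")
  structure(
    list(protons = protons, heavy = heavy,
         source_label = source_label, scorable = scorable),
    class = "spin_system"
  )
}

#' @export
print.spin_system <- function(x, ...) {
  tab <- table(factor(x$protons$group, levels = PROTON_GROUPS))
  cat("<spin_system> ", x$source_label, "\n", sep = "")
  cat(sprintf("  protons: %d ligand, %d saturated, %d unsaturated protein\n",
              tab[["LIGAND"]], tab[["SATURATED_PROTEIN"]],
              tab[["UNSATURATED_PROTEIN"]]))
  cat(sprintf("  heavy atoms (metadata): %d | scorable: %s\n",
              nrow(x$heavy), x$scorable))
  invisible(x)
}

#' Build a spin system from protein and ligand PDB files
#'
#' All hydrogens of both files become spins. Ligand protons are every
#' hydrogen of the ligand file (two-file input makes ligand identity
#' explicit; no HETATM heuristics); protein protons start as
#' UNSATURATED_PROTEIN until [select_saturated()] retags them. Heavy atoms
#' are retained as metadata only, for methyl identification and
#' exchangeable-proton perception. No hydrogens are ever added: structures
#' must be protonated upstream.
#'
#' Ligand protons get a default `epitope_key` equal to their atom name;
#' exchangeable ligand protons (OH/NH) keep an `NA` key so they are spins
#' but are excluded from epitope comparison unless a key is set explicitly.
#'
#' @param protein_pdb Path (or text) of the protein PDB.
#' @param ligand_pdb Path (or text) of the ligand PDB (possibly multi-MODEL).
#' @param model_index 1-based MODEL index into the ligand file.
#' @param protein_model_index 1-based MODEL index into the protein file.
#' @return A `spin_system` object.
#' @export
parse_complex <- function(protein_pdb, ligand_pdb, model_index = 1L,
                          protein_model_index = 1L) {
  pmodels <- read_pdb(protein_pdb)
  lmodels <- read_pdb(ligand_pdb)
  if (protein_model_index > length(pmodels)) {
    stop(sprintf("protein model_index %d out of range (%d models)",
                 protein_model_index, length(pmodels)))
  }
  if (model_index > length(lmodels)) {
    stop(sprintf("ligand model_index %d out of range (%d models)",
                 model_index, length(lmodels)))
  }
  prot <- pmodels[[protein_model_index]]
  lig <- lmodels[[model_index]]
  if (!any(prot$is_hydrogen)) {
    stop("protein file contains no hydrogen atoms; protonate the structure ",
         "upstream (no implicit hydrogen building is performed)")
  }
  if (!any(lig$is_hydrogen)) {
    stop("ligand file contains no hydrogen atoms; protonate the structure ",
         "upstream (no implicit hydrogen building is performed)")
  }
  build_spin_system(
    protein_atoms = prot, ligand_atoms = lig,
    source_label = sprintf("protein[model %d] + ligand[model %d]",
                           protein_model_index, model_index)
  )
}

# Shared constructor used by both the PDB path and trajectory frames.
build_spin_system <- function(protein_atoms, ligand_atoms, source_label) {
  pH <- protein_atoms[protein_atoms$is_hydrogen, , drop = FALSE]
  lH <- ligand_atoms[ligand_atoms$is_hydrogen, , drop = FALSE]
  pX <- protein_atoms[!protein_atoms$is_hydrogen, , drop = FALSE]
  lX <- ligand_atoms[!ligand_atoms$is_hydrogen, , drop = FALSE]

  lig_exch <- flag_exchangeable(lH, lX)
  protons <- rbind(
    data.frame(
      atom_name = lH$atom_name, residue_name = lH$residue_name,
      residue_id = lH$residue_id, x = lH$x, y = lH$y, z = lH$z,
      group = "LIGAND",
      methyl_id = NA_character_,
      epitope_key = ifelse(lig_exch, NA_character_, lH$atom_name),
      exchangeable = lig_exch,
      stringsAsFactors = FALSE
    ),
    data.frame(
      atom_name = pH$atom_name, residue_name = pH$residue_name,
      residue_id = pH$residue_id, x = pH$x, y = pH$y, z = pH$z,
      group = "UNSATURATED_PROTEIN",
      methyl_id = methyl_ids(pH),
      epitope_key = NA_character_,
      exchangeable = flag_exchangeable(pH, pX),
      stringsAsFactors = FALSE
    )
  )
  rownames(protons) <- NULL
  heavy_part <- function(df, label) {
    df <- df[, c("atom_name", "residue_name", "residue_id",
                 "x", "y", "z", "element"), drop = FALSE]
    df$molecule <- rep(label, nrow(df))
    df
  }
  heavy <- rbind(heavy_part(lX, "ligand"), heavy_part(pX, "protein"))
  rownames(heavy) <- NULL
  new_spin_system(protons, heavy, source_label)
}

#' Tag directly saturated protein protons
#'
#' Either the built-in `"methyls"` rule (every protein CH3 proton per the
#' residue/atom-name dictionary: ALA, VAL, LEU, ILE, THR(CG2), MET, ACE/NME
#' caps) or an explicit character vector of `"resid:atomname"` pairs.
#'
#' @param system A `spin_system`.
#' @param selection `"methyls"` or character vector like `c("12:HA","45:HB2")`.
#' @return The system with matching protein protons retagged
#'   `SATURATED_PROTEIN`; a system with zero saturated protons is flagged
#'   un-scorable, not an error.
#' @export
select_saturated <- function(system, selection = "methyls") {
  stopifnot(inherits(system, "spin_system"))
  pr <- system$protons
  is_protein <- pr$group != "LIGAND"
  if (identical(selection, "methyls")) {
    hit <- is_protein & !is.na(pr$methyl_id)
  } else {
    sel <- trimws(as.character(selection))
    if (length(sel)) {
      parts <- strsplit(sel, ":", fixed = TRUE)
      bad <- lengths(parts) != 2L
      if (any(bad)) {
        stop("malformed saturation entries (want 'resid:atomname'): ",
             paste(sel[bad], collapse = ", "))
      }
      want_id <- vapply(parts, function(p) as.integer(p[1]), integer(1))
      want_nm <- vapply(parts, function(p) normalize_atom_name(p[2]),
                        character(1))
      key <- paste0(pr$residue_id, ":", pr$atom_name)
      want <- paste0(want_id, ":", want_nm)
      unmatched <- setdiff(want, key[is_protein])
      if (length(unmatched)) {
        stop("saturation selection names atoms absent from the protein: ",
             paste(unmatched, collapse = ", "))
      }
      hit <- is_protein & key %in% want
    } else {
      hit <- rep(FALSE, nrow(pr))
    }
  }
  pr$group[is_protein] <- "UNSATURATED_PROTEIN"
  pr$group[hit] <- "SATURATED_PROTEIN"
  new_spin_system(pr, system$heavy, system$source_label)
}

#' Prune protein protons beyond a cutoff from the ligand
#'
#' Protein protons (saturated and unsaturated alike) whose minimum distance
#' to any ligand proton exceeds `cutoff` are removed; ligand protons are
#' never removed. A proton at exactly the cutoff is kept. Pruning is
#' idempotent and monotone in the cutoff.
#'
#' @param system A `spin_system`.
#' @param cutoff Distance in Angstrom (> 0); `Inf` leaves the system intact.
#' @return Pruned `spin_system` (scorable flag recomputed).
#' @export
apply_cutoff <- function(system, cutoff) {
  stopifnot(inherits(system, "spin_system"), is.numeric(cutoff),
            length(cutoff) == 1L, cutoff > 0)
  pr <- system$protons
  lig <- pr$group == "LIGAND"
  if (!any(lig) || is.infinite(cutoff)) {
    return(new_spin_system(pr, system$heavy, system$source_label))
  }
  lxyz <- as.matrix(pr[lig, c("x", "y", "z")])
  keep <- lig
  prot_idx <- which(!lig)
  if (length(prot_idx)) {
    pxyz <- as.matrix(pr[prot_idx, c("x", "y", "z")])
    for (k in seq_along(prot_idx)) {
      d2 <- (lxyz[, 1] - pxyz[k, 1])^2 + (lxyz[, 2] - pxyz[k, 2])^2 +
        (lxyz[, 3] - pxyz[k, 3])^2
      keep[prot_idx[k]] <- min(d2) <= cutoff^2
    }
  }
  new_spin_system(pr[keep, , drop = FALSE], system$heavy,
                  system$source_label)
}

proton_coords <- function(system, group = NULL) {
  pr <- system$protons
  if (!is.null(group)) pr <- pr[pr$group %in% group, , drop = FALSE]
  as.matrix(pr[, c("x", "y", "z")])
}
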