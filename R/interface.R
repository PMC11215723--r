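# Run configuration and the two documented modes: static (single structure
# or docking-pose ensemble) and dynamic (trajectory). Every run can write a
# resolved-config record for provenance; INFO logging narrates the
# quantities a user must sanity-check (pruning counts, saturated-proton
# counts, bound fraction).

#' Assemble and validate a run configuration
#'
#' @param mode `"static"`, `"trajectory"` or `"oracle"`.
#' @param frequency_mhz,tau_c_ns,tau_c_free_ns,cutoff_angstrom,methyl_averaging
#'   Relaxation parameters (see [relaxation_params()]).
#' @param protein_conc_uM,ligand_conc_uM,kd_uM Binding parameters (uM).
#' @param protein_pdb,ligand_pdb Static-mode inputs.
#' @param topology,trajectory_file Trajectory-mode inputs.
#' @param epitope_file Experimental epitope table.
#' @param saturation `"methyls"` or `resid:atomname` list.
#' @param ligand_select Trajectory ligand selection (residue name(s)).
#' @param stride,dt_ns,rfactor_threshold,seed Remaining knobs.
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode = c("static", "trajectory", "oracle"),
                       frequency_mhz = 600, tau_c_ns = 10,
                       tau_c_free_ns = 0.5, cutoff_angstrom = 10,
                       methyl_averaging = FALSE,
                       protein_conc_uM = 20, ligand_conc_uM = 1000,
                       kd_uM = 1000,
                       protein_pdb = NULL, ligand_pdb = NULL,
                       topology = NULL, trajectory_file = NULL,
                       epitope_file = NULL,
                       saturation = "methyls", ligand_select = "LIG",
                       stride = 1L, dt_ns = 1,
                       rfactor_threshold = 0.3, seed = 1L) {
  mode <- match.arg(mode)
  num <- c(frequency_mhz = frequency_mhz, tau_c_ns = tau_c_ns,
           tau_c_free_ns = tau_c_free_ns, cutoff_angstrom = cutoff_angstrom,
           protein_conc_uM = protein_conc_uM, ligand_conc_uM = ligand_conc_uM,
           kd_uM = kd_uM, stride = stride, dt_ns = dt_ns)
  if (any(!is.finite(num)) || any(num <= 0)) {
    bad <- names(num)[!is.finite(num) | num <= 0]
    stop("physical parameters must be positive: ", paste(bad, collapse = ", "))
  }
  if (mode == "static" && (is.null(protein_pdb) || is.null(ligand_pdb))) {
    stop("static mode needs protein_pdb and ligand_pdb")
  }
  if (mode == "trajectory" && is.null(trajectory_file)) {
    stop("trajectory mode needs trajectory_file (and topology unless PDB)")
  }
  cfg <- list(mode = mode, frequency_mhz = frequency_mhz,
              tau_c_ns = tau_c_ns, tau_c_free_ns = tau_c_free_ns,
              cutoff_angstrom = cutoff_angstrom,
              methyl_averaging = isTRUE(methyl_averaging),
              protein_conc_uM = protein_conc_uM,
              ligand_conc_uM = ligand_conc_uM, kd_uM = kd_uM,
              protein_pdb = protein_pdb, ligand_pdb = ligand_pdb,
              topology = topology, trajectory_file = trajectory_file,
              epitope_file = epitope_file, saturation = saturation,
              ligand_select = ligand_select, stride = as.integer(stride),
              dt_ns = dt_ns, rfactor_threshold = rfactor_threshold,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a key=value configuration file
#'
#' Plain text, one `key = value` per line, `#` comments. List-valued keys
#' (`saturation`, `ligand_select`) are comma-separated. Keys mirror
#' [run_config()] arguments; unknown keys are an error.
#'
#' @param path Config file path.
#' @param ... Overrides applied after the file is read.
#' @export
read_config <- function(path, ...) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- regmatches(ln, regexec("^([A-Za-z_0-9]+)[[:space:]]*=[[:space:]]*(.*)$", ln))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("malformed config line(s): ", paste(ln[bad], collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  args <- list()
  numeric_keys <- c("frequency_mhz", "tau_c_ns", "tau_c_free_ns",
                    "cutoff_angstrom", "protein_conc_uM", "ligand_conc_uM",
                    "kd_uM", "stride", "dt_ns", "rfactor_threshold", "seed")
  list_keys <- c("saturation", "ligand_select")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% numeric_keys) {
      args[[k]] <- as.numeric(v)
    } else if (k == "methyl_averaging") {
      args[[k]] <- toupper(v) %in% c("TRUE", "T", "YES", "1")
    } else if (k %in% list_keys) {
      v <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
      args[[k]] <- if (identical(v, "methyls")) "methyls" else v
    } else if (k %in% names(formals(run_config))) {
      args[[k]] <- v
    } else {
      stop("unknown config key: ", k)
    }
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

cfg_params <- function(cfg) {
  relaxation_params(cfg$frequency_mhz, cfg$tau_c_ns, cfg$tau_c_free_ns,
                    cfg$cutoff_angstrom, cfg$methyl_averaging)
}

cfg_binding <- function(cfg) {
  solve_binding(cfg$protein_conc_uM, cfg$ligand_conc_uM, cfg$kd_uM)
}

log_info <- function(verbose, ...) {
  if (verbose) message("INFO: ", sprintf(...))
}

#' Static mode: score one structure or a docking-pose ensemble
#'
#' Each MODEL in the ligand file is scored independently; the result table
#' is sorted by R-factor ascending (ties by model index). Per-model errors
#' are caught and reported in the table without aborting the other models.
#'
#' @param config A [run_config()] (mode `"static"`).
#' @param exp_epitope Optional pre-built [epitope()] (otherwise
#'   `config$epitope_file` is read).
#' @param keys Optional epitope key map (see [aggregate_by_key()]).
#' @param verbose Emit INFO logging (default `TRUE`).
#' @param output_dir If non-NULL, write the score table, per-model
#'   epitopes and a run record there.
#' @return data.frame: `model`, `r_factor`, `n_matched`, `classification`,
#'   `status`; attribute `"epitopes"` holds per-model calculated epitopes.
#' @export
run_static <- function(config, exp_epitope = NULL, keys = NULL,
                       verbose = TRUE, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"), config$mode == "static")
  t_start <- proc.time()[["elapsed"]]
  if (is.null(exp_epitope)) {
    if (is.null(config$epitope_file)) {
      stop("no experimental epitope: set epitope_file or pass exp_epitope")
    }
    if (!file.exists(config$epitope_file)) {
      stop("epitope file not found: ", config$epitope_file)
    }
    exp_epitope <- read_epitope(config$epitope_file)
  }
  params <- cfg_params(config)
  binding <- cfg_binding(config)
  log_info(verbose, "ligand bound fraction %.4f ([PL] = %.4g uM)",
           binding$bound_fraction_ligand, binding$complex_conc)
  n_models <- length(read_pdb(config$ligand_pdb))
  rows <- vector("list", n_models)
  epitopes <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    rows[[m]] <- tryCatch({
      sys <- parse_complex(config$protein_pdb, config$ligand_pdb,
                           model_index = m)
      sys <- select_saturated(sys, config$saturation)
      n_sat_all <- sum(sys$protons$group == "SATURATED_PROTEIN")
      sys <- apply_cutoff(sys, params$cutoff)
      n_sat <- sum(sys$protons$group == "SATURATED_PROTEIN")
      n_prot <- sum(sys$protons$group != "LIGAND")
      log_info(verbose,
               "model %d: %d protein protons within %.3g A (%d/%d saturated)",
               m, n_prot, params$cutoff, n_sat, n_sat_all)
      if (!sys$scorable) {
        data.frame(model = m, r_factor = NA_real_, n_matched = NA_integer_,
                   classification = NA_character_, status = "un-scorable")
      } else {
        ep <- calculated_epitope(sys, params, binding, keys = keys)
        sc <- suppressWarnings(noe_r_factor(exp_epitope, ep))
        epitopes[[m]] <- ep
        data.frame(model = m, r_factor = sc$r_factor,
                   n_matched = sc$n_matched,
                   classification = classify_fit(sc), status = "scored")
      }
    }, error = function(e) {
      data.frame(model = m, r_factor = NA_real_, n_matched = NA_integer_,
                 classification = NA_character_,
                 status = paste0("error: ", conditionMessage(e)))
    })
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(is.na(tab$r_factor), tab$r_factor, tab$model), ]
  rownames(tab) <- NULL
  attr(tab, "epitopes") <- epitopes
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- tab
    out$r_factor <- round(out$r_factor, 3)
    utils::write.table(out, file.path(output_dir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (m in which(!vapply(epitopes, is.null, logical(1)))) {
      write_epitope(epitopes[[m]],
                    file.path(output_dir, sprintf("epitope_model%03d.tsv", m)))
    }
    write_run_record(config, output_dir,
                     proc.time()[["elapsed"]] - t_start)
  }
  tab
}

#' Dynamic mode: score an MD trajectory
#'
#' Thin orchestration over [read_trajectory()] and [score_trajectory()];
#' optionally writes the time series, extracted frames and a run record.
#'
#' @inheritParams run_static
#' @param traj Optional pre-built [trajectory()] (otherwise read from
#'   `config$trajectory_file` / `config$topology`).
#' @return The `trajectory_score` (see [score_trajectory()]).
#' @export
run_dynamic <- function(config, exp_epitope = NULL, traj = NULL, keys = NULL,
                        verbose = TRUE, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"), config$mode == "trajectory")
  t_start <- proc.time()[["elapsed"]]
  if (is.null(exp_epitope)) {
    if (is.null(config$epitope_file)) {
      stop("no experimental epitope: set epitope_file or pass exp_epitope")
    }
    if (!file.exists(config$epitope_file)) {
      stop("epitope file not found: ", config$epitope_file)
    }
    exp_epitope <- read_epitope(config$epitope_file)
  }
  if (is.null(traj)) {
    traj <- read_trajectory(config$trajectory_file, config$topology,
                            dt_ns = config$dt_ns)
  }
  params <- cfg_params(config)
  binding <- cfg_binding(config)
  log_info(verbose, "ligand bound fraction %.4f; %d frames, stride %d",
           binding$bound_fraction_ligand, n_frames(traj), config$stride)
  score <- score_trajectory(traj, exp_epitope, params, binding,
                            ligand_select = config$ligand_select,
                            saturation = config$saturation,
                            stride = config$stride, keys = keys)
  log_info(verbose, "%d/%d frames dissociated",
           sum(score$dissociated), nrow(score))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- data.frame(frame = score$frame,
                      time_ns = score$time_ns,
                      r_factor = ifelse(score$dissociated, NA,
                                        round(score$r_factor, 3)))
    utils::write.table(out, file.path(output_dir, "rfactor_series.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    sel <- suppressWarnings(
      extract_frames(score, config$rfactor_threshold, traj,
                     file.path(output_dir, "extracted_frames.pdb")))
    log_info(verbose, "%d frame(s) below R-factor %.3g extracted",
             length(sel), config$rfactor_threshold)
    write_run_record(config, output_dir,
                     proc.time()[["elapsed"]] - t_start)
  }
  score
}

write_run_record <- function(config, output_dir, wall_s) {
  path <- file.path(output_dir, "run_record.txt")
  flat <- vapply(config, function(v) paste(format(v), collapse = ","),
                 character(1))
  writeLines(c(
    sprintf("# stdepitope %s run record",
            as.character(utils::packageVersion("stdepitope"))),
    sprintf("# wall_time_s = %.3f", wall_s),
    sprintf("%s = %s", names(flat), flat)
  ), path)
  invisible(path)
}

#' Minimal R-factor-vs-time figure helper
#'
#' Base-graphics plot of a `trajectory_score`; dissociated frames appear
#' as gaps.
#'
#' @param score A `trajectory_score`.
#' @param threshold Reference line (default 0.3).
#' @export
plot_rfactor_series <- function(score, threshold = 0.3) {
  stopifnot(inherits(score, "trajectory_score"))
  y <- ifelse(score$dissociated, NA, score$r_factor)
  plot(score$time_ns, y, type = "b", pch = 16,
       xlab = "time (ns)", ylab = "NOE R-factor",
       main = "NOE R-factor along the trajectory")
  graphics::abline(h = threshold, lty = 2)
  invisible(score)
}
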