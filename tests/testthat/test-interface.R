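# Multi-model static scoring fixture: 5 ligand poses, pose 2 is the
# planted near-native one (its calculated epitope generated the synthetic
# "experimental" data).
static_fixture <- function(dir = tempdir()) {
  fx <- make_spin_fixture("mini_complex", dir = dir)
  lig <- read_pdb(fx$ligand_pdb)[[1]]
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  shifts <- list(c(0, -3, 0), c(0, 0, 0), c(2, 0, 2), c(-2, -1, 0),
                 c(1.5, 1.5, -1))
  arr <- array(NA_real_, c(nrow(lig), 3, length(shifts)))
  for (m in seq_along(shifts)) arr[, , m] <- sweep(xyz, 2, shifts[[m]], "+")
  mm <- file.path(dir, "poses.pdb")
  write_pdb_frames(lig, arr, mm)
  # synthetic experimental epitope from the true pose
  p <- relaxation_params(600, 34.5, cutoff = 12)
  b <- solve_binding(20, 1000, 2000)
  sys <- apply_cutoff(select_saturated(
    parse_complex(fx$protein_pdb, mm, 2), "methyls"), 12)
  truth <- calculated_epitope(sys, p, b)
  epf <- file.path(dir, "exp_epitope.tsv")
  writeLines(paste(truth$epitope_key, round(truth$rel, 1)), epf)
  cfg <- run_config("static", frequency_mhz = 600, tau_c_ns = 34.5,
                    cutoff_angstrom = 12, protein_conc_uM = 20,
                    ligand_conc_uM = 1000, kd_uM = 2000,
                    protein_pdb = fx$protein_pdb, ligand_pdb = mm,
                    epitope_file = epf)
  list(cfg = cfg, fx = fx, poses = mm, epf = epf)
}

test_that("static mode ranks the planted near-native pose first", {
  sf <- static_fixture()
  tab <- run_static(sf$cfg, verbose = FALSE)
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$model[1], 2L)
  expect_lt(tab$r_factor[1], 0.05)
  expect_identical(tab$classification[1], "good")
  # table sorted by R-factor ascending
  scored <- tab$r_factor[!is.na(tab$r_factor)]
  expect_true(!is.unsorted(scored))
})

test_that("un-scorable and failing models do not abort the ensemble", {
  sf <- static_fixture()
  lig <- read_pdb(sf$fx$ligand_pdb)[[1]]
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  arr <- array(NA_real_, c(nrow(lig), 3, 3))
  arr[, , 1] <- xyz
  arr[, , 2] <- xyz + 100  # far outside every cutoff: un-scorable
  arr[, , 3] <- xyz
  mm <- tempfile(fileext = ".pdb")
  write_pdb_frames(lig, arr, mm)
  cfg <- sf$cfg; cfg$ligand_pdb <- mm
  tab <- run_static(cfg, verbose = FALSE)
  expect_identical(sort(tab$status), sort(c("scored", "scored", "un-scorable")))
  expect_true(all(is.na(tab$r_factor[tab$status == "un-scorable"])))
})

test_that("a single-model ligand yields a one-row table", {
  sf <- static_fixture()
  cfg <- sf$cfg; cfg$ligand_pdb <- sf$fx$ligand_pdb
  tab <- run_static(cfg, verbose = FALSE)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$status, "scored")
})

test_that("config files parse with overrides, and bad keys or params fail", {
  cf <- tempfile()
  writeLines(c(
    "# run settings",
    "mode = static",
    "frequency_mhz = 500",
    "tau_c_ns = 10",
    "cutoff_angstrom = 10",
    "protein_conc_uM = 45",
    "ligand_conc_uM = 1000",
    "kd_uM = 2000",
    "saturation = methyls",
    "protein_pdb = /tmp/p.pdb",
    "ligand_pdb = /tmp/l.pdb"
  ), cf)
  cfg <- read_config(cf)
  expect_identical(cfg$frequency_mhz, 500)
  expect_identical(cfg$protein_conc_uM, 45)
  cfg2 <- read_config(cf, cutoff_angstrom = 12)
  expect_identical(cfg2$cutoff_angstrom, 12)
  writeLines(c("mode = static", "bogus_key = 1"), cf)
  expect_error(read_config(cf), "unknown config key")
  expect_error(run_config("static", tau_c_ns = -1, protein_pdb = "x",
                          ligand_pdb = "y"), "positive")
  expect_error(run_config("static"), "protein_pdb")
})

test_that("missing epitope input fails before any computation", {
  sf <- static_fixture()
  cfg <- sf$cfg; cfg$epitope_file <- "/nonexistent/epitope.tsv"
  expect_error(run_static(cfg, verbose = FALSE), "not found")
  cfg$epitope_file <- NULL
  expect_error(run_static(cfg, verbose = FALSE), "no experimental epitope")
})

test_that("runs are deterministic and leave a complete run record", {
  sf <- static_fixture()
  d1 <- tempfile(); d2 <- tempfile()
  t1 <- run_static(sf$cfg, verbose = FALSE, output_dir = d1)
  t2 <- run_static(sf$cfg, verbose = FALSE, output_dir = d2)
  expect_identical(readLines(file.path(d1, "scores.tsv")),
                   readLines(file.path(d2, "scores.tsv")))
  rec <- readLines(file.path(d1, "run_record.txt"))
  expect_true(any(grepl("^mode = static", rec)))
  expect_true(any(grepl("wall_time_s", rec)))
  expect_true(file.exists(file.path(d1, "epitope_model001.tsv")))
})

test_that("dynamic mode writes the time series and extracted frames", {
  tf <- make_trajectory_fixture()
  p <- relaxation_params(600, 34.5, cutoff = 12)
  b <- solve_binding(20, 1000, 2000)
  sys <- apply_cutoff(select_saturated(
    stdepitope:::frame_spin_system(tf$traj, 1, "LIG"), "methyls"), 12)
  truth <- calculated_epitope(sys, p, b)
  epf <- tempfile()
  writeLines(paste(truth$epitope_key, round(truth$rel, 1)), epf)
  cfg <- run_config("trajectory", frequency_mhz = 600, tau_c_ns = 34.5,
                    cutoff_angstrom = 12, protein_conc_uM = 20,
                    ligand_conc_uM = 1000, kd_uM = 2000,
                    topology = tf$topology, trajectory_file = tf$mdcrd,
                    epitope_file = epf, ligand_select = "LIG", dt_ns = 0.1)
  outd <- tempfile()
  score <- run_dynamic(cfg, verbose = FALSE, output_dir = outd)
  expect_identical(score$frame[score$dissociated], 4:6)
  series <- read.table(file.path(outd, "rfactor_series.tsv"), header = TRUE,
                       sep = "\t")
  expect_identical(nrow(series), 10L)
  expect_true(all(is.na(series$r_factor[4:6])))
  expect_true(file.exists(file.path(outd, "extracted_frames.pdb")))
  expect_true(file.exists(file.path(outd, "run_record.txt")))
})
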