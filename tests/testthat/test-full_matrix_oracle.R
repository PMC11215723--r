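test_that("STD factors start at zero and rise toward an asymptote", {
  fx <- make_spin_fixture("two_spin", r = 3.0)
  p <- default_params(); b <- default_binding()
  kin <- exchange_kinetics(koff = 1e4, kd = b$kd)
  sol <- solve_buildup(fx$system, p, b, kin, c(0, 0.05, 0.2, 0.5, 1, 2, 4))
  expect_equal(unname(sol$std_factors[1, 1]), 0, tolerance = 1e-15)
  expect_true(all(diff(sol$std_factors[1, ]) > 0))
  # the local build-up rate decays (saturating curve)
  rate <- diff(sol$std_factors[1, ]) / diff(sol$t)
  expect_lt(rate[length(rate)], rate[1])
})

test_that("fully bound 2-spin limit matches the mono-exponential closed form", {
  fx <- make_spin_fixture("two_spin", r = 2.8)
  p <- default_params()
  b <- solve_binding(2000, 1000, 1e-2)  # essentially all ligand bound
  kin <- exchange_kinetics(koff = 10, kd = b$kd)
  t_grid <- c(0, exp(seq(log(1e-3), log(1.5), length.out = 14)))
  sol <- solve_buildup(fx$system, p, b, kin, t_grid)
  f <- fit_buildup(sol$t[-1], sol$std_factors[1, -1])
  # initial slope from sigma: STD0 = -sigma * [PL]/[L]_tot
  sigma <- cross_relaxation_rate(2.8, p)
  std0_ref <- -sigma * b$complex_conc / b$ligand_total
  expect_equal(f$std0, std0_ref, tolerance = 0.01)
})

test_that("finite-difference slopes are exact on linear input and O(h^2) on curves", {
  # linear synthetic input: construct a solution object by hand
  h <- 1e-4
  lin <- structure(list(
    t = c(0, h, 2 * h),
    std_factors = matrix(c(0, 3 * h, 6 * h), 1,
                         dimnames = list("H1", NULL)),
    generator = list(A = matrix(numeric(0), 0, 0)),
    ligand = data.frame(atom_name = "H1")), class = "buildup_solution")
  expect_equal(unname(initial_slope_fd(lin)), 3, tolerance = 1e-12)
  # Richardson on an exact exponential: halving h shrinks error ~4x
  stdmax <- 0.4; ksat <- 3
  mk <- function(h) structure(list(
    t = c(0, h, 2 * h),
    std_factors = matrix(stdmax * (1 - exp(-ksat * c(0, h, 2 * h))), 1,
                         dimnames = list("H1", NULL)),
    generator = list(A = matrix(numeric(0), 0, 0)),
    ligand = data.frame(atom_name = "H1")), class = "buildup_solution")
  err <- function(h) abs(initial_slope_fd(mk(h)) - stdmax * ksat)
  ratio <- err(2e-3) / err(1e-3)
  expect_gt(ratio, 3.3)
  expect_lt(ratio, 4.7)
  # zero saturated set: all slopes zero
  fx <- make_spin_fixture("two_spin")
  none <- select_saturated(fx$system, character(0))
  p <- default_params(); b <- default_binding()
  kin <- exchange_kinetics(1e4, b$kd)
  sol0 <- solve_buildup(none, p, b, kin, c(0, 1e-6, 2e-6))
  expect_true(all(sol0$std_factors == 0))
})

test_that("the linear-regime guard rejects too-large first steps", {
  fx <- make_spin_fixture("three_spin")
  p <- default_params(); b <- default_binding()
  kin <- exchange_kinetics(1e4, b$kd)
  sol <- solve_buildup(fx$system, p, b, kin, c(0, 0.5, 1.0))
  expect_error(initial_slope_fd(sol), "linear regime")
})

test_that("without the clamp the system stays at thermal equilibrium", {
  fx <- make_spin_fixture("methyl_probe")
  none <- select_saturated(fx$system, character(0))
  p <- default_params(); b <- default_binding()
  kin <- exchange_kinetics(1e3, b$kd)
  sol <- solve_buildup(none, p, b, kin, c(0, 0.1, 0.5))
  for (j in 1:3) expect_equal(sol$intensities[, j], sol$intensities[, 1],
                              tolerance = 1e-12)
})

test_that("exchange blocks satisfy detailed balance at equilibrium", {
  fx <- make_spin_fixture("three_spin")
  p <- default_params(); b <- default_binding()
  kin <- exchange_kinetics(5e3, b$kd)
  sol <- solve_buildup(fx$system, p, b, kin, c(0, 1e-6, 2e-6))
  g <- sol$generator$g
  # K annihilates the equilibrium intensity vector: no net exchange flux
  expect_equal(max(abs(g$K %*% g$I0)), 0,
               tolerance = 1e-9 * max(abs(g$K)) * max(g$I0))
  # flux identity: kon [P][L] = koff [PL]
  expect_equal(kin$kon * b$free_protein * b$free_ligand,
               kin$koff * b$complex_conc, tolerance = 1e-9)
})

test_that("oracle slopes track the reduced matrix across a koff ladder", {
  # the t -> 0 slope is exchange-independent by construction, so the
  # reduced prediction must hold across the whole kinetic ladder
  fx <- make_spin_fixture("methyl_probe", n_ligand = 2)
  p <- default_params(); b <- default_binding()
  red <- std0_calc(assemble_M(fx$system, p, b))
  errs <- vapply(c(1e2, 1e3, 1e4, 1e5), function(koff) {
    kin <- exchange_kinetics(koff, b$kd)
    h <- min(1e-7, 0.001 / koff)
    sol <- solve_buildup(fx$system, p, b, kin, c(0, h, 2 * h))
    fd <- initial_slope_fd(sol)
    max(abs(fd - red$std0_abs) / red$std0_abs)
  }, numeric(1))
  expect_true(all(errs < 0.02))
})

test_that("single-time epitopes diverge from slope epitopes at long saturation", {
  fx <- make_spin_fixture("methyl_probe", n_ligand = 2)
  p <- default_params(); b <- default_binding()
  kin <- exchange_kinetics(1e4, b$kd)
  short <- suppressWarnings(
    single_time_vs_buildup(fx$system, p, b, kin, t_single = 1e-4, h = 1e-7))
  expect_lt(short$r_single, 0.02)  # t -> 0: epitopes coincide
  expect_equal(short$r_slope, 0, tolerance = 1e-12)
  long <- suppressWarnings(
    single_time_vs_buildup(fx$system, p, b, kin, t_single = 2, h = 1e-7))
  expect_gt(long$r_single, short$r_single)
})

test_that("the oracle refuses oversized spin systems", {
  fx <- make_spin_fixture("random_cloud", seed = 2, n_ligand = 20,
                          n_sat = 20, n_unsat = 5)
  p <- default_params(); b <- default_binding()
  kin <- exchange_kinetics(1e4, b$kd)
  expect_error(solve_buildup(fx$system, p, b, kin, c(0, 1e-7, 2e-7)),
               "capped")
})
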