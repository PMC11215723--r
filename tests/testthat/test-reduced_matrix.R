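test_that("M blocks equal brute-force sigma(i,j) * equilibrium intensity", {
  fx <- make_spin_fixture("random_cloud", seed = 3, n_ligand = 2, n_sat = 2,
                          n_unsat = 2)
  sys <- fx$system
  p <- default_params()
  b <- default_binding()
  M <- assemble_M(sys, p, b)
  pr <- sys$protons
  lig <- pr[pr$group == "LIGAND", ]
  sat <- pr[pr$group == "SATURATED_PROTEIN", ]
  uns <- pr[pr$group == "UNSATURATED_PROTEIN", ]
  tau <- 34.5e-9
  for (i in seq_len(nrow(lig))) for (j in seq_len(nrow(sat))) {
    r <- sqrt(sum((lig[i, c("x", "y", "z")] - sat[j, c("x", "y", "z")])^2))
    expect_equal(M$L_block[i, j], sigma_ref(r, 600, tau) * b$complex_conc,
                 tolerance = 1e-12)
  }
  for (i in seq_len(nrow(uns))) for (j in seq_len(nrow(sat))) {
    r <- sqrt(sum((uns[i, c("x", "y", "z")] - sat[j, c("x", "y", "z")])^2))
    expect_equal(M$E1p_block[i, j], sigma_ref(r, 600, tau) * b$complex_conc,
                 tolerance = 1e-12)
    expect_equal(M$E1_block[i, j], sigma_ref(r, 600, tau) * b$free_protein,
                 tolerance = 1e-12)
  }
})

test_that("a 1x1 system gives L block = sigma * I_E2'0 and zero complex zeroes it", {
  fx <- make_spin_fixture("two_spin", r = 3.0)
  p <- default_params()
  b <- default_binding()
  M <- assemble_M(fx$system, p, b)
  expect_identical(dim(M$L_block), c(1L, 1L))
  expect_equal(M$L_block[1, 1],
               cross_relaxation_rate(3.0, p) * b$complex_conc,
               tolerance = 1e-9)
  # degenerate binding state with no complex: all-zero block, then no pathway
  b0 <- b; b0$complex_conc <- 0
  M0 <- assemble_M(fx$system, p, b0)
  expect_true(all(M0$L_block == 0))
  expect_error(std0_calc(M0), "no saturation pathway")
  # un-scorable systems are rejected up front
  expect_error(assemble_M(select_saturated(fx$system, character(0)), p, b),
               "un-scorable")
})

test_that("relative epitopes follow the pure r^-6 law for a single source", {
  fx <- make_spin_fixture("three_spin", r1 = 2.5, r2 = 5.0)
  ep <- std0_calc(assemble_M(fx$system, default_params(), default_binding()))
  expect_equal(ep$rel, c(100, 1.5625), tolerance = 1e-6)
  expect_equal(max(ep$rel), 100)
  # single ligand proton: trivially 100%
  ep1 <- std0_calc(assemble_M(make_spin_fixture("two_spin")$system,
                              default_params(), default_binding()))
  expect_identical(ep1$rel, 100)
})

test_that("relative epitopes are invariant to intensity rescaling and Kd", {
  p <- default_params()
  fx <- make_spin_fixture("three_spin")
  rel_at <- function(b) std0_calc(assemble_M(fx$system, p, b))$rel
  b1 <- solve_binding(20, 1000, 2000)
  b2 <- solve_binding(20, 1000, 50)    # very different bound fraction
  expect_equal(rel_at(b1), rel_at(b2), tolerance = 1e-9)
  # absolute STD0 scales linearly with complex concentration
  a1 <- std0_calc(assemble_M(fx$system, p, b1))$std0_abs
  a2 <- std0_calc(assemble_M(fx$system, p, b2))$std0_abs
  expect_equal(a2 / a1, rep(b2$complex_conc / b1$complex_conc, 2),
               tolerance = 1e-9)
  # duplicating the saturated source set leaves the relative epitope unchanged
  one <- line_complex(c(4))
  two <- line_complex(c(4, 4))  # second identical-distance source
  r_one <- std0_calc(assemble_M(one$system, p, b1))$std0_abs
  r_two <- std0_calc(assemble_M(two$system, p, b1))$std0_abs
  expect_equal(r_two, 2 * r_one, tolerance = 1e-9)
})

test_that("aggregation averages absolute STD0 within keys then renormalizes", {
  fx <- make_spin_fixture("methyl_probe", n_ligand = 2)
  p <- default_params(); b <- default_binding()
  ep <- std0_calc(assemble_M(fx$system, p, b))
  # identity map: unchanged
  expect_equal(aggregate_by_key(ep)$rel, ep$rel, tolerance = 1e-12)
  # merge the two ligand protons under one key: mean of absolutes
  agg <- aggregate_by_key(ep, keys = c(H1 = "HX", H2 = "HX"))
  expect_identical(nrow(agg), 1L)
  expect_equal(agg$std0_abs, mean(ep$std0_abs), tolerance = 1e-12)
  expect_identical(agg$rel, 100)
  # 2 keys over 5 protons: hand-computed means
  fx5 <- make_spin_fixture("random_cloud", seed = 5, n_ligand = 5,
                           n_sat = 2, n_unsat = 0)
  ep5 <- std0_calc(assemble_M(fx5$system, p, b))
  key_map <- c(H1 = "A", H2 = "A", H3 = "A", H4 = "B", H5 = "B")
  agg5 <- aggregate_by_key(ep5, keys = key_map)
  hand <- c(mean(ep5$std0_abs[1:3]), mean(ep5$std0_abs[4:5]))
  expect_equal(agg5$std0_abs[match(c("A", "B"), agg5$epitope_key)], hand,
               tolerance = 1e-12)
  expect_equal(max(agg5$rel), 100)
  # unknown key target errors
  expect_error(aggregate_by_key(ep, keys = c(H9 = "X")), "absent")
})

test_that("moving a ligand proton away from the sole source never raises its share", {
  p <- default_params(); b <- default_binding()
  for (seed in 1:4) {
    set.seed(seed)
    d <- sort(runif(4, 2, 9))
    # one saturated source at origin, ligand protons on a line at distances d
    prot <- data.frame(atom_name = "HA", residue_name = "GLY", residue_id = 1,
                       x = 0, y = 0, z = 0, element = "H", is_hydrogen = TRUE)
    lig <- data.frame(atom_name = paste0("H", 1:4), residue_name = "LIG",
                      residue_id = 1, x = d, y = 0, z = 0, element = "H",
                      is_hydrogen = TRUE)
    pf <- tempfile(fileext = ".pdb"); lf <- tempfile(fileext = ".pdb")
    write_pdb_frames(prot, as.matrix(prot[, c("x", "y", "z")]), pf)
    write_pdb_frames(lig, as.matrix(lig[, c("x", "y", "z")]), lf)
    sys <- select_saturated(parse_complex(pf, lf), "1:HA")
    rel <- std0_calc(assemble_M(sys, p, b))$rel
    expect_true(all(diff(rel) <= 1e-12))
  }
})
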