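test_that("parse_complex returns every hydrogen with correct group tags", {
  fx <- make_spin_fixture("mini_complex")
  # count H records in the emitted files independently of the parser
  count_h <- function(path) {
    ln <- readLines(path)
    at <- ln[substring(ln, 1, 4) == "ATOM"]
    sum(toupper(trimws(substring(at, 77, 78))) == "H")
  }
  sys <- parse_complex(fx$protein_pdb, fx$ligand_pdb)
  expect_identical(nrow(sys$protons),
                   count_h(fx$protein_pdb) + count_h(fx$ligand_pdb))
  expect_setequal(unique(sys$protons$group[sys$protons$residue_name == "LIG"]),
                  "LIGAND")
  # before selection all protein protons are unsaturated
  prot <- sys$protons[sys$protons$residue_name != "LIG", ]
  expect_true(all(prot$group == "UNSATURATED_PROTEIN"))
  # ALA methyl protons are present and dictionary-tagged
  ala <- sys$protons[sys$protons$residue_name == "ALA", ]
  expect_true(all(c("HB1", "HB2", "HB3") %in% ala$atom_name))
  # methyl trios are complete
  mid <- sys$protons$methyl_id
  expect_true(all(table(mid[!is.na(mid)]) == 3))
})

test_that("multi-model ligand files select coordinates by model index", {
  fx <- make_spin_fixture("mini_complex")
  lig <- read_pdb(fx$ligand_pdb)[[1]]
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  arr <- array(NA_real_, c(nrow(lig), 3, 5))
  for (m in 1:5) arr[, , m] <- xyz + (m - 1) * 2
  mm <- tempfile(fileext = ".pdb")
  write_pdb_frames(lig, arr, mm)
  sys3 <- parse_complex(fx$protein_pdb, mm, model_index = 3)
  lig3 <- sys3$protons[sys3$protons$group == "LIGAND", ]
  base <- parse_complex(fx$protein_pdb, fx$ligand_pdb)
  lig1 <- base$protons[base$protons$group == "LIGAND", ]
  expect_equal(lig3$x, lig1$x + 4, tolerance = 1e-3)
  expect_error(parse_complex(fx$protein_pdb, mm, model_index = 9),
               "out of range")
})

test_that("structures without hydrogens are rejected with guidance", {
  noh <- paste0(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "           C")
  withH <- c(noh, paste0(
    "ATOM      2  HA  GLY A   1       1.000   0.000   0.000  1.00  0.00",
    "           H"))
  pf <- tempfile(fileext = ".pdb"); writeLines(noh, pf)
  lf <- tempfile(fileext = ".pdb"); writeLines(withH, lf)
  expect_error(parse_complex(pf, lf), "no hydrogen.*protonate")
  expect_error(parse_complex(lf, pf), "no hydrogen.*protonate")
})

test_that("malformed coordinate records report the line number", {
  bad <- c(
    "ATOM      1  HA  GLY A   1       0.000   0.000   0.000  1.00  0.00           H",
    "ATOM      2  HB  GLY A   1       xx.xxx   0.000   0.000  1.00  0.00           H")
  pf <- tempfile(fileext = ".pdb"); writeLines(bad, pf)
  expect_error(read_pdb(pf), "line 2")
})

test_that("the all-methyls rule tags exactly the dictionary protons", {
  fx <- make_spin_fixture("mini_complex")
  sys <- select_saturated(parse_complex(fx$protein_pdb, fx$ligand_pdb),
                          "methyls")
  sat <- sys$protons[sys$protons$group == "SATURATED_PROTEIN", ]
  # ALA 3 + VAL 6; GLY contributes none; THR HG1-type hydroxyls never count
  expect_identical(nrow(sat), 9L)
  expect_setequal(sat$atom_name[sat$residue_name == "VAL"],
                  c("HG11", "HG12", "HG13", "HG21", "HG22", "HG23"))
  expect_false("HA" %in% sat$atom_name)
})

test_that("explicit saturation lists are validated and empty lists flag the system", {
  lc <- line_complex(c(3, 6))
  sat <- lc$system$protons$group == "SATURATED_PROTEIN"
  expect_identical(sum(sat), 2L)
  expect_error(select_saturated(lc$system, c("1:HA", "99:HZ")),
               "99:HZ")
  none <- select_saturated(lc$system, character(0))
  expect_false(none$scorable)
  # all-methyls on a methyl-free protein: zero saturated, flagged
  gly <- select_saturated(lc$system, "methyls")
  expect_identical(sum(gly$protons$group == "SATURATED_PROTEIN"), 0L)
  expect_false(gly$scorable)
})

test_that("cutoff pruning keeps near protons, drops far ones, never drops ligand", {
  lc <- line_complex(c(5, 9, 11, 13))
  pruned <- apply_cutoff(lc$system, 10)
  kept <- pruned$protons
  # brute-force: protons at 5 and 9 A survive a 10 A cutoff
  expect_identical(sum(kept$group != "LIGAND"), 2L)
  expect_setequal(kept$residue_id[kept$group != "LIGAND"], c(1L, 2L))
  expect_identical(sum(kept$group == "LIGAND"),
                   sum(lc$system$protons$group == "LIGAND"))
  # 15 A proton removed at cutoff 12; infinite cutoff is the identity
  far <- line_complex(15)
  expect_identical(sum(apply_cutoff(far$system, 12)$protons$group != "LIGAND"), 0L)
  expect_identical(apply_cutoff(lc$system, Inf)$protons, lc$system$protons)
  # boundary: proton at exactly the cutoff is kept
  edge <- line_complex(10)
  expect_identical(sum(apply_cutoff(edge$system, 10)$protons$group != "LIGAND"), 1L)
})

test_that("pruning is idempotent, monotone in cutoff, and groups stay a partition", {
  fx <- make_spin_fixture("random_cloud", seed = 11, n_ligand = 2,
                          n_sat = 3, n_unsat = 3)
  sys <- fx$system
  for (cut in c(3, 5, 8, 12)) {
    once <- apply_cutoff(sys, cut)
    twice <- apply_cutoff(once, cut)
    expect_identical(once$protons, twice$protons)
  }
  cuts <- c(2, 4, 6, 9, 15)
  keys <- lapply(cuts, function(cut) {
    pr <- apply_cutoff(sys, cut)$protons
    paste0(pr$residue_id, ":", pr$atom_name)[pr$group != "LIGAND"]
  })
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(keys[[i]] %in% keys[[i + 1]]))
  }
  pr <- apply_cutoff(select_saturated(sys, "methyls"), 8)$protons
  expect_true(all(pr$group %in% c("LIGAND", "SATURATED_PROTEIN",
                                  "UNSATURATED_PROTEIN")))
})
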