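test_that("dihedral reproduces the planar cis and trans cases", {
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
  expect_error(dihedral(c(0, 1, 0), c(1, 0, 0), c(1, 0, 0), c(2, 1, 0)),
               "coincide")
})

test_that("dihedral matches the axis-rotation oracle on random quadruples", {
  set.seed(42)
  for (i in 1:50) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    # avoid near-degenerate quadruples
    if (min(dist(pts)) < 0.5) next
    d_main <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    d_orac <- oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_lt(abs(wrap180(d_main - d_orac)), 1e-9)
  }
})

test_that("dihedral is invariant under rigid transforms", {
  set.seed(7)
  pts <- matrix(rnorm(12, sd = 2), 4, 3)
  d0 <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
  for (i in 1:10) {
    ax <- rnorm(3); shift <- rnorm(3, sd = 5)
    rot <- rotate_about_axis(pts, c(0, 0, 0), ax, runif(1, 0, 360))
    rot <- sweep(rot, 2, shift, "+")
    d1 <- dihedral(rot[1, ], rot[2, ], rot[3, ], rot[4, ])
    expect_lt(abs(wrap180(d1 - d0)), 1e-9)
  }
})

test_that("wrap helpers implement circular arithmetic", {
  expect_equal(wrap180(359 - 1), -2)
  expect_equal(wrap180(c(190, -190, 180, 540)), c(-170, 170, 180, 180))
  expect_equal(torsion_distance(c(359, 10), c(1, 10)), 2)
})

test_that("place_atom inverts dihedral/bond measurements", {
  set.seed(3)
  for (t in c(0.5, 60, 181, 299.5)) {
    a <- rnorm(3); b <- a + rnorm(3); c <- b + rnorm(3)
    d <- place_atom(a, b, c, 1.52, 108.7, t)
    expect_lt(abs(wrap180(dihedral(a, b, c, d) - t)), 1e-9)
    expect_lt(abs(sqrt(sum((d - c)^2)) - 1.52), 1e-9)
    expect_lt(abs(bond_angle(b, c, d) - 108.7), 1e-9)
  }
})

test_that("suites extracted from a constructed chain recover its torsions", {
  tor <- c(81, 212, 289, 295, 174, 54, 81)
  chain <- build_suite_chain(tor, n_residues = 5, sequence = "G")
  suites <- extract_suites(chain, structure_id = "nerf")
  expect_equal(nrow(suites), 4L)
  for (i in seq_len(4))
    expect_lt(max(abs(wrap180(
      unlist(suites[i, c("d1", "e1", "z1", "a", "b", "g", "d2")]) - tor))),
      1e-6)
  expect_equal(unique(suites$sequence), "GG")
})

test_that("a written-then-read PDB yields the same suites", {
  tor <- c(81, 212, 289, 295, 174, 54, 81)
  chain <- build_suite_chain(tor, n_residues = 3, sequence = c("A", "C", "U"))
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(chain, f)
  suites <- extract_suites(f)
  expect_equal(nrow(suites), 2L)
  expect_equal(suites$sequence, c("AC", "CU"))
  # PDB coordinates are rounded to 1e-3 A; torsions match to ~0.2 deg
  for (i in 1:2)
    expect_lt(max(abs(wrap180(
      unlist(suites[i, c("d1", "e1", "z1", "a", "b", "g", "d2")]) - tor))),
      0.2)
  asg <- assign_rotamer(suites[, c("d1", "e1", "z1", "a", "b", "g", "d2")],
                        CAT)
  expect_equal(asg$rotamer_id, c("1a", "1a"))
})

test_that("the mmCIF reader agrees with the PDB path", {
  tor <- c(81, 212, 289, 295, 174, 54, 81)
  chain <- build_suite_chain(tor, n_residues = 3, sequence = "A")
  f <- tempfile(fileext = ".cif")
  hdr <- paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                 "label_atom_id", "auth_comp_id",
                                 "auth_asym_id", "auth_seq_id", "Cartn_x",
                                 "Cartn_y", "Cartn_z",
                                 "pdbx_PDB_model_num"))
  rows <- sprintf("ATOM %d %s %s %s %s %d %.4f %.4f %.4f 1",
                  seq_len(nrow(chain)), chain$element, chain$elety,
                  chain$resid, chain$chain, chain$resno,
                  chain$x, chain$y, chain$z)
  writeLines(c("data_synthetic", "loop_", hdr, rows, "#"), f)
  suites <- extract_suites(f)
  expect_equal(nrow(suites), 2L)
  expect_lt(max(abs(wrap180(
    unlist(suites[1, c("d1", "e1", "z1", "a", "b", "g", "d2")]) - tor))),
    0.02)
})

test_that("chain breaks and missing atoms suppress suites", {
  tor <- c(81, 212, 289, 295, 174, 54, 81)
  chain <- build_suite_chain(tor, n_residues = 10)
  # removing residue 6 splits the chain into 5- and 4-residue segments
  broken <- chain[chain$resno != 6, ]
  expect_equal(nrow(extract_suites(broken)), 7L)
  # a 2-residue chain missing the second P has no complete suite
  two <- build_suite_chain(tor, n_residues = 2)
  two <- two[!(two$resno == 2 & two$elety == "P"), ]
  expect_equal(nrow(suppressWarnings(extract_suites(two))), 0L)
})

test_that("assign_rotamer returns every catalog mean at distance zero", {
  M <- as.matrix(CAT[, c("d1", "e1", "z1", "a", "b", "g", "d2")])
  asg <- assign_rotamer(M, CAT)
  expect_equal(asg$rotamer_id, CAT$rotamer_id)
  expect_equal(asg$distance, rep(0, 46))
})

test_that("assign_rotamer distance follows the closed form near a mean", {
  tor <- rotamer_means(CAT, "1b") + 1
  asg <- assign_rotamer(tor, CAT)
  expect_equal(asg$rotamer_id, "1b")
  expect_equal(asg$distance, sqrt(7), tolerance = 1e-12)
  # brute force: no other rotamer is nearer
  d_all <- apply(as.matrix(CAT[, c("d1", "e1", "z1", "a", "b", "g", "d2")]),
                 1, torsion_distance, t2 = tor)
  expect_equal(CAT$rotamer_id[which.min(d_all)], "1b")
  # max-distance thresholding flags far suites
  far <- assign_rotamer(tor, CAT, max_distance = 1)
  expect_true(is.na(far$rotamer_id))
})

test_that("shift tables round-trip and drop incomplete rows", {
  tab <- data.frame(structure_id = "x", chain = "A", resno_i = 2:4,
                    C1p = c(92.1, 91.8, 90.2), C2p = c(75.3, 74.9, 76.0),
                    C3p = c(72.9, 73.3, 71.8), C4p = c(82.5, 83.0, 81.7),
                    C5p = c(65.1, 64.8, 66.0))
  f <- tempfile(fileext = ".tsv")
  write_shift_table(tab, f)
  back <- read_shift_table(f)
  expect_equal(attr(back, "n_dropped"), 0L)
  attr(back, "n_dropped") <- NULL
  expect_equal(back, tab)
  tab$C4p[2] <- NA
  write_shift_table(tab, f)
  back <- read_shift_table(f)
  expect_equal(nrow(back), 2L)
  expect_equal(attr(back, "n_dropped"), 1L)
  # header must name the five nuclei
  write_shift_table(tab[, -4], f)
  expect_error(read_shift_table(f), "C1p")
})
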