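TPL <- dn_template("AA")
COORDS0 <- as.matrix(TPL$atoms[, c("x", "y", "z")])

test_that("all 16 dinucleotide templates build with resolvable torsions", {
  tpls <- dn_templates()
  expect_equal(length(tpls), 16L)
  expect_setequal(names(tpls),
                  as.vector(outer(c("A", "C", "G", "U"),
                                  c("A", "C", "G", "U"), paste0)))
  for (tpl in tpls) {
    expect_equal(names(tpl$torsions),
                 c("d1", "e1", "z1", "a", "b", "g", "d2"))
    expect_true(all(vapply(tpl$torsions,
                           function(td) length(td$downstream) > 0,
                           logical(1))))
    # bond graph connected
    sep <- bond_separation(tpl$bonds, nrow(tpl$atoms))
    expect_true(all(is.finite(sep)))
  }
  expect_error(dn_template("AX"), "A, C, G, U")
})

test_that("set_torsion hits its target and is an identity at the current value", {
  q <- TPL$torsions$z1$atoms
  cur <- dihedral(COORDS0[q[1], ], COORDS0[q[2], ], COORDS0[q[3], ],
                  COORDS0[q[4], ])
  same <- set_torsion(COORDS0, TPL$torsions$z1, cur)
  expect_lt(max(abs(same - COORDS0)), 1e-9)
  for (target in c(10, 111.25, 340)) {
    cc <- set_torsion(COORDS0, TPL$torsions$z1, target)
    got <- dihedral(cc[q[1], ], cc[q[2], ], cc[q[3], ], cc[q[4], ])
    expect_lt(abs(wrap180(got - target)), 1e-6)
  }
})

test_that("rotations about different bonds commute in measured torsions", {
  cc <- set_torsion(COORDS0, TPL$torsions$a, 222)
  cc <- set_torsion(cc, TPL$torsions$g, 33)
  cc2 <- set_torsion(COORDS0, TPL$torsions$g, 33)
  cc2 <- set_torsion(cc2, TPL$torsions$a, 222)
  for (k in c("a", "g")) {
    q <- TPL$torsions[[k]]$atoms
    t1 <- dihedral(cc[q[1], ], cc[q[2], ], cc[q[3], ], cc[q[4], ])
    t2 <- dihedral(cc2[q[1], ], cc2[q[2], ], cc2[q[3], ], cc2[q[4], ])
    expect_lt(abs(wrap180(t1 - t2)), 1e-6)
  }
})

test_that("torsion setting preserves every bond length and bond angle", {
  ref <- measure_geometry(TPL, COORDS0)
  cc <- COORDS0
  tor <- rotamer_means(CAT, "2[")
  for (k in 1:7) cc <- set_torsion(cc, TPL$torsions[[k]], tor[k])
  new <- measure_geometry(TPL, cc)
  expect_lt(max(abs(new$lengths - ref$lengths)), 1e-6)
  expect_lt(max(abs(new$angles - ref$angles)), 1e-6)
})

test_that("clash detection honours the bond-separation exclusion", {
  # bonded and 1-3/1-2 pairs never count, however close
  cc <- matrix(c(0, 0, 0,
                 0.4, 0, 0,
                 0.8, 0, 0,
                 1.2, 0, 0), 4, 3, byrow = TRUE)
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4))
  expect_false(detect_clash(cc, bonds, rep("C", 4)))
  # a 4-bond-separated carbon pair at 0.5 A is a deep clash
  cc5 <- rbind(cc, c(0.5, 0, 0))
  bonds5 <- rbind(bonds, c(4, 5))
  expect_true(detect_clash(cc5, bonds5, rep("C", 5)))
  expect_error(detect_clash(cc5, bonds5, c(rep("C", 4), "Xx")),
               "unknown element")
  # the idealized template at the A-form pose is clash-free
  expect_false(detect_clash(COORDS0, TPL$bonds, TPL$atoms$element))
})

test_that("sampling is reproducible and respects a degenerate spread", {
  rd <- CAT[CAT$rotamer_id == "1a", ]
  s1 <- sample_rotamer(TPL, rd, 10, seed = 99)
  s2 <- sample_rotamer(TPL, rd, 10, seed = 99)
  expect_identical(s1$torsion_vectors, s2$torsion_vectors)
  expect_equal(s1$counts[["retained"]],
               s1$counts[["generated"]] - s1$counts[["clash_rejected"]])
  # spread -> 0: every retained conformer sits at the catalog means
  rd0 <- rd
  rd0[paste0("sd_", c("d1", "e1", "z1", "a", "b", "g", "d2"))] <- 1e-9
  s0 <- sample_rotamer(TPL, rd0, 5, seed = 1)
  mu <- rotamer_means(CAT, "1a")
  expect_lt(max(abs(wrap180(sweep(s0$torsion_vectors, 2, mu)))), 1e-6)
})

test_that("sampled torsions have the catalog circular means (LLN)", {
  rd <- CAT[CAT$rotamer_id == "1a", ]
  s <- sample_rotamer(TPL, rd, 200, seed = 5)
  mu <- rotamer_means(CAT, "1a")
  sdv <- rotamer_spreads(CAT, "1a")
  for (k in 1:7) {
    th <- s$torsion_vectors[, k] * pi / 180
    cmean <- atan2(mean(sin(th)), mean(cos(th))) * 180 / pi
    expect_lt(abs(wrap180(cmean - mu[k])), 3 * sdv[k] / sqrt(200) + 1e-9)
  }
})

test_that("retained conformers assign back to their generating rotamer", {
  tot <- 0L; hit <- 0L
  for (id in c("1a", "1b", "2a", "2[", "5j", "0i", "7r", "6n")) {
    s <- sample_rotamer(TPL, CAT[CAT$rotamer_id == id, ], 50, seed = 13)
    asg <- assign_rotamer(s$torsion_vectors, CAT)
    tot <- tot + nrow(s$torsion_vectors)
    hit <- hit + sum(asg$rotamer_id == id)
  }
  expect_gte(hit / tot, 0.95)
})

test_that("the attempt cap yields a flagged partial set", {
  rd <- CAT[CAT$rotamer_id == "1a", ]
  # an absurd overlap factor rejects everything
  expect_warning(
    s <- sample_rotamer(TPL, rd, 5, seed = 1, overlap_factor = 5),
    "attempt cap")
  expect_true(s$warning_partial)
  expect_equal(s$counts[["retained"]], 0L)
})
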