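test_that("compositions follow headgroup + isoprene arithmetic", {
  # UQ-2: C19H26O4 (the M+H HRMS ion is C19H27O4)
  expect_equal(molecular_formula(uq2_topology()), "C19H26O4")
  # truncations: UQ-0 = UQ-2 minus two C5H8 units
  expect_equal(molecular_formula(build_topology("UQ", 0)), "C9H10O4")
  # MK-2 = menadione C11H8O2 + geranyl C10H17 - H
  expect_equal(molecular_formula(build_topology("MK", 2)), "C21H24O2")
  expect_equal(nrow(uq2_topology()$atoms), 49)
  expect_error(build_topology("PQ", 2))
  expect_error(build_topology("UQ", -1))
})

test_that("every labelled proton group is present and non-empty", {
  top <- uq2_topology()
  expect_setequal(names(top$proton_groups),
                  c("H_W", "H_J", "H_K", "H_MN", "H_B", "H_X", "H_QR",
                    "H_A", "H_Y", "H_Z"))
  expect_true(all(lengths(top$proton_groups) > 0))
  expect_length(top$proton_groups$H_QR, 4L)   # internal CH2-CH2
  mk <- build_topology("MK", 2)
  expect_true("H_aro" %in% names(mk$proton_groups))
  expect_false("H_J" %in% names(mk$proton_groups))
})

test_that("embedding preserves ideal bond lengths and angles", {
  for (top in list(uq2_topology(), build_topology("MK", 1))) {
    set.seed(2)
    tv <- top$torsions + runif(length(top$torsions), -180, 180)
    conf <- embed_conformer(top, tv)
    X <- conf$coords
    z <- top$zmat
    for (i in which(z$ref1 > 0)) {
      expect_equal(sqrt(sum((X[i, ] - X[z$ref1[i], ])^2)), z$r[i],
                   tolerance = 1e-6)
      if (z$ref2[i] > 0)
        expect_equal(bond_angle(X[i, ], X[z$ref1[i], ], X[z$ref2[i], ]),
                     z$theta[i], tolerance = 1e-6)
    }
    # ring closure bonds (not placed by the builder chain) are exact too
    closures <- if (top$headgroup == "UQ") list(c("C6", "C1")) else
      list(c("C8a", "C1"), c("C8", "C8a"))
    for (cl in closures)
      expect_equal(sqrt(sum((X[cl[1L], ] - X[cl[2L], ])^2)), 1.40,
                   tolerance = 1e-6)
  }
})

test_that("torsion assignment and measurement round-trip on a 15 degree grid", {
  top <- uq2_topology()
  for (nm in names(top$torsions)) {
    for (ang in seq(-165, 180, by = 15)) {
      conf <- embed_conformer(top, setNames(ang, nm))
      expect_equal(measure_torsion(conf, nm), ang, tolerance = 1e-6)
    }
  }
  expect_equal(measure_phi(embed_conformer(top, c(phi = 93))), 93,
               tolerance = 1e-6)
})

test_that("identical torsions embed to identical coordinates", {
  top <- uq2_topology()
  tv <- c(phi = 77, chi_1 = -33, tauA_1 = 140, tauB_1 = 65, chi_2 = -120)
  a <- embed_conformer(top, tv)
  b <- embed_conformer(top, tv)
  expect_identical(a$coords, b$coords)
  expect_lt(superpose(a, b)$rmsd, 1e-12)
})

test_that("the all-anti chain maximizes the head-to-tail distance", {
  top <- uq2_topology()
  ee <- function(tors) {
    X <- embed_conformer(top, tors)$coords
    sqrt(sum((X["C1", ] - X["S2_4", ])^2))   # carbonyl C to terminal methyl C
  }
  anti <- c(phi = 180, chi_1 = 180, tauA_1 = 180, tauB_1 = 180, chi_2 = 180)
  e0 <- ee(anti)
  # 10-degree scan of each backbone torsion with the others anti
  for (nm in names(anti)) {
    vals <- vapply(seq(-180, 170, by = 10), function(a) {
      tt <- anti; tt[nm] <- a; ee(tt)
    }, 0)
    expect_lte(max(vals), e0 + 1e-9)
  }
})

test_that("unknown torsions and groups are rejected", {
  top <- uq2_topology()
  expect_error(embed_conformer(top, c(bogus = 10)), "unknown torsion")
  conf <- embed_conformer(top)
  expect_error(group_distance(conf, "H_W", "H_nope"), "unknown proton group")
  expect_error(group_distance(conf, "H_W", "H_W"), "overlap")
})
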