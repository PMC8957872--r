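test_that("group distances reduce to Euclidean distance for single protons", {
  top <- uq2_topology()
  conf <- reference_conformer("U-shaped", top)
  # singleton groups given as raw atom labels: plain Euclidean distance
  d_raw <- sqrt(sum((conf$coords["HA", ] - conf$coords["HB", ])^2))
  expect_equal(group_distance(conf, "H_A", "H_B", mode = "mean"), d_raw)
  expect_equal(group_distance(conf, "H_A", "H_B", mode = "r6"), d_raw)
  # symmetry
  expect_equal(group_distance(conf, "H_W", "H_Y"),
               group_distance(conf, "H_Y", "H_W"))
})

test_that("r6-averaged distances never exceed mean distances", {
  top <- uq2_topology()
  set.seed(11)
  for (k in 1:5) {
    tv <- top$torsions + runif(length(top$torsions), -180, 180)
    conf <- embed_conformer(top, tv)
    pr <- all_group_pairs(top)
    for (i in seq_len(nrow(pr))) {
      expect_lte(group_distance(conf, pr[i, 1], pr[i, 2], mode = "r6"),
                 group_distance(conf, pr[i, 1], pr[i, 2], mode = "mean") +
                   1e-12)
    }
  }
})

test_that("conformation taxonomy follows the phi window and terminal rule", {
  top <- uq2_topology()
  # phi = 180, chain anti: flat-extended
  flat <- reference_conformer("flat-extended", top)
  expect_equal(classify_conformation(flat)$label, "flat-extended")
  # phi = 90, chain anti: folded but terminal methyls far away
  fold <- embed_conformer(top, c(phi = 90, chi_1 = 180, tauA_1 = 180,
                                 tauB_1 = 180, chi_2 = 180))
  cls <- classify_conformation(fold)
  expect_equal(cls$label, "folded-extended")
  expect_gt(min(cls$terminal_distances), 6)
  # phi = 90 with terminal methyls pulled back over the ring: U-shaped
  ush <- reference_conformer("U-shaped", top)
  cls_u <- classify_conformation(ush)
  expect_equal(cls_u$label, "U-shaped")
  expect_lte(min(cls_u$terminal_distances), 6)
  # just inside / outside the folded window
  expect_equal(classify_conformation(
    embed_conformer(top, c(phi = 60.5, chi_1 = 180, tauA_1 = 180,
                           tauB_1 = 180, chi_2 = 180)))$label,
    "folded-extended")
  expect_equal(classify_conformation(
    embed_conformer(top, c(phi = 59, chi_1 = 180, tauA_1 = 180,
                           tauB_1 = 180, chi_2 = 180)))$label,
    "flat-extended")
})

test_that("classification depends only on phi and the terminal distances", {
  top <- uq2_topology()
  base <- lipofold:::reference_torsions("U-shaped")
  ref <- classify_conformation(embed_conformer(top, base))
  # methoxy and remote methyl rotors do not touch phi or the terminal
  # methyl positions relative to H_W's carbon: the label cannot change
  for (rot in list(c(ome_K = 31), c(ome_J = -120), c(me_X = 45),
                   c(me_K = 90, ome_K = -140))) {
    cls <- classify_conformation(embed_conformer(top, c(base, rot)))
    expect_equal(cls$label, ref$label)
    expect_equal(cls$phi, ref$phi, tolerance = 1e-9)
  }
})

test_that("rotor-ensemble averaging reproduces fixed-state averages", {
  top <- uq2_topology()
  # scanning one torsion that does not move the pair leaves the mean at the
  # static value
  d_stat <- group_distance(reference_conformer("flat-extended", top),
                           "H_A", "H_B")
  d_ens <- ensemble_group_distance(
    top, "H_A", "H_B", vary = "me_W",
    torsions = lipofold:::reference_torsions("flat-extended"))
  expect_equal(d_ens, d_stat, tolerance = 1e-9)
})
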