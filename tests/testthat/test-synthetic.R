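test_that("simulated volumes follow the scaled r^-6 law", {
  top <- uq2_topology()
  conf <- reference_conformer("U-shaped", top)
  pt <- simulate_peak_table(conf, cv = 0)
  tr <- attr(pt, "truth")
  dref <- attr(pt, "reference_distance")
  # reference pair emits volume exactly 1 before noise
  iref <- pt$group_a == "H_MN" | pt$group_b == "H_MN"
  iref <- which((pt$group_a == "H_W" & pt$group_b == "H_MN") |
                  (pt$group_a == "H_MN" & pt$group_b == "H_W"))
  expect_equal(pt$volume[iref], 1)
  # a pair placed exactly at the reference distance would also give 1:
  # volumes scale as (dref/d)^6
  expect_equal(pt$volume, (dref / tr$distance[tr$detected])^6)
})

test_that("pairs beyond the detection limit are suppressed, and pair
           count is conserved", {
  top <- uq2_topology()
  conf <- reference_conformer("flat-extended", top)
  pt <- simulate_peak_table(conf, cv = 0, detection_limit = 5)
  tr <- attr(pt, "truth")
  expect_equal(nrow(pt) + sum(!tr$detected), nrow(all_group_pairs(top)))
  expect_true(all(tr$distance[tr$detected] <= 5))
  expect_true(all(tr$distance[!tr$detected] > 5))
  # H_W-H_Y sits far beyond 5 A in the flat-extended conformer
  expect_false(any(pt$group_a == "H_W" & pt$group_b == "H_Y"))
  # an out-of-range reference pair is an error
  expect_error(simulate_peak_table(conf, cv = 0, detection_limit = 2),
               "beyond the detection limit")
})

test_that("zero-noise volumes recalibrate to the true distances to 1e-9", {
  top <- uq2_topology()
  for (lab in c("U-shaped", "flat-extended")) {
    conf <- reference_conformer(lab, top)
    pt <- simulate_peak_table(conf, cv = 0)
    tr <- attr(pt, "truth")
    r <- ispa_distance(pt$volume, attr(pt, "reference_distance"))
    expect_lt(max(abs(r - tr$distance[tr$detected])), 1e-9)
  }
})

test_that("peak-table noise is seeded, multiplicative and mean-one", {
  top <- uq2_topology()
  conf <- reference_conformer("U-shaped", top)
  a <- simulate_peak_table(conf, cv = 0.2, seed = 42)
  b <- simulate_peak_table(conf, cv = 0.2, seed = 42)
  expect_identical(a$volume, b$volume)
  c2 <- simulate_peak_table(conf, cv = 0.2, seed = 43)
  expect_false(identical(a$volume, c2$volume))
  expect_error(simulate_peak_table(conf, cv = 0.2), "seed")
  # mean-one noise: average ratio to truth over many seeds is close to 1
  v0 <- simulate_peak_table(conf, cv = 0)$volume
  rel <- rowMeans(vapply(1:200, function(s)
    simulate_peak_table(conf, cv = 0.2, seed = s)$volume / v0,
    numeric(length(v0))))
  expect_equal(mean(rel), 1, tolerance = 0.02)
})

test_that("isotherm replicates are exact copies at zero scatter and their
           mean tracks the knot interpolation under noise", {
  m0 <- uq2_phase_model(scatter_sd = 0)
  iso <- simulate_isotherm(m0, n_replicates = 3, seed = 1)
  expect_equal(iso[[1]]$area, iso[[2]]$area)
  expect_equal(iso[[2]]$area, iso[[3]]$area)
  # plateau at the collapse pressure appears in every replicate
  expect_true(all(vapply(iso, function(cv)
    sum(abs(cv$pressure - 21) < 1e-9) > 1, TRUE)))
  # sampling-theory check at one grid point over 100 seeds
  m <- uq2_phase_model(scatter_sd = 1)
  k <- 57
  truth <- iso[[1]]$area[k]
  draws <- unlist(lapply(1:100, function(s) {
    r <- simulate_isotherm(m, n_replicates = 1, seed = s)
    r[[1]]$area[k]
  }))
  se <- 1 / sqrt(100)
  expect_lt(abs(mean(draws) - truth), 3 * se)
})

test_that("phase-model validation enforces monotone compression", {
  expect_error(isotherm_phase_model(c(100, 50), c(10, 5)),
               "non-decreasing")
  expect_error(isotherm_phase_model(c(50, 100), c(5, 10)),
               "strictly decreasing")
  expect_error(isotherm_phase_model(c(100, 50), c(0, 10),
                                    collapse_pressure = 21), "plateau")
})

test_that("permuting replicate seeds leaves the pooled isotherm mean alone", {
  m <- uq2_phase_model(scatter_sd = 0.5)
  pool <- function(seeds) {
    rowMeans(vapply(seeds, function(s)
      simulate_isotherm(m, n_replicates = 1, seed = s)[[1]]$area,
      numeric(200)))
  }
  expect_equal(pool(c(1, 2, 3)), pool(c(3, 1, 2)), tolerance = 1e-12)
})

test_that("shift-table generation closes the loop with localization", {
  for (loc in c("interface", "aqueous", "organic")) {
    tab <- simulate_shift_table(loc, seed = 1, jitter_sd = 0)
    expect_equal(localize(tab)$location, loc)
  }
})
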