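test_that("surface pressure is the tension deficit", {
  expect_equal(surface_pressure(72.8, 72.8), 0)
  expect_equal(surface_pressure(72.8, 42.8), 30.0)
  expect_warning(p <- surface_pressure(72.8, 73.8), "negative")
  expect_equal(p, -1.0)
})

test_that("area normalization divides by the phospholipid mole fraction", {
  expect_equal(normalize_area(50, 1.0), 50)
  expect_equal(normalize_area(50, 0.5), 100)
  expect_equal(normalize_area(50, 0.25), 200)
  expect_error(normalize_area(50, 0))
  expect_error(normalize_area(50, 1.2))
  # scale equivariance
  a <- c(80, 60, 40)
  expect_equal(normalize_area(3 * a, 0.5), 3 * normalize_area(a, 0.5))
})

test_that("replicate averaging reports SD at the 5 mN/m checkpoints", {
  base <- linear_isotherm()
  m1 <- average_replicates(list(base, base, base))
  expect_true(all(m1$sd_checkpoints$sd_area == 0))
  expect_equal(m1$sd_checkpoints$pressure,
               seq(0, 40, by = 5))
  # two replicates offset by +/-1 A^2: two-point sample SD is sqrt(2)
  up <- base; up$area <- base$area + 1
  dn <- base; dn$area <- base$area - 1
  m2 <- average_replicates(list(up, dn))
  expect_equal(m2$sd_checkpoints$sd_area,
               rep(sqrt(2), nrow(m2$sd_checkpoints)))
  expect_equal(m2$curve$area,
               approx(base$pressure, base$area, m2$curve$pressure)$y,
               tolerance = 1e-9)
  # single replicate: SD absent
  m3 <- average_replicates(list(base))
  expect_true(all(is.na(m3$sd_checkpoints$sd_area)))
  # disjoint supports are an error
  hi <- isotherm_curve(area = c(50, 40), pressure = c(60, 70))
  expect_error(average_replicates(list(base, hi)), "disjoint")
})

test_that("simulated replicate means stay within sampling error of the
           phase model", {
  m <- uq2_phase_model(scatter_sd = 0.8)
  truth <- average_replicates(simulate_isotherm(uq2_phase_model(), 1,
                                                seed = 1))
  areas <- vapply(1:100, function(s) {
    av <- average_replicates(simulate_isotherm(m, 1, seed = s))
    approx(av$curve$pressure, av$curve$area, xout = 15)$y
  }, 0)
  t0 <- approx(truth$curve$pressure, truth$curve$area, xout = 15)$y
  expect_lt(abs(mean(areas) - t0), 3 * 0.8 / sqrt(100))
})

test_that("compression modulus matches closed forms", {
  # linear isotherm pi = a - b A  ->  Cs^-1 = b A
  cv <- linear_isotherm(a = 100, b = 1.5)
  mod <- compression_modulus(cv)
  keep <- mod$pressure > 2 & mod$pressure < 38   # away from filter edges
  # A(pi) = a - b pi means pi = a/b - A/b, so Cs^-1 = A/b
  expect_equal(mod$modulus[keep], (100 - 1.5 * mod$pressure[keep]) / 1.5,
               tolerance = 1e-6, ignore_attr = TRUE)
  # ideal 2D gas pi A = const  ->  Cs^-1 = pi
  p <- seq(5, 40, length.out = 300)
  gas <- isotherm_curve(area = 2000 / p, pressure = p)
  mg <- compression_modulus(gas)
  kg <- mg$pressure > 7 & mg$pressure < 38
  expect_equal(mg$modulus[kg], mg$pressure[kg], tolerance = 1e-2,
               ignore_attr = TRUE)
  expect_error(compression_modulus(isotherm_curve(area = c(2, 1),
                                                  pressure = c(1, 2))))
})

test_that("modulus stays positive on monotone synthetic compressions and
           drops when a softer component is mixed in", {
  stiff <- average_replicates(simulate_isotherm(dppc_phase_model(), 1,
                                                seed = 1))
  mstiff <- compression_modulus(stiff)
  keep <- is.finite(mstiff$modulus) & mstiff$pressure > 1 &
    mstiff$pressure < 68
  expect_true(all(mstiff$modulus[keep] > -1e-6))
  # softer mixed film: shallower slope everywhere
  soft <- isotherm_phase_model(area = c(120, 100, 80, 60, 40),
                               pressure = c(0, 5, 15, 30, 50))
  msoft <- compression_modulus(
    average_replicates(simulate_isotherm(soft, 1, seed = 1)))
  expect_lt(max(msoft$modulus[is.finite(msoft$modulus)], na.rm = TRUE),
            max(mstiff$modulus[keep]))
})

test_that("collapse detection finds the plateau and ignores straight lines", {
  iso <- simulate_isotherm(uq2_phase_model(), 3, seed = 5)
  cp <- collapse_pressure(average_replicates(iso))
  expect_true(cp$detected)
  expect_lte(abs(cp$collapse_pressure - 21), cp$grid_step + 1e-9)
  # straight line: no pronounced interior curvature minimum
  expect_false(collapse_pressure(linear_isotherm())$detected)
  # invariance under uniform area rescaling (within threshold range)
  for (k in c(0.5, 2)) {
    sc <- average_replicates(iso)$curve
    sc$area <- sc$area * k
    cpk <- collapse_pressure(sc)
    expect_equal(cpk$collapse_pressure, cp$collapse_pressure,
                 tolerance = cp$grid_step + 1e-9)
  }
})

test_that("area expansion measures the normalized offset over the window", {
  pure <- linear_isotherm(a = 100, b = 1.5)
  # mixed curve identical after normalization: 0 %
  mixed0 <- linear_isotherm(a = 100 * 0.5, b = 1.5 * 0.5, x = 0.5)
  expect_equal(area_expansion(mixed0, pure), 0, tolerance = 1e-9)
  # normalized mixed = 1.09 x pure: 9 %
  mixed9 <- linear_isotherm(a = 100 * 0.5 * 1.09, b = 1.5 * 0.5 * 1.09,
                            x = 0.5)
  expect_equal(area_expansion(mixed9, pure), 9, tolerance = 1e-6)
  # 12 % built-in expansion recovered
  mixed12 <- linear_isotherm(a = 100 * 0.25 * 1.12, b = 1.5 * 0.25 * 1.12,
                             x = 0.25)
  expect_equal(area_expansion(mixed12, pure), 12, tolerance = 0.1)
  expect_error(area_expansion(linear_isotherm(pmax = 20), pure),
               "window")
})

test_that("band overlap verdicts follow 1-SD disjointness at checkpoints", {
  reps <- function(offset, x = 1, jitter = 0.5) {
    lapply(c(-1, 0, 1), function(j) {
      cv <- linear_isotherm(a = 100 + offset, x = x)
      cv$area <- cv$area + j * jitter
      cv
    })
  }
  pure <- average_replicates(reps(0))
  same <- average_replicates(reps(0))
  expect_equal(overlap_flag(same, pure), "overlapping", ignore_attr = TRUE)
  apart <- average_replicates(reps(10))
  expect_equal(overlap_flag(apart, pure), "separated", ignore_attr = TRUE)
  # bands exactly touching at the checkpoints (offset = 2 x SD): overlapping
  touch <- average_replicates(reps(1.0))
  expect_equal(overlap_flag(touch, pure, window = c(30, 35)),
               "overlapping", ignore_attr = TRUE)
})
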