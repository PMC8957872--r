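test_that("volume standardization is a plain ratio with the reference at 1", {
  pk <- tiny_peak_table()
  norm <- normalize_volumes(pk)
  expect_identical(norm$v_norm[1], 1)
  expect_equal(norm$v_norm, c(1, 2, 0.25))
  expect_equal(norm$intensity_class, c("medium", "strong", "weak"))
  # input order preserved
  expect_identical(norm$group_b, pk$group_b)
})

test_that("standardization errors are explicit", {
  pk <- tiny_peak_table()
  expect_error(normalize_volumes(pk, c("H_W", "H_Q")), "H_W-H_Q")
  pk2 <- pk; pk2$volume[2] <- -1
  expect_error(normalize_volumes(pk2), "row\\(s\\): 2")
  pk3 <- pk; pk3$group_b[3] <- "H_W"
  expect_error(normalize_volumes(pk3), "diagonal")
})

test_that("normalization is idempotent", {
  norm <- normalize_volumes(tiny_peak_table())
  again <- norm
  again$volume <- norm$v_norm
  norm2 <- normalize_volumes(again)
  expect_equal(norm2$v_norm, norm$v_norm)
  expect_equal(norm2$intensity_class, norm$intensity_class)
})

test_that("intensity classes and bins match the calibration table", {
  # class thresholds: strong > 1.5, medium 0.6-1.5 closed, weak < 0.6
  cases <- list(list(1.6, "strong"), list(1.51, "strong"),
                list(1.5, "medium"), list(0.6, "medium"),
                list(1.0, "medium"), list(0.59, "weak"), list(0, "weak"))
  for (cs in cases) expect_equal(classify_intensity(cs[[1]]), cs[[2]])
  expect_error(classify_intensity(-0.1))
  # bins: strong < 3 A (floored at vdW contact), medium 3-4, weak > 4
  expect_equal(class_to_bounds("strong"), c(1.8, 3.0))
  expect_equal(class_to_bounds("medium"), c(3.0, 4.0))
  expect_equal(class_to_bounds("weak"), c(4.0, 5.0))
  cfg <- noe_config(weak_upper = Inf)
  expect_equal(class_to_bounds("weak", cfg), c(4.0, Inf))
})

test_that("classification is monotone in normalized volume", {
  ord <- c(weak = 1, medium = 2, strong = 3)
  v <- sort(c(seq(0, 3, by = 0.05), 0.6, 1.5))
  cl <- ord[vapply(v, classify_intensity, "")]
  expect_true(all(diff(cl) >= 0))
})

test_that("ispa distance inverts the sixth-power law", {
  expect_equal(ispa_distance(1, 3.5), 3.5)
  expect_equal(ispa_distance(64, 3.5), 1.75)
  expect_equal(ispa_distance(2^-6, 3.5), 7.0)
  expect_error(ispa_distance(0))
  expect_error(ispa_distance(1, -3.5))
})

test_that("binned bounds contain the continuous ISPA distance except in the
           two known bin/r6 disagreement zones", {
  cfg <- noe_config()
  # volume values whose ISPA distance lies in (contact_floor, 4]
  v <- exp(seq(log((cfg$r_ref / 1.8)^6), log((cfg$r_ref / 4.0)^6),
               length.out = 400))
  zone_strong <- c(3.0, cfg$r_ref * cfg$strong_threshold^(-1 / 6))  # 3-3.27
  zone_weak <- c(cfg$r_ref * cfg$weak_threshold^(-1 / 6), 4.0)      # 3.81-4
  for (vi in v) {
    r <- ispa_distance(vi, cfg$r_ref)
    b <- class_to_bounds(classify_intensity(vi, cfg), cfg)
    inside <- r >= b[1] - 1e-9 && r <= b[2] + 1e-9
    in_zone <- (r > zone_strong[1] + 1e-9 && r <= zone_strong[2] + 1e-9) ||
      (r > zone_weak[1] - 1e-9 && r <= zone_weak[2] + 1e-9)
    expect_true(inside || in_zone)
  }
})

test_that("restraint assembly excludes the reference and flagged peaks", {
  norm <- normalize_volumes(tiny_peak_table())
  rs <- restraints_from_table(norm)
  expect_equal(nrow(rs$restraints), 2L)        # reference is the calibrator
  expect_false("H_MN" %in% c(rs$restraints$group_a, rs$restraints$group_b))
  # a solvent-overlap peak yields an exclusion record, not a restraint
  pk <- tiny_peak_table()
  pk$overlap_flag[3] <- TRUE
  rs2 <- restraints_from_table(normalize_volumes(pk))
  expect_equal(nrow(rs2$restraints), 1L)
  expect_equal(nrow(rs2$excluded), 1L)
  expect_equal(rs2$excluded$group_b, "H_Y")
})

test_that("duplicate NOESY/ROESY observations merge to the narrower bound", {
  pk <- rbind(tiny_peak_table(),
              data.frame(group_a = "H_X", group_b = "H_W", volume = 2.4e5,
                         spectrum = "ROESY", environment = "d6-DMSO",
                         overlap_flag = FALSE))
  expect_warning(rs <- restraints_from_table(normalize_volumes(pk)),
                 "conflicting")
  row <- rs$restraints[rs$restraints$group_b == "H_X" |
                         rs$restraints$group_a == "H_X", ]
  expect_true(row$conflict)
  expect_equal(c(row$lower, row$upper), c(1.8, 4.0))
  # compatible duplicates (same class) keep the bin
  pk$volume[4] <- 4.8e5
  rs2 <- suppressWarnings(restraints_from_table(normalize_volumes(pk)))
  row2 <- rs2$restraints[rs2$restraints$group_a == "H_W" &
                           rs2$restraints$group_b == "H_X", ]
  expect_false(row2$conflict)
  expect_equal(c(row2$lower, row2$upper), c(1.8, 3.0))
  expect_match(row2$source, "NOESY\\+ROESY")
})

test_that("monitored-but-absent pairs become lower-bound restraints", {
  norm <- normalize_volumes(tiny_peak_table())
  rs <- restraints_from_table(
    norm, expected_pairs = rbind(c("H_W", "H_A"), c("H_W", "H_X")))
  ab <- rs$restraints[rs$restraints$class == "absent", ]
  expect_equal(nrow(ab), 1L)                    # H_W-H_X was observed
  expect_equal(c(ab$group_a, ab$group_b), c("H_A", "H_W"))  # canonical order
  expect_equal(ab$lower, 5.0)
  expect_true(is.infinite(ab$upper))
})
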