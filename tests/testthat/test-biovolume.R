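# biovolume quantification: sphere volumes, concentration scaling,
# replicate summaries, full-sample quantification

test_that("sphere_volume follows (pi/6) d^3 and rejects negative diameters", {
  expect_equal(sphere_volume(0), 0)
  expect_equal(sphere_volume(0.45), pi / 6 * 0.45^3)
  expect_equal(sphere_volume(0.45), 0.0477, tolerance = 1e-3)
  expect_equal(sphere_volume(10), 523.5988, tolerance = 1e-6)
  # strictly increasing in diameter
  d <- seq(0, 20, by = 0.25)
  expect_true(all(diff(sphere_volume(d)) > 0))
  expect_error(sphere_volume(-1), class = "invalid_input")
})

test_that("counts_to_concentration applies the geometry scale per replicate", {
  g_unit <- unit_geometry()
  expect_equal(unname(counts_to_concentration(c(5, 5), geometry = g_unit)), 5)
  # mean 3/field, area ratio 100, 0.5 ml, dilution 2000 -> 1.2e6/ml
  g <- microscope_geometry(dilution_factor = 2000, filtered_volume_ml = 0.5,
                           filter_effective_area_um2 = 100,
                           field_area_um2 = 1)
  expect_equal(unname(counts_to_concentration(c(2, 3, 4), geometry = g)),
               1.2e6)
  expect_equal(unname(counts_to_concentration(rep(0, 10), geometry = g)), 0)
  # per-replicate values are independent
  out <- counts_to_concentration(c(1, 3, 5, 7), replicate = c(1, 1, 2, 2),
                                 geometry = g_unit)
  expect_equal(unname(out), c(2, 6))
  expect_error(counts_to_concentration(numeric(0), geometry = g_unit),
               class = "invalid_input")
  expect_error(microscope_geometry(filtered_volume_ml = 0),
               class = "invalid_geometry")
  expect_error(microscope_geometry(field_area_um2 = 0),
               class = "invalid_geometry")
})

test_that("replicate_summary gives mean and n-1 SE, flagging single replicates", {
  expect_equal(replicate_summary(c(2, 2, 2, 2)), c(mean = 2, se = 0))
  out <- replicate_summary(c(1, 2, 3, 4))
  expect_equal(out[["mean"]], 2.5)
  expect_equal(out[["se"]], sqrt(5 / 3) / 2, tolerance = 1e-12)
  expect_equal(out[["se"]], 0.6455, tolerance = 1e-4)
  single <- replicate_summary(7)
  expect_equal(single[["mean"]], 7)
  expect_true(is.na(single[["se"]]))
  expect_error(replicate_summary(numeric(0)), class = "invalid_input")
})

test_that("quantify_sample matches a hand-computed enumeration on a tiny design", {
  # 2 replicates x 3 fields, classes 4 and 10 um, with single cells
  single <- rbind(c(2, 3, 1), c(4, 0, 2))
  c4 <- rbind(c(1, 0, 2), c(0, 1, 1))
  c10 <- rbind(c(0, 1, 0), c(1, 0, 0))
  tab <- make_counts(single = single, classes = list("4" = c4, "10" = c10))
  g <- microscope_geometry(dilution_factor = 10, filtered_volume_ml = 2,
                           filter_effective_area_um2 = 50, field_area_um2 = 5)
  sf <- (50 / 5) / 2 * 10   # = 50
  bv <- quantify_sample(tab, g, diameter_classes = c(4, 10))

  # brute-force oracle: per replicate, mean count/field * sf; volumes by
  # direct arithmetic
  conc4 <- rowMeans(c4) * sf
  conc10 <- rowMeans(c10) * sf
  concs <- rowMeans(single) * sf
  v4 <- pi / 6 * 64; v10 <- pi / 6 * 1000; vs <- pi / 6 * 0.45^3
  tot <- concs * vs + conc4 * v4 + conc10 * v10
  expect_equal(bv$per_class$concentration, c(mean(conc4), mean(conc10)))
  expect_equal(bv$total_biovolume[["mean"]], mean(tot))
  expect_equal(bv$total_biovolume[["se"]], stats::sd(tot) / sqrt(2))
  expect_equal(bv$single_cell$concentration[["mean"]], mean(concs))
  expect_equal(bv$aggregate_share[["mean"]],
               mean((conc4 * v4 + conc10 * v10) / tot))
})

test_that("quantify_sample handles degenerate inputs per the conventions", {
  # a single 10-um class at known concentration, no cells
  g <- unit_geometry()
  tab <- make_counts(classes = list("10" = rbind(c(1e5, 1e5))))
  bv <- quantify_sample(tab, g, diameter_classes = c(5, 10))
  expect_equal(bv$per_class$biovolume[2], 1e5 * sphere_volume(10))
  expect_equal(bv$per_class$biovolume[2], 5.236e7, tolerance = 1e-3)
  expect_equal(bv$aggregate_share[["mean"]], 1)
  # absent classes count as zero
  expect_equal(bv$per_class$biovolume[1], 0)
  # all-zero counts: total 0, share 0 by convention (with a warning)
  zero <- make_counts(single = rbind(c(0, 0), c(0, 0)))
  expect_warning(bv0 <- quantify_sample(zero, g), "zero total biovolume")
  expect_equal(bv0$total_biovolume[["mean"]], 0)
  expect_equal(bv0$aggregate_share[["mean"]], 0)
  # unknown diameter class is a schema error
  bad <- make_counts(classes = list("30" = rbind(1)))
  expect_error(quantify_sample(bad, g), class = "schema_error")
  # duplicate key rows are rejected with a row number
  dup <- rbind(zero, zero[1, ])
  expect_error(quantify_sample(dup, g), "duplicate",
               class = "validation_error")
})

test_that("concentrations and biovolumes are linear in the dilution factor", {
  tab <- make_counts(single = rbind(c(3, 1), c(2, 2)),
                     classes = list("6" = rbind(c(1, 2), c(0, 1))))
  g1 <- microscope_geometry(dilution_factor = 100, filtered_volume_ml = 2,
                            filter_effective_area_um2 = 1e4,
                            field_area_um2 = 10)
  g2 <- microscope_geometry(dilution_factor = 200, filtered_volume_ml = 2,
                            filter_effective_area_um2 = 1e4,
                            field_area_um2 = 10)
  b1 <- quantify_sample(tab, g1)
  b2 <- quantify_sample(tab, g2)
  expect_equal(2 * b1$per_class$concentration, b2$per_class$concentration)
  expect_equal(2 * b1$total_biovolume[["mean"]], b2$total_biovolume[["mean"]])
  expect_equal(2 * b1$total_biovolume[["se"]], b2$total_biovolume[["se"]])
  # shares are geometry-invariant
  expect_equal(b1$aggregate_share, b2$aggregate_share)
})

test_that("total biovolume conserves the single-cell plus per-class sum", {
  set.seed(11)
  for (i in 1:5) {
    tr <- reference_truth(if (i %% 2) "S1" else "S2", seed = i)
    tab <- simulate_counts(tr, n_fields = 20)
    bv <- quantify_sample(tab, tr$geometry)
    expect_equal(bv$total_biovolume[["mean"]],
                 bv$single_cell$biovolume[["mean"]] +
                   sum(bv$per_class$biovolume),
                 tolerance = 1e-9)
  }
})
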