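# CARD-FISH composition: probe fractions, detection bounds, composition
# assembly

test_that("probe_fraction recovers simple ratios and block summaries", {
  # saturation: every DAPI object probe-positive
  sat <- make_probes(replicate_id = 1, field_id = 1:5,
                     object_type = "aggregate", diameter_class_um = 3,
                     probe_count = c(2, 1, 4, 0, 3),
                     dapi_count = c(2, 1, 4, 0, 3))
  f <- probe_fraction(sat, "aggregates")
  expect_equal(f[["mean"]], 1)
  # 37 positives of 100 DAPI in one block: 0.37, SE flagged NA
  one <- make_probes(replicate_id = 1, field_id = 1:4,
                     object_type = "aggregate", diameter_class_um = 5,
                     probe_count = c(9, 9, 10, 9), dapi_count = rep(25, 4))
  f1 <- probe_fraction(one, "aggregates")
  expect_equal(f1[["mean"]], 0.37)
  expect_true(is.na(f1[["se"]]))
  # four replicate blocks with fractions 0.30/0.35/0.40/0.43
  blocks <- make_probes(replicate_id = 1:4, field_id = 1,
                        object_type = "aggregate", diameter_class_um = 5,
                        probe_count = c(30, 35, 40, 43),
                        dapi_count = rep(100, 4))
  fb <- probe_fraction(blocks, "aggregates")
  expect_equal(fb[["mean"]], 0.37)
  expect_equal(fb[["se"]], 0.0286, tolerance = 1e-3)
})

test_that("probe_fraction validates pairing and degenerate inputs", {
  bad <- make_probes(replicate_id = 1, field_id = 1,
                     object_type = "aggregate", diameter_class_um = 5,
                     probe_count = 3, dapi_count = 2)
  expect_error(probe_fraction(bad, "aggregates"),
               class = "data_integrity_error")
  zero <- make_probes(replicate_id = 1:2, field_id = 1,
                      object_type = "aggregate", diameter_class_um = 5,
                      probe_count = 0, dapi_count = 0)
  expect_error(probe_fraction(zero, "aggregates"),
               class = "undefined_fraction")
})

test_that("biovolume fractions weight objects by their class sphere volume", {
  # 2-um aggregates all positive, 10-um all negative: biovolume fraction is
  # the 2-um share of volume, not of counts
  tab <- rbind(
    make_probes(replicate_id = 1, field_id = 1:2, object_type = "aggregate",
                diameter_class_um = 2, probe_count = 4, dapi_count = 4),
    make_probes(replicate_id = 1, field_id = 1:2, object_type = "aggregate",
                diameter_class_um = 10, probe_count = 0, dapi_count = 1))
  f <- probe_fraction(tab, "biovolume")
  v2 <- sphere_volume(2); v10 <- sphere_volume(10)
  expect_equal(f[["mean"]], 8 * v2 / (8 * v2 + 2 * v10))
  # count-based aggregate fraction differs
  expect_equal(probe_fraction(tab, "aggregates")[["mean"]], 8 / 10)
})

test_that("fractions are invariant to the microscope geometry", {
  tr <- reference_truth("S1", seed = 3)
  dapi <- simulate_counts(tr, seed = 4)
  probes <- simulate_probe_counts(tr, dapi, probes = "EelMS932", seed = 5)
  g_other <- microscope_geometry(dilution_factor = 77,
                                 filtered_volume_ml = 0.3,
                                 filter_effective_area_um2 = 5e7,
                                 field_area_um2 = 2e4)
  f1 <- fish_composition(probes, tr$geometry)
  f2 <- fish_composition(probes, g_other)
  expect_equal(f1$mean, f2$mean)
  expect_equal(f1$se, f2$se)
  # but detection bounds do scale with geometry
  expect_false(isTRUE(all.equal(
    detection_bound(tr$geometry, 200), detection_bound(g_other, 200))))
})

test_that("detection_bound reports the concentration of one (or 3) objects", {
  g_unit <- unit_geometry()
  expect_equal(detection_bound(g_unit, n_fields = 50), 1 / 50)
  expect_equal(detection_bound(g_unit, n_fields = 50,
                               criterion = "poisson95"), 3 / 50)
  # a geometry where one object over all fields maps to ~4e4/ml
  g <- microscope_geometry(dilution_factor = 2000, filtered_volume_ml = 10,
                           filter_effective_area_um2 = 1e9,
                           field_area_um2 = 1e4)
  expect_equal(detection_bound(g, n_fields = 500), 4e4)
  expect_error(detection_bound(g_unit, n_fields = 50, n_positive = 1),
               class = "not_applicable")
})

test_that("fish_composition flags zero-positive probes as below detection", {
  tr <- reference_truth("S1", seed = 8)
  dapi <- simulate_counts(tr, seed = 9)
  probes <- simulate_probe_counts(tr, dapi, seed = 10)
  comp <- fish_composition(probes, tr$geometry)
  anme1 <- comp[comp$group == "ANME-1", ]
  expect_true(all(anme1$below_detection))
  expect_true(all(is.na(anme1$mean)))
  expect_true(all(anme1$bound > 0))
  anme2 <- comp[comp$group == "ANME-2", ]
  expect_true(all(!anme2$below_detection))
  expect_true(all(anme2$mean >= 0 & anme2$mean <= 1))
  expect_true(all(anme2$se >= 0))
  # rendering uses the below-detection wording
  expect_true(any(grepl("Below detection limit", render_report(comp))))
})

test_that("binomially thinned synthetic data recovers the true fraction", {
  tr <- reference_truth("S1", seed = 21, n_fields = 2500)
  dapi <- simulate_counts(tr, seed = 22)
  probes <- simulate_probe_counts(tr, dapi, probes = "DSS658", seed = 23)
  agg <- probes[probes$object_type == "aggregate", ]
  # truth: two-tier fractions; compare pooled estimate to expected mixture
  cls <- as.character(agg$diameter_class_um)
  expected <- sum(tr$fractions["DSS658", cls] * agg$dapi_count) /
    sum(agg$dapi_count)
  est <- sum(agg$probe_count) / sum(agg$dapi_count)
  n <- sum(agg$dapi_count)
  expect_lt(abs(est - expected), 3 * sqrt(expected * (1 - expected) / n))
  # equal washout: fractions unbiased under common thinning
  thinned <- simulate_probe_counts(tr, dapi, probes = "DSS658", seed = 24,
                                   washout_retention = 0.5)
  agg2 <- thinned[thinned$object_type == "aggregate", ]
  est2 <- sum(agg2$probe_count) / sum(agg2$dapi_count)
  n2 <- sum(agg2$dapi_count)
  expect_lt(abs(est2 - expected), 3 * sqrt(expected * (1 - expected) / n2))
})

test_that("disjoint simulated groups give probe fractions summing below one", {
  tr <- reference_truth("S2", seed = 31, n_fields = 400)
  dapi <- simulate_counts(tr, seed = 32)
  comp <- do.call(rbind, lapply(rownames(tr$fractions), function(p) {
    pr <- simulate_probe_counts(tr, dapi, probes = p, seed = 33)
    fish_composition(pr, tr$geometry, categories = "aggregates")
  }))
  tot <- sum(comp$mean[!comp$below_detection])
  # reference marginals over aggregates sum to ~0.86 < 1
  expect_lt(tot, 1 + 0.05)
})
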