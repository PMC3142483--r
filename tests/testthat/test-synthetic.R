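# synthetic-data generator: truth construction, sampling models,
# exponential evolution, determinism

test_that("reference truth reproduces the study's summary statistics", {
  for (s in c("S1", "S2")) {
    tr <- reference_truth(s)
    total <- tr$single_cell_conc * sphere_volume(0.45) +
      sum(tr$class_conc * sphere_volume(2:15))
    expect_equal(total, if (s == "S1") 1.28e9 else 4.49e9,
                 tolerance = 1e-9)
    # aggregates carry 99.7% of the biovolume
    expect_equal(sum(tr$class_conc * sphere_volume(2:15)) / total, 0.997,
                 tolerance = 1e-9)
    # 2-5 um classes hold the observed share of aggregate counts
    small_share <- sum(tr$class_conc[as.character(2:5)]) /
      sum(tr$class_conc)
    expect_equal(small_share, if (s == "S1") 0.7335 else 0.7328,
                 tolerance = 1e-9)
    # per-probe biovolume fractions reproduce the composition table
    vol <- sphere_volume(2:15)
    bio <- function(p) (sum(tr$fractions[p, as.character(2:15)] *
                              tr$class_conc * vol) +
                          tr$fractions[p, "single_cell"] *
                          tr$single_cell_conc * sphere_volume(0.45)) / total
    tab2 <- if (s == "S1") c(0.134, 0.227, 0.015) else
      c(0.504, 0.606, 0.024)
    expect_equal(bio("EelMS932"), tab2[1], tolerance = 1e-6)
    expect_equal(bio("DSS658"), tab2[2], tolerance = 1e-6)
    expect_equal(bio("ANME3-1249"), tab2[3], tolerance = 1e-6)
    expect_true(all(tr$fractions >= 0 & tr$fractions <= 1))
  }
  # growth truth: ANME-2 doubles in ~2.5 months
  expect_equal(reference_truth("S1")$growth$doubling_time_months[["group"]],
               2.5, tolerance = 0.02)
})

test_that("simulated Poisson counts have the configured per-field mean", {
  tr <- reference_truth("S1", seed = 2)
  # lambda = concentration / scale factor; check on the single-cell stream
  lam <- tr$single_cell_conc / scale_factor(tr$geometry)
  tab <- simulate_counts(tr, n_replicates = 1, n_fields = 10000)
  sc <- tab$count[tab$object_type == "single_cell"]
  expect_equal(length(sc), 10000)
  expect_lt(abs(mean(sc) - lam), 3 * sqrt(lam / 10000))
  # zero concentrations give all-zero counts
  tr0 <- truth_model("Z", 0, c("5" = 0), geometry = tr$geometry)
  expect_true(all(simulate_counts(tr0, seed = 1)$count == 0))
  # implausible configuration: > 1e6 expected per field
  trbig <- truth_model("B", 1e20, c("5" = 0),
                       geometry = unit_geometry())
  expect_error(simulate_counts(trbig, seed = 1),
               class = "configuration_error")
})

test_that("simulation is byte-identical under a fixed seed", {
  tr <- reference_truth("S1", seed = 42)
  expect_identical(simulate_counts(tr), simulate_counts(tr))
  d <- simulate_counts(tr)
  expect_identical(simulate_probe_counts(tr, d),
                   simulate_probe_counts(tr, d))
  s1 <- simulate_enrichment(seed = 9, n_fields = 5)
  s2 <- simulate_enrichment(seed = 9, n_fields = 5)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$probes, s2$probes)
  expect_identical(s1$clones$archaea$group_counts,
                   s2$clones$archaea$group_counts)
  # different seed, different draws
  expect_false(identical(simulate_counts(tr, seed = 43), d))
})

test_that("probe simulation respects saturation and zero fractions", {
  geom <- microscope_geometry(dilution_factor = 1, filtered_volume_ml = 1,
                              filter_effective_area_um2 = 10,
                              field_area_um2 = 10)
  fr <- matrix(c(1, 1, 0, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("all", "none"), c("5", "single_cell")))
  tr <- truth_model("T", 5, c("5" = 5), fractions = fr, geometry = geom,
                    n_replicates = 2, n_fields = 30)
  d <- simulate_counts(tr, seed = 5)
  pall <- simulate_probe_counts(tr, d, probes = "all", seed = 6)
  expect_identical(pall$probe_count, pall$dapi_count)
  pnone <- simulate_probe_counts(tr, d, probes = "none", seed = 6)
  expect_true(all(pnone$probe_count == 0))
  # the below-detection path is exercised downstream
  comp <- fish_composition(pnone, geom)
  expect_true(all(comp$below_detection))
})

test_that("estimated concentration converges to the truth (Poisson design)", {
  tr <- reference_truth("S1", seed = 13)
  tab <- simulate_counts(tr, n_replicates = 1, n_fields = 10000)
  bv <- quantify_sample(tab, tr$geometry)
  # bias below 3 Monte-Carlo SEs for the total aggregate concentration
  est <- sum(bv$per_class$concentration)
  truth <- sum(tr$class_conc)
  lam_tot <- truth / scale_factor(tr$geometry)
  mc_se <- sqrt(lam_tot / 10000) * scale_factor(tr$geometry)
  expect_lt(abs(est - truth), 3 * mc_se)
})

test_that("evolve() scales the partition exponentially and consistently", {
  tr <- reference_truth("S1")
  expect_identical(evolve(tr, 0), tr)
  # one doubling time with equal group rates doubles everything
  tru <- tr
  tru$growth$doubling_time_months <- c(group = 2, other = 2)
  ev <- evolve(tru, 2 * 30.44)
  expect_equal(ev$class_conc, tr$class_conc * 2)
  expect_equal(ev$single_cell_conc, tr$single_cell_conc * 2)
  expect_equal(ev$fractions["EelMS932", ], tr$fractions["EelMS932", ])
  # closed-form group factor: t_d 2.5 months over 286 days -> 13.5x
  tr25 <- tr
  tr25$growth$doubling_time_months[["group"]] <- 2.5
  ev2 <- evolve(tr25, 286)
  v <- sphere_volume(2:15)
  V0 <- sum(tr$fractions["EelMS932", as.character(2:15)] * tr$class_conc *
              v) + tr$fractions["EelMS932", "single_cell"] *
    tr$single_cell_conc * sphere_volume(0.45)
  V1 <- sum(ev2$fractions["EelMS932", as.character(2:15)] *
              ev2$class_conc * v) +
    ev2$fractions["EelMS932", "single_cell"] * ev2$single_cell_conc *
    sphere_volume(0.45)
  expect_equal(V1 / V0, 2^(286 / (2.5 * 30.44)))
  expect_equal(V1 / V0, 13.5, tolerance = 0.01)
  expect_error(evolve(tr, -1), class = "invalid_input")
})

test_that("negative-binomial overdispersion keeps the mean, inflates variance", {
  tr <- reference_truth("S1", seed = 17)
  lam <- tr$single_cell_conc / scale_factor(tr$geometry)
  tab <- simulate_counts(tr, n_replicates = 1, n_fields = 8000,
                         overdispersion = 2)
  sc <- tab$count[tab$object_type == "single_cell"]
  expect_equal(mean(sc), lam, tolerance = 0.1)
  expect_gt(stats::var(sc), 1.5 * lam)
})
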