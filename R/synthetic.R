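# Synthetic-data generator: a declared truth model (true concentrations,
# group fractions, community composition, exponential growth) from which
# Poisson field counts, binomial probe counts and multinomial clone
# libraries are drawn, so every pipeline stage can be tested against known
# parameters.

#' Declare a truth model for simulation
#'
#' @param sample_id Sample label.
#' @param single_cell_conc True single-cell concentration (cells/ml slurry).
#' @param class_conc Named numeric vector of true aggregate concentrations
#'   per diameter class (objects/ml slurry); names are integer class labels
#'   in um.
#' @param fractions Optional matrix of per-probe marginal labelling
#'   probabilities: rows are probe ids, columns are the diameter classes
#'   plus `"single_cell"`; entries in `[0, 1]`. Probes are single
#'   hybridizations, so rows need not sum to 1 across probes (aggregates may
#'   host several groups).
#' @param composition Optional list of per-domain community compositions
#'   (named probability vectors summing to 1) for clone-library simulation.
#' @param growth Optional list describing exponential growth for
#'   [evolve()]: `partition_probe` (a probe id whose marginal fraction
#'   defines a disjoint two-component partition of the community, or `NULL`
#'   for uniform growth) and `doubling_time_months`, a numeric vector with
#'   entries `group` and `other` (months, > 0).
#' @param geometry A [microscope_geometry()].
#' @param n_replicates,n_fields Counting design (stainings x fields per
#'   staining).
#' @param seed Default seed for simulations from this truth.
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(sample_id, single_cell_conc, class_conc,
                        fractions = NULL, composition = NULL, growth = NULL,
                        geometry = microscope_geometry(),
                        n_replicates = 4, n_fields = 50, seed = 1) {
  check_number(single_cell_conc, "single_cell_conc", lower = 0)
  if (!is.numeric(class_conc) || is.null(names(class_conc)) ||
      any(class_conc < 0))
    stop_aq("class_conc must be a named non-negative vector",
            class = "invalid_input")
  if (!is.null(fractions)) {
    fractions <- as.matrix(fractions)
    need <- c(names(class_conc), "single_cell")
    if (!all(need %in% colnames(fractions)))
      stop_aq("fractions must have one column per class plus 'single_cell'",
              class = "invalid_input")
    if (any(fractions < 0 | fractions > 1))
      stop_aq("fractions must lie in [0, 1]", class = "invalid_input")
  }
  if (!is.null(composition)) {
    for (d in names(composition)) {
      p <- composition[[d]]
      if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
        stop_aq("composition[['", d, "']] must be probabilities summing to 1",
                class = "invalid_input")
    }
  }
  if (!is.null(growth)) {
    td <- growth$doubling_time_months
    if (is.null(td) || any(td <= 0))
      stop_aq("growth doubling times must be > 0", class = "invalid_input")
    if (!is.null(growth$partition_probe) &&
        !growth$partition_probe %in% rownames(fractions))
      stop_aq("growth partition_probe must be a row of fractions",
              class = "invalid_input")
  }
  check_number(n_replicates, "n_replicates", lower = 1)
  check_number(n_fields, "n_fields", lower = 1)
  stopifnot(inherits(geometry, "microscope_geometry"))
  structure(list(sample_id = sample_id,
                 single_cell_conc = single_cell_conc,
                 class_conc = class_conc, fractions = fractions,
                 composition = composition, growth = growth,
                 geometry = geometry,
                 n_replicates = as.integer(n_replicates),
                 n_fields = as.integer(n_fields), seed = as.integer(seed)),
            class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  v <- sphere_volume(as.numeric(names(x$class_conc)))
  total <- x$single_cell_conc *
    sphere_volume(x$geometry$single_cell_diameter_um) + sum(x$class_conc * v)
  cat(sprintf("Truth model '%s': %d classes, design %d x %d fields\n",
              x$sample_id, length(x$class_conc), x$n_replicates, x$n_fields))
  cat(sprintf("  total biovolume %.3g um^3/ml; single cells %.3g/ml\n",
              total, x$single_cell_conc))
  if (!is.null(x$fractions))
    cat("  probes:", paste(rownames(x$fractions), collapse = ", "), "\n")
  invisible(x)
}

# true total biovolume of a truth model (um^3/ml slurry)
truth_total_biovolume <- function(truth) {
  v <- sphere_volume(as.numeric(names(truth$class_conc)))
  truth$single_cell_conc *
    sphere_volume(truth$geometry$single_cell_diameter_um) +
    sum(truth$class_conc * v)
}

# true biovolume of one probe's group
truth_group_biovolume <- function(truth, probe) {
  v <- sphere_volume(as.numeric(names(truth$class_conc)))
  f <- truth$fractions[probe, names(truth$class_conc)]
  fs <- truth$fractions[probe, "single_cell"]
  sum(f * truth$class_conc * v) + fs * truth$single_cell_conc *
    sphere_volume(truth$geometry$single_cell_diameter_um)
}

# geometric within-group weights over classes; ratio r per 1-um step
geom_weights <- function(classes, r) {
  w <- r^(classes - min(classes))
  w / sum(w)
}

# solve the geometric ratio so the count-weighted mean sphere volume over
# `classes` equals `target`
solve_shape_ratio <- function(classes, target) {
  v <- sphere_volume(classes)
  if (target <= min(v) || target >= max(v))
    stop_aq("target mean volume ", signif(target, 4),
            " not attainable within classes ",
            paste(range(classes), collapse = "-"), class = "invalid_input")
  f <- function(logr) sum(geom_weights(classes, exp(logr)) * v) - target
  exp(stats::uniroot(f, c(-10, 10), tol = 1e-12)$root)
}

# summary statistics of the reference enrichment experiment used to build
# the preset truth: totals and shares observed at the two sampling points
.reference_constants <- list(
  S1 = list(total = 1.28e9, p_single = 0.003, small_cnt_share = 0.7335,
            p_mid = 0.5273, p_big = 0.2667, big_count = 2.22e5,
            dilution = 2000,
            # per-probe (cell-count fraction, aggregate-count fraction,
            # biovolume fraction)
            probes = list(
              "ANME1-350"  = c(cells = 0,     aggregates = 0,     biovolume = 0),
              "EelMS932"   = c(cells = 0.082, aggregates = 0.371, biovolume = 0.134),
              "ANME3-1249" = c(cells = 0.001, aggregates = 0.021, biovolume = 0.015),
              "DSS658"     = c(cells = 0.029, aggregates = 0.320, biovolume = 0.227))),
  S2 = list(total = 4.49e9, p_single = 0.003, small_cnt_share = 0.7328,
            p_mid = 0.4702, p_big = 0.3334, big_count = NA,
            dilution = 5600,
            probes = list(
              "ANME1-350"  = c(cells = 0,     aggregates = 0,     biovolume = 0),
              "EelMS932"   = c(cells = 0.025, aggregates = 0.472, biovolume = 0.504),
              "ANME3-1249" = c(cells = 0.001, aggregates = 0.008, biovolume = 0.024),
              "DSS658"     = c(cells = 0.008, aggregates = 0.376, biovolume = 0.606))),
  composition = list(
    archaea = c("ANME-2a" = 0.88, "MBG-D" = 0.12),
    bacteria = c("Gammaproteobacteria" = 0.43,
                 "Deltaproteobacteria (other)" = 0.09,
                 "SEEP-SRB1a" = 0.08, "Other bacteria" = 0.40)),
  clones = list(archaea = c(sequenced = 50, obtained = 56),
                bacteria = c(sequenced = 100, obtained = 110)),
  delta_t_days = 286
)

# build the per-class concentration state for one reference sample.
# Construction: single cells carry p_single of the total biovolume; small
# classes (2-5 um) hold the printed fraction of aggregate counts with
# uniform within-group weights; the big-class (11-15 um) shape ratio is
# solved from the S1 printed count and biovolume share and reused for S2
# (whose printed count and share are mutually infeasible below 15 um); the
# mid-class (6-10 um) shape is solved from the remaining count and
# biovolume budget.
.reference_state <- function(sample) {
  cst <- .reference_constants[[sample]]
  s1 <- .reference_constants$S1
  small <- 2:5; mid <- 6:10; big <- 11:15
  v <- sphere_volume(2:15)
  names(v) <- 2:15

  p_small <- 1 - cst$p_single - cst$p_mid - cst$p_big
  # big-class shape from S1's jointly feasible printed values
  m_big_s1 <- s1$p_big * s1$total /  s1$big_count
  r_big <- solve_shape_ratio(big, m_big_s1)
  m_big <- sum(geom_weights(big, r_big) * v[as.character(big)])
  big_count <- if (!is.na(cst$big_count) &&
                   abs(cst$p_big * cst$total / cst$big_count - m_big) /
                     m_big < 0.05)
    cst$big_count else cst$p_big * cst$total / m_big

  w_small <- geom_weights(small, 1)              # uniform within 2-5 um
  m_small <- sum(w_small * v[as.character(small)])
  small_count <- p_small * cst$total / m_small
  agg_count <- small_count / cst$small_cnt_share
  mid_count <- agg_count - small_count - big_count
  if (mid_count <= 0)
    stop_aq("reference construction failed: no count budget for mid classes",
            class = "invalid_input")
  m_mid <- cst$p_mid * cst$total / mid_count
  r_mid <- solve_shape_ratio(mid, m_mid)

  class_conc <- c(small_count * w_small,
                  mid_count * geom_weights(mid, r_mid),
                  big_count * geom_weights(big, r_big))
  names(class_conc) <- 2:15
  single_cell_conc <- cst$p_single * cst$total / sphere_volume(0.45)

  # two-tier per-probe fractions (one level for 2-5 um, one for 6-15 um)
  # solved so the count-weighted and volume-weighted means reproduce the
  # observed aggregate-count and biovolume fractions
  s_cnt <- small_count / agg_count
  agg_vol <- sum(class_conc * v)
  s_vol <- sum(class_conc[as.character(small)] * v[as.character(small)]) /
    agg_vol
  fractions <- matrix(0, nrow = length(cst$probes), ncol = 15,
                      dimnames = list(names(cst$probes), c(2:15,
                                                           "single_cell")))
  for (p in names(cst$probes)) {
    tgt <- cst$probes[[p]]
    f_vol_agg <- (tgt[["biovolume"]] * cst$total -
                    tgt[["cells"]] * single_cell_conc *
                    sphere_volume(0.45)) / agg_vol
    sol <- solve(matrix(c(s_cnt, 1 - s_cnt, s_vol, 1 - s_vol), 2,
                        byrow = TRUE),
                 c(tgt[["aggregates"]], f_vol_agg))
    sol <- pmin(pmax(sol, 0), 1)
    fractions[p, as.character(small)] <- sol[1]
    fractions[p, as.character(c(mid, big))] <- sol[2]
    fractions[p, "single_cell"] <- tgt[["cells"]]
  }
  list(class_conc = class_conc, single_cell_conc = single_cell_conc,
       fractions = fractions, dilution = cst$dilution)
}

#' Reference truth model for the high-pressure AOM enrichment scenario
#'
#' Builds the simulation truth that emulates the reference enrichment
#' experiment: two sampling points (S1 before and S2 after 286 days of
#' high-pressure incubation) with total biovolumes 1.28e9 and 4.49e9
#' um^3/ml slurry, aggregate diameter classes 2-15 um whose size
#' distribution reproduces the observed count and biovolume shares,
#' per-probe CARD-FISH fractions reproducing the observed composition
#' table, the archaeal/bacterial clone-library compositions, and an
#' exponential-growth truth in which the ANME-2 partition doubles every
#' ~2.5 months. The counting design is 4 stainings x 50 fields.
#'
#' @param sample `"S1"` or `"S2"`.
#' @param seed Default simulation seed.
#' @param n_replicates,n_fields Counting design overrides.
#' @return A [truth_model()].
#' @examples
#' tr <- reference_truth("S1")
#' print(tr)
#' @export
reference_truth <- function(sample = c("S1", "S2"), seed = 1,
                            n_replicates = 4, n_fields = 50) {
  sample <- match.arg(sample)
  st <- .reference_state(sample)
  geometry <- microscope_geometry(dilution_factor = st$dilution,
                                  filtered_volume_ml = 10)
  truth <- truth_model(
    sample_id = sample,
    single_cell_conc = st$single_cell_conc,
    class_conc = st$class_conc,
    fractions = st$fractions,
    composition = .reference_constants$composition,
    geometry = geometry,
    n_replicates = n_replicates, n_fields = n_fields, seed = seed)

  # growth truth: disjoint two-component partition (ANME-2 vs rest), with
  # doubling times implied by the two reference states over 286 days
  s1 <- .reference_state("S1")
  s2 <- .reference_state("S2")
  tmp1 <- truth; tmp1$class_conc <- s1$class_conc
  tmp1$single_cell_conc <- s1$single_cell_conc; tmp1$fractions <- s1$fractions
  tmp2 <- truth; tmp2$class_conc <- s2$class_conc
  tmp2$single_cell_conc <- s2$single_cell_conc; tmp2$fractions <- s2$fractions
  dt <- .reference_constants$delta_t_days
  V1 <- truth_group_biovolume(tmp1, "EelMS932")
  V2 <- truth_group_biovolume(tmp2, "EelMS932")
  O1 <- truth_total_biovolume(tmp1) - V1
  O2 <- truth_total_biovolume(tmp2) - V2
  truth$growth <- list(
    partition_probe = "EelMS932",
    doubling_time_months = c(group = doubling_time(V1, V2, dt),
                             other = doubling_time(O1, O2, dt)))
  truth
}

#' Simulate DAPI field counts from a truth model
#'
#' Each field's count of single cells and of aggregates per diameter class
#' is an independent Poisson draw with mean `lambda = concentration *
#' filtered_volume * (field_area / filter_area) / dilution` — the sampling
#' model for a well-mixed slurry filtered onto a membrane.
#'
#' @param truth A [truth_model()].
#' @param seed Seed; defaults to the truth's seed. Fixed seed gives a
#'   byte-identical table.
#' @param n_replicates,n_fields Design overrides.
#' @param overdispersion Optional negative-binomial size parameter to model
#'   aggregate clumping (`Inf`, the default, is pure Poisson).
#' @return A long counts data frame (see [quantify_sample()]), one row per
#'   (replicate, field, object type, class), zero rows included.
#' @export
simulate_counts <- function(truth, seed = NULL, n_replicates = NULL,
                            n_fields = NULL, overdispersion = Inf) {
  stopifnot(inherits(truth, "truth_model"))
  seed <- seed %||% truth$seed
  k <- n_replicates %||% truth$n_replicates
  nf <- n_fields %||% truth$n_fields
  lam <- c(single_cell = truth$single_cell_conc, truth$class_conc) /
    scale_factor(truth$geometry)
  if (any(lam > 1e6))
    stop_aq("expected counts exceed 1e6 per field; geometry/dilution ",
            "configuration implausible", class = "configuration_error")
  n <- k * nf
  design <- expand.grid(field_id = seq_len(nf), replicate_id = seq_len(k))
  set.seed(sub_seed(seed, 1))
  draw <- function(l) {
    if (is.finite(overdispersion))
      stats::rnbinom(n, size = overdispersion, mu = l)
    else stats::rpois(n, l)
  }
  blocks <- lapply(names(lam), function(cls) {
    data.frame(sample_id = truth$sample_id,
               replicate_id = design$replicate_id,
               field_id = design$field_id,
               object_type = if (cls == "single_cell") "single_cell"
                             else "aggregate",
               diameter_class_um = if (cls == "single_cell") NA_real_
                                   else as.numeric(cls),
               count = draw(lam[[cls]]))
  })
  do.call(rbind, blocks)
}

#' Simulate CARD-FISH probe counts given DAPI counts
#'
#' Each probe-positive count is a binomial thinning of the field's DAPI
#' count with the probe's marginal class fraction as success probability.
#' An optional common washing-loss retention (the equal-washout assumption:
#' every object type is lost at the same rate) is applied to the DAPI
#' counts first, so probe fractions remain unbiased under loss.
#'
#' @param truth A [truth_model()] with a `fractions` matrix.
#' @param dapi_counts A counts table (e.g. from [simulate_counts()]) giving
#'   the DAPI counts on the hybridization filter.
#' @param probes Probe ids to simulate (default: all rows of the truth's
#'   fraction matrix).
#' @param seed Seed; defaults to the truth's seed.
#' @param washout_retention Probability that an object survives the washing
#'   steps, applied equally to all classes (default 1 = no loss).
#' @return A probe-count table (see [probe_fraction()]).
#' @export
simulate_probe_counts <- function(truth, dapi_counts,
                                  probes = rownames(truth$fractions),
                                  seed = NULL, washout_retention = 1) {
  stopifnot(inherits(truth, "truth_model"))
  if (is.null(truth$fractions))
    stop_aq("truth has no probe fractions", class = "invalid_input")
  check_number(washout_retention, "washout_retention", lower = 0, upper = 1)
  seed <- seed %||% truth$seed
  dapi_counts <- validate_counts(dapi_counts,
                                 as.numeric(names(truth$class_conc)))
  out <- lapply(seq_along(probes), function(i) {
    p <- probes[i]
    set.seed(sub_seed(seed, 100 + i))
    cls <- ifelse(dapi_counts$object_type == "single_cell", "single_cell",
                  as.character(dapi_counts$diameter_class_um))
    pr <- truth$fractions[p, cls]
    dapi <- dapi_counts$count
    if (washout_retention < 1)
      dapi <- stats::rbinom(length(dapi), dapi, washout_retention)
    pos <- stats::rbinom(length(dapi), dapi, pr)
    data.frame(sample_id = dapi_counts$sample_id, probe_id = p,
               replicate_id = dapi_counts$replicate_id,
               field_id = dapi_counts$field_id,
               object_type = dapi_counts$object_type,
               diameter_class_um = dapi_counts$diameter_class_um,
               probe_count = pos, dapi_count = dapi)
  })
  do.call(rbind, out)
}

#' Evolve a truth model forward under exponential growth
#'
#' Scales the community by group-specific exponential factors
#' `2^(elapsed_days / (doubling_time_months * 30.44))`. The growth truth is
#' a disjoint two-component partition (the `partition_probe` group versus
#' everything else); per-class concentrations are rescaled by the mixture
#' factor and the partition probe's marginal fractions are updated
#' consistently. Marginal fractions of other probes are left unchanged
#' (their groups are not disjoint from the partition, so no consistent
#' update exists without a joint co-occurrence model).
#'
#' @param truth A [truth_model()] with a `growth` component.
#' @param elapsed_days Days to advance, >= 0.
#' @return The evolved [truth_model()].
#' @examples
#' tr <- reference_truth("S1")
#' tr286 <- evolve(tr, 286)
#' @export
evolve <- function(truth, elapsed_days) {
  stopifnot(inherits(truth, "truth_model"))
  check_number(elapsed_days, "elapsed_days")
  if (elapsed_days < 0)
    stop_aq("elapsed_days must be >= 0", class = "invalid_input")
  if (is.null(truth$growth))
    stop_aq("truth has no growth component", class = "invalid_input")
  if (elapsed_days == 0) return(truth)
  td <- truth$growth$doubling_time_months
  gamma <- 2^(elapsed_days / (td * DAYS_PER_MONTH))
  p <- truth$growth$partition_probe
  if (is.null(p)) {
    fac <- unname(gamma[["other"]])
    truth$class_conc <- truth$class_conc * fac
    truth$single_cell_conc <- truth$single_cell_conc * fac
    return(truth)
  }
  cols <- c(names(truth$class_conc), "single_cell")
  f <- truth$fractions[p, cols]
  phi <- f * gamma[["group"]] + (1 - f) * gamma[["other"]]
  conc <- c(truth$class_conc, single_cell = truth$single_cell_conc)
  conc_new <- conc * phi
  truth$fractions[p, cols] <- f * gamma[["group"]] / phi
  truth$class_conc <- conc_new[names(truth$class_conc)]
  truth$single_cell_conc <- unname(conc_new[["single_cell"]])
  truth
}

#' Simulate a 16S clone library
#'
#' Clone group counts are a multinomial draw from the community
#' composition.
#'
#' @param composition Named probability vector summing to 1.
#' @param n_sequenced Number of clones sequenced, > 0.
#' @param seed Seed.
#' @param domain `"archaea"` or `"bacteria"`.
#' @param clones_obtained Clones obtained before picking (defaults to
#'   `n_sequenced`).
#' @return A [clone_library()].
#' @export
simulate_clone_library <- function(composition, n_sequenced, seed,
                                   domain = "archaea",
                                   clones_obtained = n_sequenced) {
  if (abs(sum(composition) - 1) > 1e-8 || any(composition < 0))
    stop_aq("composition must be probabilities summing to 1",
            class = "invalid_input")
  check_number(n_sequenced, "n_sequenced")
  if (n_sequenced <= 0)
    stop_aq("n_sequenced must be > 0", class = "invalid_input")
  set.seed(sub_seed(seed, 200))
  counts <- stats::rmultinom(1, n_sequenced, composition)[, 1]
  names(counts) <- names(composition)
  clone_library(domain, counts, clones_sequenced = n_sequenced,
                clones_obtained = clones_obtained)
}

#' Simulate a complete enrichment dataset
#'
#' Generates, for both reference sampling points, the DAPI counts table,
#' the per-probe CARD-FISH table (each probe hybridized on its own
#' independently simulated filter), and the S2 archaeal and bacterial clone
#' libraries; optionally writes everything (plus geometry configs and the
#' truth sidecars) as TSV/YAML files for round-trip and recovery tests. All
#' randomness derives from one seed by stable sub-seeding.
#'
#' @param seed Global seed.
#' @param out_dir Optional directory to write `counts.tsv`, `probes.tsv`,
#'   `clones.tsv`, `geometry_S1.yml`, `geometry_S2.yml`, `truth_S1.yml`,
#'   `truth_S2.yml`.
#' @param n_replicates,n_fields Counting design (default 4 x 50).
#' @return Invisibly, a list with elements `truth` (per sample), `counts`,
#'   `probes`, `clones`, and `paths` when files were written.
#' @export
simulate_enrichment <- function(seed = 1, out_dir = NULL,
                                n_replicates = 4, n_fields = 50) {
  truths <- list(S1 = reference_truth("S1", seed = sub_seed(seed, 11),
                                      n_replicates = n_replicates,
                                      n_fields = n_fields),
                 S2 = reference_truth("S2", seed = sub_seed(seed, 12),
                                      n_replicates = n_replicates,
                                      n_fields = n_fields))
  counts <- do.call(rbind, lapply(truths, simulate_counts))
  probes <- do.call(rbind, lapply(truths, function(tr) {
    do.call(rbind, lapply(seq_along(rownames(tr$fractions)), function(i) {
      p <- rownames(tr$fractions)[i]
      dapi <- simulate_counts(tr, seed = sub_seed(tr$seed, 50 + i))
      simulate_probe_counts(tr, dapi, probes = p,
                            seed = sub_seed(tr$seed, 70 + i))
    }))
  }))
  rownames(counts) <- rownames(probes) <- NULL
  cl <- .reference_constants$clones
  clones <- list(
    archaea = simulate_clone_library(
      truths$S2$composition$archaea, cl$archaea[["sequenced"]],
      seed = sub_seed(seed, 31), domain = "archaea",
      clones_obtained = cl$archaea[["obtained"]]),
    bacteria = simulate_clone_library(
      truths$S2$composition$bacteria, cl$bacteria[["sequenced"]],
      seed = sub_seed(seed, 32), domain = "bacteria",
      clones_obtained = cl$bacteria[["obtained"]]))
  out <- list(truth = truths, counts = counts, probes = probes,
              clones = clones)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      counts = file.path(out_dir, "counts.tsv"),
      probes = file.path(out_dir, "probes.tsv"),
      clones = file.path(out_dir, "clones.tsv"))
    write_counts_table(counts, paths$counts)
    write_probe_table(probes, paths$probes)
    write_clone_table(clones, paths$clones)
    for (s in names(truths)) {
      g <- file.path(out_dir, paste0("geometry_", s, ".yml"))
      write_geometry_config(truths[[s]]$geometry, g)
      t <- file.path(out_dir, paste0("truth_", s, ".yml"))
      write_truth_config(truths[[s]], t)
      paths[[paste0("geometry_", s)]] <- g
      paths[[paste0("truth_", s)]] <- t
    }
    out$paths <- paths
  }
  invisible(out)
}

#' Write or read a truth-model sidecar config
#'
#' Serializes a [truth_model()] to YAML (and back) so simulated datasets can
#' carry their generating parameters for parameter-recovery tests.
#'
#' @param truth A `truth_model`.
#' @param path File path.
#' @return `write_truth_config()` returns `path` invisibly;
#'   `read_truth_config()` returns a `truth_model`.
#' @export
write_truth_config <- function(truth, path) {
  stopifnot(inherits(truth, "truth_model"))
  x <- list(sample_id = truth$sample_id,
            single_cell_conc = truth$single_cell_conc,
            class_conc = as.list(truth$class_conc),
            geometry = unclass(truth$geometry),
            n_replicates = truth$n_replicates,
            n_fields = truth$n_fields,
            seed = truth$seed)
  if (!is.null(truth$fractions)) {
    x$fractions <- stats::setNames(
      lapply(rownames(truth$fractions),
             function(p) as.list(truth$fractions[p, ])),
      rownames(truth$fractions))
  }
  if (!is.null(truth$composition))
    x$composition <- lapply(truth$composition, as.list)
  if (!is.null(truth$growth))
    x$growth <- list(partition_probe = truth$growth$partition_probe,
                     doubling_time_months =
                       as.list(truth$growth$doubling_time_months))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_truth_config
#' @export
read_truth_config <- function(path) {
  if (!file.exists(path))
    stop_aq("truth config not found: ", path, class = "io_error")
  x <- yaml::read_yaml(path)
  fractions <- NULL
  if (!is.null(x$fractions)) {
    fractions <- do.call(rbind, lapply(x$fractions, unlist))
    rownames(fractions) <- names(x$fractions)
  }
  growth <- NULL
  if (!is.null(x$growth))
    growth <- list(partition_probe = x$growth$partition_probe,
                   doubling_time_months =
                     unlist(x$growth$doubling_time_months))
  truth_model(sample_id = x$sample_id,
              single_cell_conc = x$single_cell_conc,
              class_conc = unlist(x$class_conc),
              fractions = fractions,
              composition = if (!is.null(x$composition))
                lapply(x$composition, unlist) else NULL,
              growth = growth,
              geometry = do.call(microscope_geometry, x$geometry),
              n_replicates = x$n_replicates, n_fields = x$n_fields,
              seed = x$seed)
}
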