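# Growth and enrichment: group biovolumes, relative increases, doubling
# times, dry-weight biomass, uncertainty propagation.

#' Biovolume of one phylogenetic group
#'
#' Multiplies a total biovolume concentration by the group's fraction of
#' biovolume, e.g. 1.28e9 um^3/ml x 13.4% = 1.7e8 um^3/ml.
#'
#' @param total_biovolume Total biovolume (um^3/ml slurry), >= 0.
#' @param fraction Group fraction of biovolume, in `[0, 1]`.
#' @return Group biovolume in um^3/ml slurry.
#' @export
group_biovolume <- function(total_biovolume, fraction) {
  if (!is.numeric(total_biovolume) || any(total_biovolume < 0))
    stop_aq("total_biovolume must be >= 0", class = "invalid_input")
  if (!is.numeric(fraction) || any(fraction < 0 | fraction > 1))
    stop_aq("fraction must lie in [0, 1]", class = "invalid_input")
  total_biovolume * fraction
}

#' Relative increase and fold change between two biovolumes
#'
#' The relative increase `(V2 - V1)/V1` is the "increased X times" convention
#' of the enrichment literature; the fold change `V2/V1` is exposed alongside
#' to avoid ambiguity (`fold_change = increase + 1`).
#'
#' @param V1,V2 Biovolumes (same units) at the first and second timepoint;
#'   `V1 > 0`.
#' @return Named numeric `c(increase_factor, fold_change)`.
#' @examples
#' increase_factor(1.7e8, 2.3e9) # 12.5-fold relative increase
#' @export
increase_factor <- function(V1, V2) {
  check_number(V1, "V1")
  check_number(V2, "V2", lower = 0)
  if (V1 <= 0)
    stop_aq("V1 must be > 0 (baseline undefined)",
            class = "undefined_baseline")
  c(increase_factor = (V2 - V1) / V1, fold_change = V2 / V1)
}

#' Doubling time under exponential growth
#'
#' Assuming exponential ("logarithmic") growth between two timepoints,
#' `t_d = delta_t * ln 2 / ln(V2/V1)`, converted from days to months using a
#' mean month of 30.44 days.
#'
#' @param V1,V2 Biovolumes at the two timepoints, `V2 > V1 > 0`.
#' @param delta_t_days Elapsed time in days, > 0.
#' @param days_per_month Days per month used for the unit conversion.
#' @return Doubling time in months.
#' @examples
#' doubling_time(1.7e8, 2.3e9, 286) # ~2.5 months
#' @export
doubling_time <- function(V1, V2, delta_t_days,
                          days_per_month = DAYS_PER_MONTH) {
  check_number(V1, "V1")
  check_number(V2, "V2")
  check_number(delta_t_days, "delta_t_days")
  if (V1 <= 0 || delta_t_days <= 0)
    stop_aq("V1 and delta_t_days must be > 0", class = "invalid_input")
  if (V2 <= V1)
    stop_aq("V2 must exceed V1: no net growth to time",
            class = "no_growth")
  delta_t_days * log(2) / log(V2 / V1) / days_per_month
}

#' Convert a biovolume concentration to dry-weight biomass
#'
#' Uses a literature conversion of about 0.2 g cell dry weight per ml of
#' biovolume for marine sediment cells: `g/l = um^3/ml x 1e-12 ml/um^3 x
#' factor g/ml x 1e3 ml/l`.
#'
#' @param biovolume Biovolume concentration (um^3/ml slurry), >= 0.
#' @param factor Dry weight per biovolume (g/ml), default 0.2.
#' @return Dry-weight biomass in g/l slurry.
#' @examples
#' dry_weight(4.49e9) # ~0.9 g/l
#' @export
dry_weight <- function(biovolume, factor = 0.2) {
  if (!is.numeric(biovolume) || any(is.na(biovolume)) || any(biovolume < 0))
    stop_aq("biovolume must be >= 0", class = "invalid_input")
  check_number(factor, "factor", lower = 0)
  biovolume / UM3_PER_ML * factor * 1e3
}

#' Propagate biovolume uncertainty into derived growth quantities
#'
#' First-order (delta-method) standard errors for the fold change/relative
#' increase, doubling time and dry weights derived from two biovolumes with
#' independent errors; optionally a seeded parametric bootstrap (normal
#' resampling of `V1` and `V2`) for comparison. Draws in which a resampled
#' biovolume is non-positive or `V2 <= V1` are dropped from the affected
#' bootstrap statistic.
#'
#' @param V1,V2 Biovolumes at the two timepoints (`V2 > V1 > 0` for the
#'   doubling-time SE).
#' @param V1_se,V2_se Standard errors, >= 0.
#' @param delta_t_days Elapsed time in days.
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param B Number of bootstrap draws.
#' @param seed Seed for the bootstrap stream (required for
#'   `method = "bootstrap"`; results are reproducible given the seed).
#' @param days_per_month,dry_weight_factor Unit conventions, as in
#'   [doubling_time()] and [dry_weight()].
#' @return Named numeric vector of SEs: `increase_factor`, `fold_change`,
#'   `doubling_time_months`, `dry_weight_1`, `dry_weight_2`.
#' @export
propagate_growth_uncertainty <- function(V1, V1_se, V2, V2_se,
                                         delta_t_days = 286,
                                         method = c("delta", "bootstrap"),
                                         B = 10000, seed = NULL,
                                         days_per_month = DAYS_PER_MONTH,
                                         dry_weight_factor = 0.2) {
  method <- match.arg(method)
  check_number(V1, "V1", lower = 0)
  check_number(V2, "V2", lower = 0)
  check_number(V1_se, "V1_se", lower = 0)
  check_number(V2_se, "V2_se", lower = 0)
  if (method == "delta") {
    cv2 <- (V1_se / V1)^2 + (V2_se / V2)^2
    R <- V2 / V1
    se_R <- R * sqrt(cv2)
    lnR <- log(R)
    se_td <- if (V2 > V1)
      delta_t_days * log(2) / days_per_month * sqrt(cv2) / lnR^2
      else NA_real_
    c(increase_factor = se_R, fold_change = se_R,
      doubling_time_months = se_td,
      dry_weight_1 = dry_weight(V1_se, dry_weight_factor),
      dry_weight_2 = dry_weight(V2_se, dry_weight_factor))
  } else {
    if (is.null(seed))
      stop_aq("bootstrap requires a seed for reproducibility",
              class = "invalid_input")
    set.seed(sub_seed(seed, 0))
    v1 <- stats::rnorm(B, V1, V1_se)
    v2 <- stats::rnorm(B, V2, V2_se)
    ok <- v1 > 0 & v2 > 0
    R <- v2[ok] / v1[ok]
    grow <- R > 1
    td <- delta_t_days * log(2) / log(R[grow]) / days_per_month
    c(increase_factor = stats::sd(R),
      fold_change = stats::sd(R),
      doubling_time_months = if (sum(grow) >= 2) stats::sd(td) else NA_real_,
      dry_weight_1 = stats::sd(dry_weight(pmax(v1, 0), dry_weight_factor)),
      dry_weight_2 = stats::sd(dry_weight(pmax(v2, 0), dry_weight_factor)))
  }
}

# coerce the `totals` argument of estimate_growth to c(mean, se)
as_total <- function(x, name) {
  if (inherits(x, "sample_biovolume")) {
    c(mean = x$total_biovolume[["mean"]], se = x$total_biovolume[["se"]])
  } else if (is.numeric(x) && length(x) %in% 1:2) {
    c(mean = unname(x[1]), se = if (length(x) == 2) unname(x[2]) else 0)
  } else {
    stop_aq(name, " must be a sample_biovolume or c(mean, se)",
            class = "invalid_input")
  }
}

# coerce a composition argument to data.frame(group, mean, se,
# below_detection) for one category
as_fractions <- function(x, name, category) {
  if (inherits(x, "group_composition")) {
    sub <- x[x$category == category, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop_aq(name, ": no '", category, "' category rows",
              class = "invalid_input")
    data.frame(group = sub$group, mean = sub$mean,
               se = ifelse(is.na(sub$se) & !sub$below_detection, 0, sub$se),
               below_detection = sub$below_detection)
  } else if (is.numeric(x) && !is.null(names(x))) {
    data.frame(group = names(x), mean = unname(x), se = 0,
               below_detection = FALSE)
  } else if (is.data.frame(x)) {
    if (!all(c("group", "mean") %in% names(x)))
      stop_aq(name, " needs columns group, mean", class = "schema_error")
    data.frame(group = x$group, mean = x$mean,
               se = if ("se" %in% names(x)) x$se else 0,
               below_detection = if ("below_detection" %in% names(x))
                 x$below_detection else FALSE)
  } else {
    stop_aq(name, " must be a group_composition, named numeric vector or ",
            "data frame", class = "invalid_input")
  }
}

#' Estimate group growth between two sampling timepoints
#'
#' The central estimator of the package: combines the total biovolumes of
#' two samples with per-group biovolume fractions into group biovolumes at
#' both timepoints, their relative increase and fold change, the exponential
#' doubling time over the elapsed interval, and dry-weight biomass
#' concentrations, each with a delta-method standard error. A `"total"` row
#' tracks the whole community.
#'
#' `mode = "reproduce"` mirrors the rounding conventions of the original
#' enrichment report: group biovolumes are rounded to 2 significant figures
#' before any derived quantity is computed, and dry weights are reported at
#' 1 significant figure. `mode = "full"` keeps full precision throughout.
#'
#' @param total1,total2 Total biovolume at each timepoint: a
#'   [quantify_sample()] result or `c(mean, se)` in um^3/ml slurry.
#' @param composition1,composition2 Biovolume fractions per group at each
#'   timepoint: a [fish_composition()]/[group_composition()] object (its
#'   `"biovolume"` category is used), a named numeric vector of fractions, or
#'   a data frame with columns `group`, `mean` and optionally `se`,
#'   `below_detection`.
#' @param delta_t_days Elapsed time between the two samples, days.
#' @param mode `"full"` or `"reproduce"` (see Details).
#' @param dry_weight_factor Dry weight per biovolume (g/ml).
#' @param days_per_month Days per month for the doubling-time unit.
#' @param category Composition category to use when compositions are
#'   `group_composition` objects.
#' @return An object of class `growth_estimate`: a table with one row per
#'   group (plus `"total"`) holding `V1`, `V2`, `increase_factor`,
#'   `fold_change`, `doubling_time_months`, `dry_weight_1`, `dry_weight_2`
#'   and their SEs, with metadata in attributes. Groups below detection at
#'   either timepoint carry `NA` estimates and are flagged.
#' @examples
#' est <- estimate_growth(c(1.28e9, 0.06e9), c(4.49e9, 0.51e9),
#'                        c("ANME-2" = 0.134), c("ANME-2" = 0.504),
#'                        delta_t_days = 286, mode = "reproduce")
#' print(est)
#' @export
estimate_growth <- function(total1, total2, composition1 = NULL,
                            composition2 = NULL, delta_t_days = 286,
                            mode = c("full", "reproduce"),
                            dry_weight_factor = 0.2,
                            days_per_month = DAYS_PER_MONTH,
                            category = "biovolume") {
  mode <- match.arg(mode)
  check_number(delta_t_days, "delta_t_days")
  if (delta_t_days <= 0)
    stop_aq("delta_t_days must be > 0", class = "invalid_input")
  t1 <- as_total(total1, "total1")
  t2 <- as_total(total2, "total2")

  groups <- data.frame(group = "total", f1 = 1, f1_se = 0, f2 = 1,
                       f2_se = 0, below_detection = FALSE)
  if (!is.null(composition1) || !is.null(composition2)) {
    if (is.null(composition1) || is.null(composition2))
      stop_aq("compositions must be given for both timepoints or neither",
              class = "invalid_input")
    c1 <- as_fractions(composition1, "composition1", category)
    c2 <- as_fractions(composition2, "composition2", category)
    shared <- intersect(c1$group, c2$group)
    i1 <- match(shared, c1$group)
    i2 <- match(shared, c2$group)
    groups <- rbind(groups, data.frame(
      group = shared,
      f1 = c1$mean[i1], f1_se = c1$se[i1],
      f2 = c2$mean[i2], f2_se = c2$se[i2],
      below_detection = c1$below_detection[i1] | c2$below_detection[i2]))
  }

  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    if (g$below_detection || is.na(g$f1) || is.na(g$f2)) {
      return(data.frame(group = g$group, V1 = NA_real_, V1_se = NA_real_,
                        V2 = NA_real_, V2_se = NA_real_,
                        increase_factor = NA_real_, increase_se = NA_real_,
                        fold_change = NA_real_,
                        doubling_time_months = NA_real_,
                        doubling_time_se = NA_real_,
                        dry_weight_1 = NA_real_, dry_weight_1_se = NA_real_,
                        dry_weight_2 = NA_real_, dry_weight_2_se = NA_real_,
                        below_detection = TRUE))
    }
    V1 <- group_biovolume(t1[["mean"]], g$f1)
    V2 <- group_biovolume(t2[["mean"]], g$f2)
    V1_se <- sqrt((g$f1 * t1[["se"]])^2 + (t1[["mean"]] * g$f1_se)^2)
    V2_se <- sqrt((g$f2 * t2[["se"]])^2 + (t2[["mean"]] * g$f2_se)^2)
    if (mode == "reproduce") {
      V1 <- signif(V1, 2)
      V2 <- signif(V2, 2)
    }
    inc <- if (V1 > 0) increase_factor(V1, V2)
           else c(increase_factor = NA_real_, fold_change = NA_real_)
    td <- if (V1 > 0 && V2 > V1)
      doubling_time(V1, V2, delta_t_days, days_per_month) else NA_real_
    se <- if (V1 > 0 && V2 > 0)
      propagate_growth_uncertainty(V1, V1_se, V2, V2_se, delta_t_days,
                                   days_per_month = days_per_month,
                                   dry_weight_factor = dry_weight_factor)
      else rep(NA_real_, 5)
    dw1 <- dry_weight(V1, dry_weight_factor)
    dw2 <- dry_weight(V2, dry_weight_factor)
    if (mode == "reproduce") {
      dw1 <- signif(dw1, 1)
      dw2 <- signif(dw2, 1)
    }
    data.frame(group = g$group, V1 = V1, V1_se = V1_se, V2 = V2,
               V2_se = V2_se,
               increase_factor = inc[["increase_factor"]],
               increase_se = se[[1]],
               fold_change = inc[["fold_change"]],
               doubling_time_months = td, doubling_time_se = se[[3]],
               dry_weight_1 = dw1, dry_weight_1_se = se[[4]],
               dry_weight_2 = dw2, dry_weight_2_se = se[[5]],
               below_detection = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "delta_t_days") <- delta_t_days
  attr(out, "mode") <- mode
  attr(out, "dry_weight_factor") <- dry_weight_factor
  attr(out, "days_per_month") <- days_per_month
  class(out) <- c("growth_estimate", "data.frame")
  out
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("Growth estimate over %g days (%s mode)\n",
              attr(x, "delta_t_days"), attr(x, "mode")))
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    if (r$below_detection) {
      cat(sprintf("  %-8s below detection limit\n", r$group))
      next
    }
    cat(sprintf("  %-8s V1 %s, V2 %s um^3/ml\n", r$group,
                format_mean_se(r$V1, r$V1_se),
                format_mean_se(r$V2, r$V2_se)))
    cat(sprintf("           increase %.1fx (fold %.1f)%s\n",
                r$increase_factor, r$fold_change,
                if (!is.na(r$doubling_time_months))
                  sprintf(", doubling time %.1f months",
                          r$doubling_time_months) else ""))
    cat(sprintf("           dry weight %.2g -> %.2g g/l slurry\n",
                r$dry_weight_1, r$dry_weight_2))
  }
  invisible(x)
}

#' @export
summary.growth_estimate <- function(object, ...) {
  print(object)
  invisible(as.data.frame(object))
}

#' @export
coef.growth_estimate <- function(object, ...) {
  stats::setNames(object$increase_factor, object$group)
}

#' Parametric-bootstrap draws from a growth estimate
#'
#' Draws `nsim` normal resamples of each group's `V1` and `V2` and returns
#' the implied increase factors and doubling times, for uncertainty checks
#' beyond the delta method.
#'
#' @param object A `growth_estimate`.
#' @param nsim Number of draws.
#' @param seed Seed (required; draws are reproducible given it).
#' @param ... Unused.
#' @return A data frame with columns `group`, `draw`, `increase_factor`,
#'   `doubling_time_months`.
#' @export
simulate.growth_estimate <- function(object, nsim = 1000, seed = NULL, ...) {
  if (is.null(seed))
    stop_aq("simulate() requires a seed", class = "invalid_input")
  dt <- attr(object, "delta_t_days")
  dpm <- attr(object, "days_per_month")
  keep <- !object$below_detection & object$V1 > 0
  out <- lapply(which(keep), function(i) {
    set.seed(sub_seed(seed, i))
    v1 <- stats::rnorm(nsim, object$V1[i], object$V1_se[i])
    v2 <- stats::rnorm(nsim, object$V2[i], object$V2_se[i])
    inc <- ifelse(v1 > 0, (v2 - v1) / v1, NA_real_)
    td <- ifelse(v1 > 0 & v2 > v1, dt * log(2) / log(v2 / v1) / dpm,
                 NA_real_)
    data.frame(group = object$group[i], draw = seq_len(nsim),
               increase_factor = inc, doubling_time_months = td)
  })
  do.call(rbind, out)
}
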