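# CARD-FISH group composition: probe/DAPI fractions with detection limits

PROBE_GROUPS <- c("ANME1-350" = "ANME-1", "EelMS932" = "ANME-2",
                  "ANME3-1249" = "ANME-3", "DSS658" = "SRB")

# validate a probe-count table (counts schema + probe_id/probe_count/
# dapi_count paired columns)
validate_probe_counts <- function(probes, diameter_classes = 2:15,
                                  context = "probe table") {
  required <- c("sample_id", "probe_id", "replicate_id", "field_id",
                "object_type", "diameter_class_um", "probe_count",
                "dapi_count")
  missing <- setdiff(required, names(probes))
  if (length(missing))
    stop_aq(context, ": missing column(s) ", paste(missing, collapse = ", "),
            class = "schema_error")
  check_counts_vector(probes$probe_count, "probe_count")
  check_counts_vector(probes$dapi_count, "dapi_count")
  over <- probes$probe_count > probes$dapi_count
  if (any(over))
    stop_aq(context, ": probe_count exceeds dapi_count at row(s) ",
            paste(utils::head(which(over), 5), collapse = ", "),
            class = "data_integrity_error")
  agg <- probes$object_type == "aggregate"
  bad <- agg & !probes$diameter_class_um %in% diameter_classes
  if (any(bad))
    stop_aq(context, ": aggregate diameter class outside configured range",
            class = "schema_error")
  probes
}

#' Fraction of a community labelled by one CARD-FISH probe
#'
#' Estimates the probe-positive fraction of single cells, of aggregates, or
#' of biovolume from paired probe/DAPI counts over the same fields. Because
#' probe and DAPI counts share every field, all geometry factors cancel and
#' the fraction is a pure ratio; the equal-washout assumption (all object
#' types lost at the same rate during washing) makes it unbiased for the
#' pre-washing community. For the biovolume category, each object is weighted
#' by the sphere volume of its size class (single cells by the single-cell
#' diameter).
#'
#' With two or more replicate blocks the fraction is computed per block and
#' summarized with [replicate_summary()]; with a single block the pooled
#' ratio is returned and the SE is `NA` (flagged undefined).
#'
#' @param probes Probe-count table for one probe: columns `sample_id`,
#'   `probe_id`, `replicate_id`, `field_id`, `object_type`,
#'   `diameter_class_um`, `probe_count`, `dapi_count`.
#' @param category `"cells"`, `"aggregates"` or `"biovolume"`.
#' @param single_cell_diameter Sphere diameter (um) used to weight single
#'   cells in the biovolume category.
#' @param diameter_classes Configured aggregate classes (um).
#' @return Named numeric `c(mean, se)` with attribute `n_blocks`.
#' @examples
#' tab <- data.frame(sample_id = "S", probe_id = "EelMS932",
#'                   replicate_id = 1, field_id = 1:4,
#'                   object_type = "aggregate", diameter_class_um = 5,
#'                   probe_count = c(9, 9, 10, 9), dapi_count = 25)
#' probe_fraction(tab, "aggregates") # 37/100
#' @export
probe_fraction <- function(probes,
                           category = c("cells", "aggregates", "biovolume"),
                           single_cell_diameter = 0.45,
                           diameter_classes = 2:15) {
  category <- match.arg(category)
  probes <- validate_probe_counts(probes, diameter_classes)
  rows <- switch(category,
    cells = probes[probes$object_type == "single_cell", , drop = FALSE],
    aggregates = probes[probes$object_type == "aggregate", , drop = FALSE],
    biovolume = probes)
  if (nrow(rows) == 0L)
    stop_aq("no rows for category '", category, "'", class = "invalid_input")
  w <- if (category == "biovolume") {
    sphere_volume(ifelse(rows$object_type == "single_cell",
                         single_cell_diameter, rows$diameter_class_um))
  } else rep(1, nrow(rows))
  pos <- tapply(w * rows$probe_count, rows$replicate_id, sum)
  tot <- tapply(w * rows$dapi_count, rows$replicate_id, sum)
  if (all(tot == 0))
    stop_aq("all DAPI counts are zero for category '", category,
            "': fraction undefined", class = "undefined_fraction")
  keep <- tot > 0
  frac <- as.numeric(pos[keep] / tot[keep])
  out <- if (length(frac) >= 2L) replicate_summary(frac)
         else c(mean = sum(pos) / sum(tot), se = NA_real_)
  attr(out, "n_blocks") <- length(frac)
  out
}

#' Upper-bound concentration for a probe with zero positive observations
#'
#' When no probe-positive object is seen in any field, the group is reported
#' as below the detection limit together with the concentration that a single
#' observed object (default) would have implied over all examined fields; a
#' Poisson 95% bound (3 objects over all fields, from P(X = 0 | lambda = 3)
#' < 0.05) is available instead.
#'
#' @param geometry A [microscope_geometry()].
#' @param n_fields Total number of fields examined for the probe.
#' @param n_positive Number of probe-positive objects observed; must be 0.
#' @param criterion `"one_object"` (default) or `"poisson95"`.
#' @return Upper-bound concentration in objects/ml slurry.
#' @examples
#' detection_bound(microscope_geometry(), n_fields = 50) # 1/50 per ml
#' @export
detection_bound <- function(geometry, n_fields, n_positive = 0,
                            criterion = c("one_object", "poisson95")) {
  stopifnot(inherits(geometry, "microscope_geometry"))
  criterion <- match.arg(criterion)
  check_number(n_fields, "n_fields", lower = 1)
  check_number(n_positive, "n_positive", lower = 0)
  if (n_positive > 0)
    stop_aq("detection_bound() applies only when zero positives were ",
            "observed", class = "not_applicable")
  k <- if (criterion == "one_object") 1 else 3
  k / n_fields * scale_factor(geometry)
}

#' Group composition from CARD-FISH probe counts
#'
#' Applies [probe_fraction()] to every probe and category in a probe-count
#' table, flagging probe/category pairs with zero positives as below the
#' detection limit and attaching the upper-bound concentration from
#' [detection_bound()].
#'
#' @param probes Probe-count table covering one sample and one or more
#'   probes (see [probe_fraction()] for columns).
#' @param geometry A [microscope_geometry()]; used only for detection
#'   bounds, which are `NA` when omitted.
#' @param categories Categories to estimate.
#' @param single_cell_diameter,diameter_classes Passed to
#'   [probe_fraction()].
#' @param bound_criterion Passed to [detection_bound()].
#' @return An object of class `group_composition`: a data frame with columns
#'   `sample_id`, `probe_id`, `group`, `category`, `mean`, `se`,
#'   `below_detection`, `bound`.
#' @export
fish_composition <- function(probes, geometry = NULL,
                             categories = c("cells", "aggregates",
                                            "biovolume"),
                             single_cell_diameter = 0.45,
                             diameter_classes = 2:15,
                             bound_criterion = "one_object") {
  probes <- validate_probe_counts(probes, diameter_classes)
  sample_id <- unique(probes$sample_id)
  if (length(sample_id) > 1L)
    stop_aq("fish_composition() expects a single sample",
            class = "invalid_input")
  rows <- list()
  for (p in unique(probes$probe_id)) {
    sub <- probes[probes$probe_id == p, , drop = FALSE]
    total_fields <- length(unique(paste(sub$replicate_id, sub$field_id)))
    for (cat in categories) {
      cat_rows <- switch(cat,
        cells = sub[sub$object_type == "single_cell", , drop = FALSE],
        aggregates = sub[sub$object_type == "aggregate", , drop = FALSE],
        biovolume = sub)
      if (nrow(cat_rows) == 0L) next
      if (sum(cat_rows$probe_count) == 0) {
        bound <- if (is.null(geometry)) NA_real_ else
          detection_bound(geometry, total_fields, criterion = bound_criterion)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, probe_id = p,
          group = unname(PROBE_GROUPS[p] %||% p), category = cat,
          mean = NA_real_, se = NA_real_,
          below_detection = TRUE, bound = bound)
      } else {
        f <- probe_fraction(sub, cat,
                            single_cell_diameter = single_cell_diameter,
                            diameter_classes = diameter_classes)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, probe_id = p,
          group = unname(PROBE_GROUPS[p] %||% p), category = cat,
          mean = f[["mean"]], se = f[["se"]],
          below_detection = FALSE, bound = NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  group_composition(out)
}

#' Construct a group-composition table directly
#'
#' Wraps a data frame of per-probe fraction summaries (for example a
#' published composition table) as a `group_composition` object so it can be
#' fed to [estimate_growth()] alongside compositions estimated from raw
#' counts.
#'
#' @param df Data frame with at least `group`, `category`, `mean`, `se`;
#'   optional `sample_id`, `probe_id`, `below_detection`, `bound`.
#' @return A `group_composition` object.
#' @export
group_composition <- function(df) {
  required <- c("group", "category", "mean", "se")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_aq("group_composition: missing column(s) ",
            paste(missing, collapse = ", "), class = "schema_error")
  n <- nrow(df)
  if (!"sample_id" %in% names(df)) df$sample_id <- rep(NA_character_, n)
  if (!"probe_id" %in% names(df)) df$probe_id <- df$group
  if (!"below_detection" %in% names(df)) df$below_detection <- rep(FALSE, n)
  if (!"bound" %in% names(df)) df$bound <- rep(NA_real_, n)
  bad <- !df$below_detection & (is.na(df$mean) | df$mean < 0 | df$mean > 1)
  if (any(bad))
    stop_aq("fractions must lie in [0, 1]", class = "invalid_input")
  if (any(!is.na(df$se) & df$se < 0))
    stop_aq("SEs must be >= 0", class = "invalid_input")
  df <- df[, c("sample_id", "probe_id", "group", "category", "mean", "se",
               "below_detection", "bound")]
  class(df) <- c("group_composition", "data.frame")
  df
}

#' @export
print.group_composition <- function(x, ...) {
  cat("CARD-FISH group composition",
      if (!all(is.na(x$sample_id))) paste0("(sample ",
        paste(unique(stats::na.omit(x$sample_id)), collapse = ", "), ")"),
      "\n")
  writeLines(render_report(x))
  invisible(x)
}
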