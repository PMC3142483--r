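#' Volume of a sphere of given diameter
#'
#' Both free-living cells and multicellular aggregates are modelled as solid
#' spheres, so an object of diameter `d` um contributes `(pi/6) d^3` um^3 of
#' biovolume. Aggregate diameter classes use the integer class label as the
#' sphere diameter.
#'
#' @param diameter Diameter(s) in um, >= 0.
#' @return Volume(s) in um^3.
#' @examples
#' sphere_volume(0.45) # a single ANME/SRB-sized cell, ~0.048 um^3
#' sphere_volume(10)   # a 10-um aggregate, ~524 um^3
#' @export
sphere_volume <- function(diameter) {
  if (!is.numeric(diameter) || any(is.na(diameter)) || any(diameter < 0))
    stop_aq("diameter must be numeric and >= 0", class = "invalid_input")
  pi / 6 * diameter^3
}

#' Convert per-field counts to a concentration per ml slurry
#'
#' For each staining replicate the mean count per field of view is scaled by
#' the geometry factor [scale_factor()] (fields per filter, filtered volume,
#' dilution) to give objects per ml of undiluted slurry.
#'
#' @param count Numeric vector of per-field counts (one element per counted
#'   field).
#' @param replicate Vector of replicate labels parallel to `count`; if `NULL`
#'   all counts belong to one replicate.
#' @param geometry A [microscope_geometry()].
#' @return Named numeric vector, one concentration (objects/ml slurry) per
#'   replicate.
#' @examples
#' g <- microscope_geometry()
#' counts_to_concentration(c(4, 5, 6), geometry = g)
#' @export
counts_to_concentration <- function(count, replicate = NULL, geometry) {
  stopifnot(inherits(geometry, "microscope_geometry"))
  check_counts_vector(count, "count")
  if (length(count) < 1L)
    stop_aq("at least one field per replicate is required",
            class = "invalid_input")
  if (is.null(replicate)) replicate <- rep("1", length(count))
  if (length(replicate) != length(count))
    stop_aq("replicate must be parallel to count", class = "invalid_input")
  means <- tapply(count, replicate, mean)
  out <- as.numeric(means) * scale_factor(geometry)
  names(out) <- names(means)
  out
}

#' Mean and standard error across staining replicates
#'
#' The reporting unit of the counting design is the staining replicate: each
#' replicate's 50 fields are averaged first, then the mean and standard error
#' are taken across the replicate-level values. SE uses the n-1 sample
#' standard deviation divided by sqrt(k); with a single replicate the SE is
#' undefined and returned as `NA`.
#'
#' @param values Numeric vector, one value per replicate.
#' @return Named numeric vector `c(mean, se)`.
#' @examples
#' replicate_summary(c(1, 2, 3, 4)) # mean 2.5, se 0.645
#' @export
replicate_summary <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || any(is.na(values)))
    stop_aq("values must be a non-empty numeric vector",
            class = "invalid_input")
  se <- if (length(values) >= 2L) stats::sd(values) / sqrt(length(values))
        else NA_real_
  c(mean = mean(values), se = se)
}

# validate a long counts table against the schema shared by files and
# simulator output; returns the table with normalized types
validate_counts <- function(counts, diameter_classes = 2:15,
                            context = "counts table") {
  required <- c("sample_id", "replicate_id", "field_id", "object_type",
                "diameter_class_um", "count")
  missing <- setdiff(required, names(counts))
  if (length(missing))
    stop_aq(context, ": missing column(s) ", paste(missing, collapse = ", "),
            class = "schema_error")
  bad_type <- !counts$object_type %in% c("single_cell", "aggregate")
  if (any(bad_type))
    stop_aq(context, ": invalid object_type at row(s) ",
            paste(utils::head(which(bad_type), 5), collapse = ", "),
            class = "schema_error")
  bad_count <- is.na(counts$count) | counts$count < 0 |
    counts$count != floor(counts$count)
  if (any(bad_count))
    stop_aq(context, ": negative or non-integer count at row(s) ",
            paste(utils::head(which(bad_count), 5), collapse = ", "),
            class = "validation_error")
  agg <- counts$object_type == "aggregate"
  bad_class <- agg & (is.na(counts$diameter_class_um) |
                        !counts$diameter_class_um %in% diameter_classes)
  if (any(bad_class))
    stop_aq(context, ": aggregate diameter class outside configured classes (",
            paste(range(diameter_classes), collapse = "-"), " um) at row(s) ",
            paste(utils::head(which(bad_class), 5), collapse = ", "),
            class = "schema_error")
  key <- paste(counts$sample_id, counts$replicate_id, counts$field_id,
               counts$object_type, counts$diameter_class_um)
  if (anyDuplicated(key))
    stop_aq(context, ": duplicate (sample, replicate, field, type, class) ",
            "row(s), first at row ", which(duplicated(key))[1],
            class = "validation_error")
  counts
}

#' Quantify a sample: concentrations and spherical biovolume by size class
#'
#' Converts a long table of per-field DAPI counts (single cells plus
#' aggregates binned by integer diameter class) into per-ml concentrations
#' and biovolumes. Each staining replicate is reduced to one value per
#' quantity (mean count per field x geometry factor), and the mean and
#' standard error are computed across replicates. Biovolume per class is
#' concentration times the sphere volume of the class diameter; single cells
#' use the configured single-cell diameter.
#'
#' @param counts Data frame with columns `sample_id`, `replicate_id`,
#'   `field_id`, `object_type` (`"single_cell"` or `"aggregate"`),
#'   `diameter_class_um` (`NA` for single cells) and `count`; one row per
#'   (field, type, class). Zero-count rows may be omitted, but every counted
#'   field must appear in at least one row so the field roster is complete.
#' @param geometry A [microscope_geometry()].
#' @param diameter_classes Integer vector of configured aggregate diameter
#'   classes (um); classes absent from the data count as zero.
#' @param single_cell_diameter Sphere diameter for single cells (um); default
#'   taken from the geometry.
#' @return An object of class `sample_biovolume`: a list with per-class and
#'   single-cell concentration/biovolume summaries (`mean`, `se`), the total
#'   biovolume, the aggregate biovolume share, and the per-replicate values
#'   the summaries were computed from.
#' @examples
#' tab <- data.frame(sample_id = "S", replicate_id = rep(1:2, each = 2),
#'                   field_id = rep(1:2, 2), object_type = "aggregate",
#'                   diameter_class_um = 10, count = c(1, 2, 2, 1))
#' quantify_sample(tab, microscope_geometry())
#' @export
quantify_sample <- function(counts, geometry, diameter_classes = 2:15,
                            single_cell_diameter = NULL) {
  stopifnot(inherits(geometry, "microscope_geometry"))
  counts <- validate_counts(counts, diameter_classes)
  if (nrow(counts) == 0L)
    stop_aq("counts table is empty", class = "invalid_input")
  sample_id <- unique(counts$sample_id)
  if (length(sample_id) > 1L)
    stop_aq("quantify_sample() expects a single sample; got ",
            paste(sample_id, collapse = ", "), class = "invalid_input")
  if (is.null(single_cell_diameter))
    single_cell_diameter <- geometry$single_cell_diameter_um
  check_number(single_cell_diameter, "single_cell_diameter")

  sf <- scale_factor(geometry)
  reps <- sort(unique(counts$replicate_id))
  k <- length(reps)
  n_fields <- vapply(reps, function(r)
    length(unique(counts$field_id[counts$replicate_id == r])), integer(1))

  # per-replicate concentration matrix: rows replicates, cols classes
  conc <- matrix(0, nrow = k, ncol = length(diameter_classes),
                 dimnames = list(as.character(reps),
                                 as.character(diameter_classes)))
  agg <- counts[counts$object_type == "aggregate", , drop = FALSE]
  if (nrow(agg)) {
    sums <- tapply(agg$count,
                   list(factor(agg$replicate_id, levels = reps),
                        factor(agg$diameter_class_um,
                               levels = diameter_classes)),
                   sum)
    sums[is.na(sums)] <- 0
    conc <- sums / n_fields * sf
  }
  sc <- counts[counts$object_type == "single_cell", , drop = FALSE]
  sc_sum <- rep(0, k)
  if (nrow(sc)) {
    s <- tapply(sc$count, factor(sc$replicate_id, levels = reps), sum)
    s[is.na(s)] <- 0
    sc_sum <- as.numeric(s)
  }
  sc_conc <- sc_sum / n_fields * sf

  vol <- sphere_volume(diameter_classes)
  biovol <- sweep(conc, 2, vol, `*`)
  sc_biovol <- sc_conc * sphere_volume(single_cell_diameter)
  agg_total <- rowSums(biovol)
  total <- sc_biovol + agg_total
  if (any(total == 0))
    warning("replicate(s) with zero total biovolume: aggregate share set to 0")
  share <- ifelse(total > 0, agg_total / total, 0)

  summarize <- function(m) t(apply(m, 2, replicate_summary))
  per_class <- data.frame(
    diameter_class_um = diameter_classes,
    concentration = apply(conc, 2, mean),
    concentration_se = apply(conc, 2, function(v) replicate_summary(v)["se"]),
    biovolume = apply(biovol, 2, mean),
    biovolume_se = apply(biovol, 2, function(v) replicate_summary(v)["se"]),
    row.names = NULL
  )

  out <- list(
    sample_id = sample_id,
    geometry = geometry,
    n_replicates = k,
    n_fields = n_fields,
    single_cell_diameter = single_cell_diameter,
    per_class = per_class,
    single_cell = list(concentration = replicate_summary(sc_conc),
                       biovolume = replicate_summary(sc_biovol)),
    aggregate_biovolume = replicate_summary(agg_total),
    total_biovolume = replicate_summary(total),
    aggregate_share = replicate_summary(share),
    replicates = list(concentration = conc, biovolume = biovol,
                      single_cell_concentration = sc_conc,
                      single_cell_biovolume = sc_biovol,
                      total_biovolume = total)
  )
  class(out) <- "sample_biovolume"
  out
}

#' @export
print.sample_biovolume <- function(x, ...) {
  cat(sprintf("Sample biovolume: %s (%d replicates x %s fields)\n",
              x$sample_id, x$n_replicates,
              paste(unique(x$n_fields), collapse = "/")))
  cat("  total biovolume    :",
      format_mean_se(x$total_biovolume["mean"], x$total_biovolume["se"]),
      "um^3/ml slurry\n")
  cat("  single cells       :",
      format_mean_se(x$single_cell$concentration["mean"],
                     x$single_cell$concentration["se"]), "cells/ml\n")
  cat(sprintf("  aggregate biovolume share: %.1f%%\n",
              100 * x$aggregate_share["mean"]))
  invisible(x)
}

#' @export
summary.sample_biovolume <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Sample %s: per-class concentrations and biovolumes\n",
              object$sample_id))
  print(df, digits = 3, row.names = FALSE)
  invisible(df)
}

#' @export
as.data.frame.sample_biovolume <- function(x, ...) {
  pc <- x$per_class
  rbind(
    data.frame(sample_id = x$sample_id, object = "single_cell",
               diameter_class_um = x$single_cell_diameter,
               concentration = x$single_cell$concentration[["mean"]],
               concentration_se = x$single_cell$concentration[["se"]],
               biovolume = x$single_cell$biovolume[["mean"]],
               biovolume_se = x$single_cell$biovolume[["se"]]),
    data.frame(sample_id = x$sample_id, object = "aggregate",
               diameter_class_um = pc$diameter_class_um,
               concentration = pc$concentration,
               concentration_se = pc$concentration_se,
               biovolume = pc$biovolume,
               biovolume_se = pc$biovolume_se),
    data.frame(sample_id = x$sample_id, object = "total",
               diameter_class_um = NA_real_,
               concentration = NA_real_, concentration_se = NA_real_,
               biovolume = x$total_biovolume[["mean"]],
               biovolume_se = x$total_biovolume[["se"]])
  )
}

#' @export
plot.sample_biovolume <- function(x, which = c("biovolume", "concentration"),
                                  ...) {
  which <- match.arg(which)
  pc <- x$per_class
  y <- if (which == "biovolume") pc$biovolume else pc$concentration
  se <- if (which == "biovolume") pc$biovolume_se else pc$concentration_se
  bp <- graphics::barplot(y, names.arg = pc$diameter_class_um,
                          xlab = "aggregate diameter class (um)",
                          ylab = paste0(which, if (which == "biovolume")
                            " (um^3/ml)" else " (objects/ml)"),
                          main = x$sample_id, ...)
  ok <- !is.na(se) & se > 0
  graphics::arrows(bp[ok], y[ok] - se[ok], bp[ok], y[ok] + se[ok],
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
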