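# Schema-validated TSV readers/writers and report rendering. TSV with a
# header line is the canonical interchange format (CSV accepted on read);
# UTF-8, '.' decimal separator. Writers are atomic: output appears only
# after a fully successful write.

read_delim_auto <- function(path) {
  if (!file.exists(path))
    stop_aq("file not found: ", path, class = "io_error")
  head_lines <- readLines(path, n = 50)
  first <- head_lines[!startsWith(head_lines, "#")][1]
  if (is.na(first))
    stop_aq(basename(path), ": no header line found", class = "schema_error")
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = TRUE)
}

write_tsv_atomic <- function(df, path, headers = NULL) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wt", encoding = "UTF-8")
  if (!is.null(headers)) writeLines(headers, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  close(con)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Read and write counts tables
#'
#' The counts TSV holds one row per (sample, replicate, field, object type,
#' diameter class) with columns `sample_id`, `replicate_id`, `field_id`,
#' `object_type` (`single_cell` or `aggregate`), `diameter_class_um` (`NA`
#' for single cells) and `count`. Validation rejects missing columns (named
#' in the error), negative or non-integer counts and duplicate keys (with
#' row numbers), and diameter classes outside the configured range.
#'
#' @param path File path (TSV canonical; CSV accepted on read).
#' @param diameter_classes Permitted aggregate classes (um).
#' @return `read_counts_table()` returns the validated data frame;
#'   writers return `path` invisibly.
#' @export
read_counts_table <- function(path, diameter_classes = 2:15) {
  validate_counts(read_delim_auto(path), diameter_classes,
                  context = basename(path))
}

#' @rdname read_counts_table
#' @param counts A counts data frame.
#' @export
write_counts_table <- function(counts, path) {
  counts <- validate_counts(counts)
  write_tsv_atomic(counts, path)
}

#' Read and write CARD-FISH probe-count tables
#'
#' Same schema as the counts table plus `probe_id` and the paired
#' `probe_count`/`dapi_count` columns; `probe_count` may not exceed
#' `dapi_count` in any row.
#'
#' @param path File path.
#' @param diameter_classes Permitted aggregate classes (um).
#' @return `read_probe_table()` returns the validated data frame; the
#'   writer returns `path` invisibly.
#' @export
read_probe_table <- function(path, diameter_classes = 2:15) {
  validate_probe_counts(read_delim_auto(path), diameter_classes,
                        context = basename(path))
}

#' @rdname read_probe_table
#' @param probes A probe-count data frame.
#' @export
write_probe_table <- function(probes, path) {
  probes <- validate_probe_counts(probes)
  write_tsv_atomic(probes, path)
}

#' Read and write clone-library tables
#'
#' Clone TSVs have columns `domain`, `group`, `count` plus one metadata
#' comment line per domain of the form
#' `# library domain=archaea clones_obtained=56 clones_sequenced=50`.
#'
#' @param path File path.
#' @return `read_clone_table()` returns a named list of [clone_library()]
#'   objects (one per domain); the writer returns `path` invisibly.
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path))
    stop_aq("file not found: ", path, class = "io_error")
  lines <- readLines(path)
  meta_lines <- grep("^# library ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- regmatches(ml, gregexpr("[a-z_]+=[^ ]+", ml))[[1]]
    vals <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
    meta[[vals[["domain"]]]] <- vals
  }
  df <- read_delim_auto(path)
  if (!all(c("domain", "group", "count") %in% names(df)))
    stop_aq(basename(path), ": clone table needs columns domain, group, ",
            "count", class = "schema_error")
  out <- lapply(unique(df$domain), function(d) {
    sub <- df[df$domain == d, ]
    counts <- stats::setNames(as.integer(sub$count), sub$group)
    m <- meta[[d]]
    clone_library(d, counts,
                  clones_sequenced = if (!is.null(m))
                    as.integer(m[["clones_sequenced"]]) else sum(counts),
                  clones_obtained = if (!is.null(m))
                    as.integer(m[["clones_obtained"]]) else sum(counts))
  })
  stats::setNames(out, unique(df$domain))
}

#' @rdname read_clone_table
#' @param libs A `clone_library` or list of them.
#' @export
write_clone_table <- function(libs, path) {
  if (inherits(libs, "clone_library")) libs <- list(libs)
  headers <- vapply(libs, function(l)
    sprintf("# library domain=%s clones_obtained=%d clones_sequenced=%d",
            l$domain, l$clones_obtained, l$clones_sequenced), character(1))
  df <- do.call(rbind, lapply(libs, function(l)
    data.frame(domain = l$domain, group = names(l$group_counts),
               count = as.integer(l$group_counts))))
  write_tsv_atomic(df, path, headers = headers)
}

#' Format a mean and standard error in scientific notation
#'
#' Renders `mean +/- se` as e.g. `"(1.28 ± 0.06)*10^9"`: both mantissas
#' share the exponent of the mean and are rounded to `digits` decimal
#' places.
#'
#' @param mean,se Numbers (se may be `NA`).
#' @param digits Decimal places of the mantissa.
#' @return A character string.
#' @examples
#' format_mean_se(1.28e9, 6e7)
#' @export
format_mean_se <- function(mean, se = NA, digits = 2) {
  if (is.na(mean)) return("NA")
  if (mean == 0) {
    e <- 0
  } else {
    e <- floor(log10(abs(mean)))
    # keep the mantissa in [1, 10) after rounding
    if (round(abs(mean) / 10^e, digits) >= 10) e <- e + 1
  }
  if (e >= -2 && e <= 2) {
    # moderate magnitudes print plainly (the style used for percentages)
    if (is.na(se)) sprintf("%.*f", digits, mean)
    else sprintf("%.*f ± %.*f", digits, mean, digits, se)
  } else if (is.na(se)) {
    sprintf("%.*f*10^%d", digits, mean / 10^e, e)
  } else {
    sprintf("(%.*f ± %.*f)*10^%d", digits, mean / 10^e,
            digits, se / 10^e, e)
  }
}

#' Render results as a human-readable report
#'
#' @param x A `group_composition`, `growth_estimate` or `sample_biovolume`.
#' @param ... Unused.
#' @return Character vector of report lines (empty results give the header
#'   only).
#' @export
render_report <- function(x, ...) UseMethod("render_report")

#' @export
render_report.group_composition <- function(x, ...) {
  cats <- c(cells = "% of cell count", aggregates = "% of aggregate count",
            biovolume = "% of biovolume")
  lines <- sprintf("%-12s%-22s%-22s%-22s", "Group", cats[1], cats[2],
                   cats[3])
  cell <- function(row) {
    if (nrow(row) == 0) return("-")
    if (row$below_detection) return("Below detection limit")
    se <- if (is.na(row$se)) "" else sprintf(" ± %.1f", 100 * row$se)
    sprintf("%.1f%s", 100 * row$mean, se)
  }
  for (g in unique(x$group)) {
    vals <- vapply(names(cats), function(cat)
      cell(x[x$group == g & x$category == cat, , drop = FALSE]),
      character(1))
    lines <- c(lines, sprintf("%-12s%-22s%-22s%-22s", g, vals[1], vals[2],
                              vals[3]))
  }
  lines
}

#' @export
render_report.growth_estimate <- function(x, ...) {
  lines <- sprintf("%-10s%-24s%-24s%10s%10s%12s", "Group", "V1 (um^3/ml)",
                   "V2 (um^3/ml)", "increase", "fold", "t_d (mo)")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    if (r$below_detection) {
      lines <- c(lines, sprintf("%-10sBelow detection limit", r$group))
      next
    }
    lines <- c(lines, sprintf(
      "%-10s%-24s%-24s%10.1f%10.1f%12s", r$group,
      format_mean_se(r$V1, r$V1_se), format_mean_se(r$V2, r$V2_se),
      r$increase_factor, r$fold_change,
      if (is.na(r$doubling_time_months)) "-" else
        sprintf("%.1f", r$doubling_time_months)))
  }
  lines
}

#' @export
render_report.sample_biovolume <- function(x, ...) {
  c(sprintf("Sample %s", x$sample_id),
    sprintf("  total biovolume: %s um^3/ml slurry",
            format_mean_se(x$total_biovolume[["mean"]],
                           x$total_biovolume[["se"]])),
    sprintf("  aggregate biovolume share: %.1f%%",
            100 * x$aggregate_share[["mean"]]))
}

#' Write a tidy TSV of composition or growth results
#'
#' @param x A `group_composition` or `growth_estimate`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_report_table <- function(x, path) {
  df <- as.data.frame(x)
  write_tsv_atomic(df, path)
}
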