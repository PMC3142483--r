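# 16S rRNA gene clone-library composition and FISH concordance

#' Construct a clone library
#'
#' A clone library is a per-domain table of sequenced 16S rRNA gene clones
#' classified into free-form phylogenetic group labels.
#'
#' @param domain `"archaea"` or `"bacteria"`.
#' @param group_counts Named integer vector: clones per phylogenetic group;
#'   must sum to `clones_sequenced`.
#' @param clones_sequenced Number of clones picked and sequenced (defaults to
#'   the sum of `group_counts`).
#' @param clones_obtained Number of clones obtained before picking; must be
#'   >= `clones_sequenced`.
#' @return An object of class `clone_library`.
#' @examples
#' clone_library("archaea", c("ANME-2a" = 44, "MBG-D" = 6),
#'               clones_obtained = 56)
#' @export
clone_library <- function(domain = c("archaea", "bacteria"), group_counts,
                          clones_sequenced = sum(group_counts),
                          clones_obtained = clones_sequenced) {
  domain <- match.arg(domain)
  if (length(group_counts) == 0L || is.null(names(group_counts)) ||
      any(!nzchar(names(group_counts))))
    stop_aq("group_counts must be a non-empty named vector",
            class = "invalid_input")
  check_counts_vector(group_counts, "group_counts")
  check_number(clones_sequenced, "clones_sequenced", lower = 1)
  check_number(clones_obtained, "clones_obtained", lower = 1)
  if (sum(group_counts) != clones_sequenced)
    stop_aq("group counts (", sum(group_counts),
            ") must sum to clones_sequenced (", clones_sequenced, ")",
            class = "invalid_input")
  if (clones_sequenced > clones_obtained)
    stop_aq("clones_sequenced cannot exceed clones_obtained",
            class = "invalid_input")
  structure(list(domain = domain,
                 group_counts = group_counts,
                 clones_sequenced = as.integer(clones_sequenced),
                 clones_obtained = as.integer(clones_obtained)),
            class = "clone_library")
}

#' Composition of a community
#'
#' @param x An object holding community counts.
#' @param ... Method arguments.
#' @return Named numeric vector of percentages.
#' @export
composition <- function(x, ...) UseMethod("composition")

#' @describeIn composition Percentage of each phylogenetic group among
#'   sequenced clones: `100 * count / clones_sequenced`; sums to 100.
#' @param digits Optional rounding of the percentages (the original report
#'   prints integers); `NULL` keeps full precision.
#' @export
composition.clone_library <- function(x, digits = NULL, ...) {
  pct <- 100 * x$group_counts / x$clones_sequenced
  if (!is.null(digits)) pct <- round(pct, digits)
  pct
}

#' @export
print.clone_library <- function(x, ...) {
  cat(sprintf("%s 16S clone library: %d sequenced of %d obtained\n",
              x$domain, x$clones_sequenced, x$clones_obtained))
  pct <- composition(x)
  for (g in names(pct))
    cat(sprintf("  %-28s %3d clones  %5.1f%%\n", g, x$group_counts[[g]],
                pct[[g]]))
  invisible(x)
}

#' Concordance between clone-library and CARD-FISH composition
#'
#' Cross-checks the two composition methods. For each mapped group the
#' report flags whether it was found in the clone library and/or detected by
#' FISH, and, for groups absent from the library but FISH-detected at
#' frequency `f`, the probability of drawing zero clones of the group in `n`
#' sequenced clones under multinomial sampling, `(1 - f)^n`. A small
#' probability flags a genuine discordance (e.g. possible
#' mis-hybridization) rather than sampling noise.
#'
#' @param lib A [clone_library()].
#' @param fish A `group_composition` (e.g. from [fish_composition()]).
#' @param mapping Named character vector mapping clone-library group labels
#'   to FISH group labels, e.g. `c("ANME-2a" = "ANME-2")`.
#' @param category FISH category whose fractions approximate the sampled
#'   community (`"aggregates"` by default, the dominant biomass form).
#' @return Data frame with columns `library_group`, `fish_group`,
#'   `clones`, `library_percent`, `fish_fraction`, `fish_below_detection`,
#'   `status` (`"concordant"`, `"library-only"`, `"fish-only"`,
#'   `"absent-both"`) and `p_absent_given_fish`.
#' @export
fish_concordance <- function(lib, fish, mapping,
                             category = "aggregates") {
  stopifnot(inherits(lib, "clone_library"),
            inherits(fish, "group_composition"))
  if (length(mapping) == 0L || is.null(names(mapping)))
    stop_aq("mapping must be a named character vector (library group -> ",
            "FISH group)", class = "mapping_error")
  sub <- fish[fish$category == category, , drop = FALSE]
  if (!any(mapping %in% sub$group))
    stop_aq("no mapped FISH groups found in the composition table",
            class = "mapping_error")
  rows <- lapply(names(mapping), function(lg) {
    fg <- mapping[[lg]]
    clones <- if (lg %in% names(lib$group_counts))
      lib$group_counts[[lg]] else 0L
    fr <- sub[sub$group == fg, , drop = FALSE]
    if (nrow(fr) == 0L)
      stop_aq("FISH group '", fg, "' not in composition table",
              class = "mapping_error")
    bd <- fr$below_detection[1]
    f <- if (bd) 0 else fr$mean[1]
    status <- if (clones > 0 && !bd) "concordant"
      else if (clones > 0 && bd) "library-only"
      else if (clones == 0 && !bd) "fish-only"
      else "absent-both"
    data.frame(library_group = lg, fish_group = fg, clones = clones,
               library_percent = 100 * clones / lib$clones_sequenced,
               fish_fraction = if (bd) NA_real_ else f,
               fish_below_detection = bd,
               status = status,
               p_absent_given_fish = if (clones == 0)
                 (1 - f)^lib$clones_sequenced else NA_real_)
  })
  do.call(rbind, rows)
}
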