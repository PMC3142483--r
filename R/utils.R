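# internal helpers: unit constants, validation, sub-seeding

# 1 ml = 1e12 um^3; mean Gregorian month in days
UM3_PER_ML <- 1e12
DAYS_PER_MONTH <- 30.44

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_aq <- function(..., class) {
  stop(structure(class = c(class, "aomquant_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x)))
    stop_aq(name, " must be a single number", class = "invalid_input")
  if (!is.na(x) && (x < lower || x > upper))
    stop_aq(name, " must be in [", lower, ", ", upper, "], got ", x,
            class = "invalid_input")
  invisible(x)
}

check_counts_vector <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) ||
      any(x != floor(x)))
    stop_aq(name, " must be non-negative integers", class = "validation_error")
  invisible(x)
}

#' Derive a reproducible sub-stream seed
#'
#' All stochastic stages derive their own seed from one global seed so that
#' adding a simulation stage never perturbs the random numbers drawn by an
#' earlier stage. Result is kept within the 32-bit integer range `set.seed()`
#' accepts.
#'
#' @param seed Integer global seed.
#' @param stream Integer stream index (>= 0), one per simulation stage.
#' @return A single integer usable with [set.seed()].
#' @keywords internal
sub_seed <- function(seed, stream) {
  check_number(seed, "seed")
  check_number(stream, "stream", lower = 0)
  as.integer((abs(seed) %% 1000003L) * 2017L + stream * 7919L) %% 2147483647L
}

# round to n significant figures, NA-safe
signif_na <- function(x, digits) ifelse(is.na(x), x, signif(x, digits))
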