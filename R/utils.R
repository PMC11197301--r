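# Shared helpers: seeding, rounding, percentage formatting, intervals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All stochastic operations route their seed through here so a single root
# seed gives byte-identical outputs without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Round half away from zero
#'
#' Unlike [round()], which rounds half to even, values exactly on the midpoint
#' are rounded away from zero (53.125 -> 53.13 at 2 digits). This is the
#' convention used when formatting published percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage of a count over a total
#'
#' @param numerator,denominator numeric; `denominator` must be non-zero.
#' @param digits decimal places (half-up rounding).
#' @return numeric percentage, e.g. `percent_of(4494, 27635)` is 16.26.
#' @export
percent_of <- function(numerator, denominator, digits = 2) {
  if (any(denominator == 0)) stop("denominator must be non-zero")
  round_half_up(100 * numerator / denominator, digits)
}

#' Format a percentage as printed in genome reports
#'
#' @inheritParams percent_of
#' @return character, e.g. `"16.26%"`.
#' @export
format_percent <- function(numerator, denominator, digits = 2) {
  sprintf(paste0("%.", digits, "f%%"), percent_of(numerator, denominator, digits))
}

#' Genomic interval (1-based, inclusive)
#'
#' All coordinates in this package are 1-based inclusive (GFF3 convention);
#' 0-based half-open inputs (PAF) are converted at the I/O boundary.
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return an object of class `"gd_interval"`.
#' @export
interval <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(chrom) == 1, length(start) == 1, length(end) == 1)
  if (is.na(start) || is.na(end) || start < 1 || end < start)
    stop("invalid interval: need 1 <= start <= end")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "gd_interval")
}

#' @export
print.gd_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s\n", x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ",")))
  invisible(x)
}

interval_width <- function(x) x$end - x$start + 1

# bp overlap of two intervals (0 if different chromosome or disjoint)
interval_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start) + 1)
}
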