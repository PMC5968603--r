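#' Weighted summary statistics for survey microdata
#'
#' Survey-weighted mean, standard deviation and lower weighted median.
#' The lower weighted median is the smallest observed value whose
#' cumulative weight reaches half the total weight; this is the
#' convention used throughout the package (medians of weekly welfare
#' payments are frequently degenerate at a flat payment rate, and the
#' lower median reports that rate rather than an interpolated value).
#'
#' @param x Numeric vector of values.
#' @param w Numeric vector of positive survey weights, recycled if of
#'   length 1.
#' @param na.rm Drop pairs where `x` is `NA`.
#' @return A single numeric value; `NA_real_` for empty input.
#' @examples
#' weighted_median(c(10, 20), c(1, 3)) # 20: 10 only covers 25% of weight
#' weighted_median(1:3, rep(1, 3))     # 2
#' @export
weighted_median <- function(x, w = rep(1, length(x)), na.rm = FALSE) {
  if (length(w) == 1L) w <- rep(w, length(x))
  stopifnot(length(x) == length(w))
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]; w <- w[keep]
  }
  if (length(x) == 0L) return(NA_real_)
  if (any(is.na(w)) || any(w <= 0)) stop("weights must be positive and non-missing")
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[match(TRUE, cw >= sum(w) / 2)]
}

#' @rdname weighted_median
#' @export
weighted_mean <- function(x, w = rep(1, length(x)), na.rm = FALSE) {
  if (length(w) == 1L) w <- rep(w, length(x))
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]; w <- w[keep]
  }
  if (length(x) == 0L) return(NA_real_)
  sum(w * x) / sum(w)
}

#' @rdname weighted_median
#' @export
weighted_sd <- function(x, w = rep(1, length(x)), na.rm = FALSE) {
  if (length(w) == 1L) w <- rep(w, length(x))
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]; w <- w[keep]
  }
  if (length(x) < 2L) return(NA_real_)
  m <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

#' Rounding helpers used for reported figures
#'
#' `round_half_away()` rounds half away from zero (the convention of the
#' reported tables, unlike base R's round-half-to-even). `round_1000()`
#' rounds headcounts to the nearest 1,000 as printed in national tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname round_half_away
#' @export
round_1000 <- function(x) round_half_away(x / 1000) * 1000

#' Percentage change between two reported values
#'
#' Headline growth figures are reported as integer percentages of the
#' baseline value, rounded half away from zero.
#'
#' @param v0 Baseline value (> 0).
#' @param v1 New value.
#' @return Integer percent change.
#' @examples
#' percent_change(54000, 61000) # 13
#' percent_change(1516, 2406)   # 59
#' @export
percent_change <- function(v0, v1) {
  if (any(v0 <= 0)) stop("baseline value must be positive")
  as.integer(round_half_away((v1 - v0) / v0 * 100))
}

#' Weighted population share as a printed percentage
#'
#' @param count Weighted count of the group.
#' @param total Weighted population total (> 0).
#' @return Share in percent, rounded half away from zero to 2 decimals.
#' @examples
#' share_pct(54000, 5945000)   # 0.91
#' share_pct(2912000, 5945000) # 48.98
#' @export
share_pct <- function(count, total) {
  if (any(total <= 0)) stop("population total must be positive")
  round_half_away(count / total * 100, 2)
}

# Deterministic per-stage seeds derived from one master seed, so that
# stages (generator, donors, matching, bootstrap) can be re-run in
# isolation. Kept below 2^31 - 1.
derive_seed <- function(master_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) %% 2147483647 * 31 + h * 2654435) %% 2147483647)
}
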