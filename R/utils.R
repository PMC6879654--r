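#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves rounded up (0.05 -> 0.1), the
#' convention used by clinical summary tables, rather than R's banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(0.25, 1)  # 0.3
#' round(0.25, 1)        # 0.2 (banker's)
#' @export
roundHalfUp <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Percentage of a count, table style
#'
#' `100 * count / total` rounded half-up to one decimal, the format used for
#' the n (%) entries of cohort summary tables.
#'
#' @param count,total non-negative counts, `total > 0`.
#' @return percentage rounded to one decimal.
#' @examples
#' percentHalfUp(269, 472)  # 57.0
#' @export
percentHalfUp <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  roundHalfUp(100 * count / total, 1)
}

## sample SEM: sd (n-1 denominator) / sqrt(n); 0 for constant samples, NA at n<2
semOf <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

## Moore-Penrose least squares via SVD, for singular designs
pinvCoef <- function(X, y, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1]
  drop(s$v[, keep, drop = FALSE] %*%
         ((crossprod(s$u[, keep, drop = FALSE], y)) / s$d[keep]))
}

## minutes-since-midnight from "HH:MM"
parseClockTime <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed injury_time (expected HH:MM): ",
         paste(x[bad], collapse = ", "))
  }
  hh <- vapply(m, function(z) as.numeric(z[2]), 1)
  mm <- vapply(m, function(z) as.numeric(z[3]), 1)
  if (any(hh > 23 | mm > 59)) stop("injury_time out of range: ",
                                   paste(x[hh > 23 | mm > 59], collapse = ", "))
  hh * 60 + mm
}

formatClockTime <- function(minutes) {
  sprintf("%02d:%02d", minutes %/% 60, minutes %% 60)
}
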