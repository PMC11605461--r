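#' Calendar-month arithmetic for lookback windows
#'
#' Maps a date to the same day-of-month `m` months earlier, clamping to the
#' end of the target month when the day does not exist there (e.g. 31 March
#' minus one month is 28/29 February). Lookback and trimming windows are
#' defined in calendar months, so all window boundaries go through this
#' helper.
#'
#' @param dates a `Date` vector.
#' @param m non-negative integer number of months to step back.
#' @return a `Date` vector of the same length.
#' @examples
#' monthsBefore(as.Date("2020-03-31"), 1)  # 2020-02-29
#' @export
monthsBefore <- function(dates, m) {
  stopifnot(inherits(dates, "Date"), length(m) == 1L, m >= 0)
  lt <- as.POSIXlt(dates)
  tot <- lt$year * 12L + lt$mon - as.integer(m)
  yr <- tot %/% 12L
  mo <- tot %% 12L
  # clamp day to length of target month
  dim <- daysInMonth(yr + 1900L, mo + 1L)
  day <- pmin(lt$mday, dim)
  as.Date(sprintf("%04d-%02d-%02d", yr + 1900L, mo + 1L, day))
}

daysInMonth <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  d[month == 2L & leap] <- 29L
  d
}

#' Parse ISO-8601 dates strictly
#'
#' `as.Date()` silently coerces some malformed strings; readers need a
#' strict parse that flags the offending row instead.
#'
#' @param x character vector of `YYYY-MM-DD` strings.
#' @return `Date` vector with `NA` where the string is not a valid date.
#' @keywords internal
parseIsoDate <- function(x) {
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out <- rep(as.Date(NA), length(x))
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y-%m-%d")
    # round-trip check catches impossible dates like 2020-13-01 / 2020-02-30
    d[!is.na(d) & format(d, "%Y-%m-%d") != x[ok]] <- NA
    out[ok] <- d
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# GELU in the tanh approximation used throughout the BERT family. The
# forward pass caches the tanh term so the backward pass avoids
# recomputing it (geluGradT).
GELU_C <- sqrt(2 / pi)
geluT <- function(x) {
  t <- tanh(GELU_C * (x + 0.044715 * (x * x * x)))
  list(y = 0.5 * x * (1 + t), t = t)
}
gelu <- function(x) geluT(x)$y
geluGradT <- function(x, t) {
  0.5 * (1 + t) + 0.5 * x * (1 - t * t) * GELU_C * (1 + 0.134145 * (x * x))
}
geluGrad <- function(x) geluGradT(x, tanh(GELU_C * (x + 0.044715 * (x * x * x))))

# row-wise softmax of a matrix, numerically stabilised
softmaxRows <- function(s) {
  n <- nrow(s)
  mx <- s[cbind(seq_len(n), max.col(s, ties.method = "first"))]
  e <- exp(s - mx)
  e / .rowSums(e, n, ncol(s))
}

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Derive a stream-specific RNG seed from a master seed
#'
#' Every stochastic stage draws its own seed from the run seed so that
#' stages can be re-run independently yet reproducibly. Kept below 2^31.
#'
#' @param seed master integer seed.
#' @param stream character label of the consumer.
#' @return an integer seed.
#' @keywords internal
deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# sample() without the undesirable scalar-x behaviour
sampleVec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
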