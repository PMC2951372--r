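#' Shared percentile convention
#'
#' Every quantile reported by the package (region medians, gene scores,
#' box-plot quartiles, methylation medians) uses the same linear-interpolation
#' rule on ascending order statistics: `h = (n - 1) * q`, value =
#' `x[floor(h) + 1] + (h - floor(h)) * (x[floor(h) + 2] - x[floor(h) + 1])`.
#' This is `stats::quantile()` type 7.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @param q probability in `[0, 1]`.
#' @return the interpolated quantile, or `NA_real_` if no finite value remains.
#' @export
pctl <- function(x, q) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  unname(stats::quantile(x, probs = q, type = 7, names = FALSE))
}

## integer midpoint of a 0-based half-open interval
interval_midpoint <- function(start, end) {
  floor((start + end) / 2)
}

## is each position inside any of the (0-based half-open) intervals?
point_in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  out <- logical(length(pos))
  for (i in seq_len(nrow(intervals))) {
    hit <- chrom == intervals$chrom[i] &
      pos >= intervals$start[i] & pos < intervals$end[i]
    out <- out | hit
  }
  out
}

## round a percentage to one decimal, the convention used in report tables
as_pct <- function(k, n) {
  if (n == 0) return(NA_real_)
  round(100 * k / n, 1)
}

#' Derive a stage-specific RNG seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds by hashing the stage
#' name, so each stage is independently reproducible.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
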