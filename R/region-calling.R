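#' Region-calling parameters
#'
#' @param score_threshold minimum probe score for a probe to qualify.
#' @param min_run minimum genomic span (bp) of a called region.
#' @param max_gap maximum allowed gap (bp) between the end of one qualifying
#'   probe and the start of the next within a region.
#' @param region_score how a region's score summarises its probes:
#'   maximum (default), mean, or 75th percentile.
#' @return object of class `region_call_params`.
#' @export
region_call_params <- function(score_threshold = 3.5, min_run = 300L,
                               max_gap = 200L,
                               region_score = c("max", "mean", "q75")) {
  if (min_run <= 0) stopf("min_run must be > 0")
  if (max_gap < 0) stopf("max_gap must be >= 0")
  structure(list(score_threshold = score_threshold, min_run = min_run,
                 max_gap = max_gap,
                 region_score = match.arg(region_score)),
            class = "region_call_params")
}

#' Call enriched regions from a score track
#'
#' Probes with score at or above the threshold are chained while the gap
#' between consecutive qualifying probes (`next start - previous end`) does
#' not exceed `max_gap`; each chain spans from its first probe's start to its
#' last probe's end, and chains whose span falls short of `min_run` are
#' discarded. Output regions are sorted and non-overlapping.
#'
#' @param scores score track data.frame (`chrom`, `start`, `end`, `score`),
#'   sorted by (chrom, start).
#' @param params a [region_call_params()].
#' @return data.frame `region_id`, `chrom`, `start`, `end`, `n_probes`,
#'   `region_score`.
#' @export
call_regions <- function(scores, params = region_call_params()) {
  stopifnot(inherits(params, "region_call_params"))
  ord <- order(scores$chrom, scores$start)
  if (!identical(ord, seq_len(nrow(scores))))
    stopf("score track must be sorted by (chrom, start)")
  summarise <- switch(params$region_score,
                      max = max, mean = mean, q75 = function(x) pctl(x, 0.75))
  rows <- list()
  for (cn in unique(scores$chrom)) {
    sub <- scores[scores$chrom == cn, , drop = FALSE]
    q <- which(sub$score >= params$score_threshold)
    if (length(q) == 0L) next
    gaps <- sub$start[q][-1L] - sub$end[q][-length(q)]
    chain <- cumsum(c(TRUE, gaps > params$max_gap))
    for (cid in unique(chain)) {
      qi <- q[chain == cid]
      s <- sub$start[qi[1L]]
      e <- sub$end[qi[length(qi)]]
      if (e - s < params$min_run) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, start = s, end = e, n_probes = length(qi),
        region_score = summarise(sub$score[qi]), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_probes = integer(), region_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  reg <- do.call(rbind, rows)
  reg <- reg[order(reg$chrom, reg$start), , drop = FALSE]
  reg <- cbind(region_id = sprintf("region_%05d", seq_len(nrow(reg))), reg,
               stringsAsFactors = FALSE)
  rownames(reg) <- NULL
  reg
}

#' Summarise a set of called regions
#'
#' @param regions regions data.frame from [call_regions()].
#' @param spec a [genome_spec()]; supplies total genome length and the
#'   heterochromatin partition (a region is heterochromatic when its midpoint
#'   falls inside a heterochromatin interval).
#' @return list with `n_regions`, `total_bp`, `genome_fraction`,
#'   `median_length` (`NA` when empty), `n_heterochromatic`,
#'   `heterochromatic_fraction`, and `pct_heterochromatic` (one decimal).
#' @export
region_summary <- function(regions, spec) {
  stopifnot(inherits(spec, "genome_spec"))
  n <- nrow(regions)
  lens <- regions$end - regions$start
  total <- sum(lens)
  genome <- sum(spec$chromosomes$length)
  mids <- interval_midpoint(regions$start, regions$end)
  het <- point_in_intervals(regions$chrom, mids, spec$heterochromatin)
  list(n_regions = n,
       total_bp = total,
       genome_fraction = total / genome,
       median_length = if (n > 0) pctl(lens, 0.5) else NA_real_,
       n_heterochromatic = sum(het),
       heterochromatic_fraction = if (n > 0) sum(het) / n else NA_real_,
       pct_heterochromatic = if (n > 0) as_pct(sum(het), n) else NA_real_)
}

#' Histogram of region lengths
#'
#' @param regions regions data.frame.
#' @param bin_width histogram bin width, bp (> 0).
#' @return data.frame `bin_start`, `bin_end` (half-open bins), `count`;
#'   counts sum to the number of regions.
#' @export
length_histogram <- function(regions, bin_width = 100L) {
  if (bin_width <= 0) stopf("bin_width must be > 0")
  lens <- regions$end - regions$start
  if (length(lens) == 0L) {
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  }
  idx <- floor(lens / bin_width)
  top <- max(idx)
  counts <- tabulate(idx + 1L, nbins = top + 1L)
  data.frame(bin_start = (0:top) * bin_width,
             bin_end = (1:(top + 1L)) * bin_width,
             count = counts)
}
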