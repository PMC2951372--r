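#' Scoring parameters
#'
#' @param window_size sliding-window width, bp; probes whose start lies within
#'   `window_size / 2` of the focal probe's start contribute to its score.
#' @param trim_fraction proportion trimmed from each end of the window values
#'   before averaging (`floor(trim_fraction * n)` values per end).
#' @param n_affinity_bins number of affinity quantile bins used for
#'   standardization.
#' @param scale_floor lower bound on the per-bin scale estimate, guarding
#'   degenerate bins.
#' @param robust standardize with median/MAD (default) or mean/SD.
#' @return object of class `scoring_params`.
#' @export
scoring_params <- function(window_size = 500L, trim_fraction = 0.10,
                           n_affinity_bins = 20L, scale_floor = 1e-6,
                           robust = TRUE) {
  if (window_size <= 0) stopf("window_size must be > 0")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stopf("trim_fraction must lie in [0, 0.5)")
  if (n_affinity_bins < 1) stopf("n_affinity_bins must be >= 1")
  if (scale_floor <= 0) stopf("scale_floor must be > 0")
  structure(list(window_size = window_size, trim_fraction = trim_fraction,
                 n_affinity_bins = n_affinity_bins, scale_floor = scale_floor,
                 robust = robust),
            class = "scoring_params")
}

## quantile bins of the affinity covariate; collapses ties with a warning
affinity_bins <- function(affinity, n_bins) {
  br <- unique(stats::quantile(affinity, probs = seq(0, 1,
                                                     length.out = n_bins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(affinity)))
  eff <- length(br) - 1L
  if (eff < n_bins)
    warnf("affinity bins collapsed from %d to %d (too few distinct values)",
          n_bins, eff)
  cut(affinity, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Standardize probe intensities within affinity bins
#'
#' Probes are partitioned into quantile bins of the affinity covariate (bin
#' membership identical across channels and replicates); within each bin and
#' channel/replicate the intensities are centred and scaled,
#' `t = (x - location) / max(scale, scale_floor)`, with location/scale the
#' median and `1.4826 * MAD` (or mean/SD when `robust = FALSE`). This removes
#' probe-affinity structure before enrichment contrasts are formed.
#'
#' @param track a [probe_track()].
#' @param params a [scoring_params()].
#' @return the track with a `standardized` list of matrices attached.
#' @export
standardize_probes <- function(track, params = scoring_params()) {
  stopifnot(inherits(track, "probe_track"),
            inherits(params, "scoring_params"))
  n <- nrow(track$probes)
  n_bins <- min(params$n_affinity_bins, n)
  if (n_bins < params$n_affinity_bins)
    warnf("fewer probes than affinity bins; collapsed to %d bin(s)", n_bins)
  bin <- affinity_bins(track$probes$affinity, n_bins)
  idx <- split(seq_len(n), bin)
  track$standardized <- lapply(track$intensity, function(m) {
    out <- m
    for (j in seq_len(ncol(m))) {
      x <- m[, j]
      for (ii in idx) {
        if (params$robust) {
          loc <- stats::median(x[ii])
          sc <- stats::mad(x[ii], center = loc)  # 1.4826 * median |x - med|
        } else {
          loc <- mean(x[ii])
          sc <- stats::sd(x[ii]); if (is.na(sc)) sc <- 0
        }
        out[ii, j] <- (x[ii] - loc) / max(sc, params$scale_floor)
      }
    }
    out
  })
  track
}

#' Per-probe enrichment against both controls, averaged
#'
#' For each control channel, the replicate-mean standardized difference
#' `mean_r(t_IP - t_control)` is computed; the per-control contrasts are then
#' averaged with equal weight.
#'
#' @param track a standardized [probe_track()].
#' @param controls control channels to contrast against.
#' @return the track with a numeric `enrichment` vector attached.
#' @export
enrichment_signal <- function(track, controls = c("input", "IgG")) {
  stopifnot(inherits(track, "probe_track"))
  if (is.null(track$standardized))
    stopf("standardize_probes() must be run first")
  missing_ch <- setdiff(controls, names(track$standardized))
  if (length(missing_ch) > 0L)
    stopf("missing control channel: %s", paste(missing_ch, collapse = ", "))
  tIP <- track$standardized$IP
  per_control <- vapply(controls, function(ch) {
    rowMeans(tIP - track$standardized[[ch]])
  }, numeric(nrow(tIP)))
  track$enrichment <- rowMeans(as.matrix(per_control))
  track
}

## trimmed-mean * sqrt(retained n) over a value vector
trimmed_window_score <- function(v, trim) {
  n <- length(v)
  drop <- floor(trim * n)
  if (drop > 0L) {
    v <- sort(v)[(drop + 1L):(n - drop)]
  }
  mean(v) * sqrt(length(v))
}

#' Windowed MAT-style probe scores
#'
#' For each probe, the enrichment values of all probes on the same chromosome
#' whose start lies within `window_size / 2` of the focal probe's start are
#' pooled; `floor(trim_fraction * n)` values are removed from each end of the
#' sorted pool and the score is `mean(retained) * sqrt(m)` with `m` the
#' retained count. Windows never cross chromosomes, and the focal probe is
#' always in its own window, so scores are defined for every probe.
#'
#' @param track a [probe_track()] with enrichment values, or a data.frame
#'   with columns `chrom`, `start`, `end`, `enrichment` (sorted).
#' @param params a [scoring_params()].
#' @return data.frame `probe_id`, `chrom`, `start`, `end`, `score` sorted by
#'   (chrom, start) — a score track.
#' @export
mat_score <- function(track, params = scoring_params()) {
  stopifnot(inherits(params, "scoring_params"))
  if (inherits(track, "probe_track")) {
    if (is.null(track$enrichment))
      stopf("enrichment_signal() must be run first")
    df <- track$probes
    df$enrichment <- track$enrichment
  } else {
    df <- track
    if (is.null(df$probe_id)) df$probe_id <- sprintf("p%07d", seq_len(nrow(df)))
  }
  ord <- order(df$chrom, df$start)
  if (!identical(ord, seq_len(nrow(df))))
    stopf("probes must be sorted by (chrom, start)")
  half <- params$window_size / 2
  score <- numeric(nrow(df))
  for (cn in unique(df$chrom)) {
    sel <- which(df$chrom == cn)
    s <- df$start[sel]
    e <- df$enrichment[sel]
    lo <- findInterval(s - half, s, left.open = TRUE) + 1L
    hi <- findInterval(s + half, s)
    score[sel] <- vapply(seq_along(sel), function(i) {
      trimmed_window_score(e[lo[i]:hi[i]], params$trim_fraction)
    }, numeric(1))
  }
  data.frame(probe_id = df$probe_id, chrom = df$chrom, start = df$start,
             end = df$end, score = score, stringsAsFactors = FALSE)
}

#' Score a probe track end to end
#'
#' Convenience wrapper: standardize, contrast against both controls, window.
#'
#' @inheritParams standardize_probes
#' @return a score track data.frame (see [mat_score()]).
#' @export
score_track <- function(track, params = scoring_params()) {
  mat_score(enrichment_signal(standardize_probes(track, params)), params)
}
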