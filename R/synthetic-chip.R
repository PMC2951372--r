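#' Plant ground-truth enrichment domains over annotated features
#'
#' Selects features per type to be true H3K27me3 targets and places one
#' enrichment domain over each selected feature's body, padded symmetrically
#' to at least `min_length` so that the minimum-run constraint of the region
#' caller is exercised on both flanks. Overlapping candidate domains are
#' dropped (the later feature is skipped) so truth domains are disjoint.
#'
#' @param spec a [genome_spec()].
#' @param annotation annotation data.frame from [generate_annotation()].
#' @param n_targets named integer vector of true targets per feature type.
#' @param effect domain effect size on log2 intensity (equivalently, in
#'   standardized-score units when the simulated noise SD is 1).
#' @param min_length minimum domain length, bp.
#' @param min_separation minimum distance between truth domains, bp;
#'   candidates closer than this to an accepted domain are skipped so that
#'   each domain is individually resolvable by a 500-bp window.
#' @param seed RNG seed.
#' @return an object of class `sim_truth`: list with `domains` (data.frame
#'   `chrom`, `start`, `end`, `effect`), `target_ids`, and `target_flag`
#'   (named logical over all features).
#' @export
simulate_truth <- function(spec, annotation,
                           n_targets = c(gene = 55L, pseudogene = 4L,
                                         TE = 6L, TEG = 9L),
                           effect = 2.0, min_length = 600L,
                           min_separation = 1000L, seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  if (effect <= 0) stopf("domain effect sizes must be > 0")
  set.seed(seed)
  chosen <- character()
  for (type in names(n_targets)) {
    pool <- annotation$feature_id[annotation$feature_type == type]
    n <- min(n_targets[[type]], length(pool))
    if (n > 0) chosen <- c(chosen, sample(pool, n))
  }
  rows <- list(); kept <- character()
  occupied <- list()
  for (id in chosen) {
    f <- annotation[annotation$feature_id == id, ]
    L <- spec$chromosomes$length[spec$chromosomes$name == f$chrom]
    pad <- max(0, ceiling((min_length - (f$end - f$start)) / 2))
    s <- max(0L, f$start - pad); e <- min(L, f$end + pad)
    occ <- occupied[[f$chrom]]
    if (!is.null(occ) &&
        any(s - min_separation < occ$end & occ$start < e + min_separation))
      next
    occupied[[f$chrom]] <- rbind(occ, data.frame(start = s, end = e))
    rows[[length(rows) + 1L]] <- data.frame(chrom = f$chrom, start = s,
                                            end = e, effect = effect,
                                            stringsAsFactors = FALSE)
    kept <- c(kept, id)
  }
  domains <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               effect = numeric())
  domains <- domains[order(domains$chrom, domains$start), , drop = FALSE]
  rownames(domains) <- NULL
  flag <- stats::setNames(annotation$feature_id %in% kept,
                          annotation$feature_id)
  structure(list(domains = domains, target_ids = sort(kept),
                 target_flag = flag),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$domains), "domain(s) over",
      length(x$target_ids), "target feature(s)\n")
  invisible(x)
}

#' Probe track container
#'
#' Bundles a probe layout with per-channel, per-replicate log2 intensity
#' matrices (channels IP, input, IgG). Standardized values, per-probe
#' enrichment and windowed scores are attached by the scoring functions.
#'
#' @param probes data.frame `probe_id`, `chrom`, `start`, `end`, `affinity`.
#' @param intensity named list of numeric matrices (`IP`, `input`, `IgG`),
#'   one row per probe, one column per replicate.
#' @return object of class `probe_track`.
#' @export
probe_track <- function(probes, intensity) {
  need <- c("probe_id", "chrom", "start", "end", "affinity")
  stopifnot(is.data.frame(probes), all(need %in% names(probes)))
  stopifnot(is.list(intensity), all(c("IP", "input", "IgG") %in%
                                      names(intensity)))
  ord <- order(probes$chrom, probes$start)
  probes <- probes[ord, , drop = FALSE]
  rownames(probes) <- NULL
  intensity <- lapply(intensity, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != nrow(probes)) stopf("intensity rows must match probes")
    m[ord, , drop = FALSE]
  })
  if (anyDuplicated(probes[c("chrom", "start", "probe_id")]))
    stopf("duplicate (chrom, start, id) probes")
  for (ch in names(intensity)) {
    bad <- which(!is.finite(intensity[[ch]]), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stopf("non-finite %s intensity at probe %s", ch,
            probes$probe_id[bad[1L, 1L]])
  }
  structure(list(probes = probes, intensity = intensity,
                 standardized = NULL, enrichment = NULL, score = NULL),
            class = "probe_track")
}

#' @export
print.probe_track <- function(x, ...) {
  cat("probe_track:", nrow(x$probes), "probes,",
      ncol(x$intensity$IP), "replicate(s) x 3 channels;",
      "standardized:", !is.null(x$standardized),
      "| scored:", !is.null(x$score), "\n")
  invisible(x)
}

#' Simulate ChIP-chip probe intensities with embedded enrichment domains
#'
#' Log2 intensity = `baseline + affinity_effect * affinity + domain effect
#' (IP channel only, probes whose midpoint lies inside a truth domain) +
#' Normal(0, noise_sd)`. Input and IgG channels share the null model, so the
#' enrichment contrast against either control recovers the domain effect.
#'
#' @param layout probe layout from [generate_probes()].
#' @param truth a `sim_truth` object (its domains must lie inside the
#'   chromosomes spanned by the layout).
#' @param noise_sd per-observation Gaussian noise SD on log2 scale (> 0).
#'   At the default of 1, a domain effect is expressed in the same units as
#'   the standardized scores downstream.
#' @param affinity_effect slope of the probe-affinity covariate.
#' @param n_reps replicates per channel (>= 1).
#' @param baseline mean log2 intensity.
#' @param seed RNG seed.
#' @return a [probe_track()] with attribute `truth`.
#' @export
simulate_chip <- function(layout, truth = NULL, noise_sd = 1.0,
                          affinity_effect = 1.0, n_reps = 3L,
                          baseline = 10, seed = 1L) {
  if (n_reps < 1L) stopf("n_reps must be >= 1")
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  set.seed(seed)
  n <- nrow(layout)
  mid <- interval_midpoint(layout$start, layout$end)
  effect <- numeric(n)
  if (!is.null(truth) && nrow(truth$domains) > 0L) {
    chrom_max <- tapply(layout$end, layout$chrom, max)
    for (i in seq_len(nrow(truth$domains))) {
      d <- truth$domains[i, ]
      if (!d$chrom %in% names(chrom_max) || d$start < 0)
        stopf("truth domain outside the probed chromosomes")
      inside <- layout$chrom == d$chrom & mid >= d$start & mid < d$end
      effect[inside] <- effect[inside] + d$effect
    }
  }
  base_mean <- baseline + affinity_effect * layout$affinity
  mk <- function(extra) {
    m <- matrix(stats::rnorm(n * n_reps, sd = noise_sd), n, n_reps)
    m <- m + base_mean + extra
    colnames(m) <- paste0("rep", seq_len(n_reps))
    m
  }
  track <- probe_track(layout, list(IP = mk(effect), input = mk(0),
                                    IgG = mk(0)))
  attr(track, "truth") <- truth
  track
}
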