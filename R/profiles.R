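#' Profiling parameters
#'
#' @param body_bins number of equal-length bins across the gene body
#'   (20 bins = 5 percent length intervals).
#' @param flank_bp length of each flank, bp.
#' @param flank_bin_bp fixed flank bin width, bp; must divide `flank_bp`.
#' @param density_window_bp window for chromosomal density profiles, bp.
#' @return object of class `profile_params`.
#' @export
profile_params <- function(body_bins = 20L, flank_bp = 2000L,
                           flank_bin_bp = 100L,
                           density_window_bp = 200000L) {
  if (body_bins < 1) stopf("body_bins must be >= 1")
  if (flank_bp %% flank_bin_bp != 0)
    stopf("flank_bp must be divisible by flank_bin_bp")
  if (density_window_bp <= 0) stopf("density_window_bp must be > 0")
  structure(list(body_bins = as.integer(body_bins),
                 flank_bp = as.integer(flank_bp),
                 flank_bin_bp = as.integer(flank_bin_bp),
                 density_window_bp = as.integer(density_window_bp)),
            class = "profile_params")
}

## metagene bin index (1..2*nf+body) for probe starts p relative to one gene,
## or NA when outside the profiled span; strand-aware (bin 1 = 5' flank end)
metagene_bin <- function(p, gstart, gend, strand, params) {
  nf <- params$flank_bp %/% params$flank_bin_bp
  nb <- params$body_bins
  len <- gend - gstart
  if (strand == "+") {
    up <- p >= gstart - params$flank_bp & p < gstart
    body <- p >= gstart & p < gend
    down <- p >= gend & p < gend + params$flank_bp
    b <- rep(NA_integer_, length(p))
    b[up] <- (p[up] - (gstart - params$flank_bp)) %/% params$flank_bin_bp + 1L
    b[body] <- nf + pmin(nb, floor((p[body] - gstart) / len * nb) + 1L)
    b[down] <- nf + nb + (p[down] - gend) %/% params$flank_bin_bp + 1L
  } else {
    up <- p >= gend & p < gend + params$flank_bp
    body <- p >= gstart & p < gend
    down <- p >= gstart - params$flank_bp & p < gstart
    b <- rep(NA_integer_, length(p))
    b[up] <- (gend + params$flank_bp - 1L - p[up]) %/% params$flank_bin_bp + 1L
    b[body] <- nf + pmin(nb, floor((gend - 1L - p[body]) / len * nb) + 1L)
    b[down] <- nf + nb + (gstart - 1L - p[down]) %/% params$flank_bin_bp + 1L
  }
  b
}

#' Metagene score profile
#'
#' Averages probe scores over a gene set after rescaling each gene body to
#' `body_bins` fixed-fraction bins (5' to 3', respecting strand) and the 2-kb
#' flanks to fixed-width bins. A probe contributes to the bin containing its
#' start. By default all contributing probes are pooled across genes
#' (`average = "pooled"`); `"per_gene"` first averages within genes.
#'
#' @param scores score track data.frame.
#' @param genes annotation rows to profile (non-empty, with strand).
#' @param params a [profile_params()].
#' @param average pooled-probe or per-gene averaging.
#' @return data.frame `bin`, `zone` (`upstream`/`body`/`downstream`),
#'   `mean_score`, `n_probes` (`mean_score` is `NA` for empty bins).
#' @export
metagene_profile <- function(scores, genes, params = profile_params(),
                             average = c("pooled", "per_gene")) {
  average <- match.arg(average)
  if (nrow(genes) == 0L) stopf("gene_set must be non-empty")
  if (any(!genes$strand %in% c("+", "-"))) {
    warnf("unstranded features treated as plus strand")
    genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  }
  nf <- params$flank_bp %/% params$flank_bin_bp
  n_bins <- 2L * nf + params$body_bins
  sums <- numeric(n_bins); counts <- integer(n_bins)
  pg_sum <- numeric(n_bins); pg_n <- integer(n_bins)
  by_chrom <- split(seq_len(nrow(scores)), scores$chrom)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    idx <- by_chrom[[g$chrom]]
    if (is.null(idx)) next
    s <- scores$start[idx]
    keep <- s >= g$start - params$flank_bp & s < g$end + params$flank_bp
    if (!any(keep)) next
    b <- metagene_bin(s[keep], g$start, g$end, g$strand, params)
    v <- scores$score[idx][keep]
    ok <- !is.na(b)
    if (!any(ok)) next
    bs <- tapply(v[ok], b[ok], sum)
    bn <- tapply(v[ok], b[ok], length)
    ii <- as.integer(names(bs))
    sums[ii] <- sums[ii] + bs
    counts[ii] <- counts[ii] + bn
    pg_sum[ii] <- pg_sum[ii] + bs / bn
    pg_n[ii] <- pg_n[ii] + 1L
  }
  mean_score <- if (average == "pooled") {
    ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  } else {
    ifelse(pg_n > 0, pg_sum / pmax(pg_n, 1L), NA_real_)
  }
  zone <- c(rep("upstream", nf), rep("body", params$body_bins),
            rep("downstream", nf))
  data.frame(bin = seq_len(n_bins), zone = zone, mean_score = mean_score,
             n_probes = counts)
}

#' Chromosomal density of regions and features
#'
#' Tiles each chromosome with non-overlapping windows and counts regions,
#' genes, and TEs/TEGs by the window containing their midpoint; window counts
#' sum exactly to the element counts.
#'
#' @param regions regions data.frame.
#' @param features annotation data.frame.
#' @param spec a [genome_spec()].
#' @param params a [profile_params()] (supplies the window size).
#' @return data.frame `chrom`, `win_start`, `win_end`, `n_regions`,
#'   `n_genes`, `n_tes`.
#' @export
chromosome_density <- function(regions, features, spec,
                               params = profile_params()) {
  w <- params$density_window_bp
  count_mid <- function(df, cn, nwin) {
    if (nrow(df) == 0L) return(integer(nwin))
    sub <- df[df$chrom == cn, , drop = FALSE]
    if (nrow(sub) == 0L) return(integer(nwin))
    mids <- interval_midpoint(sub$start, sub$end)
    tabulate(pmin(mids %/% w + 1L, nwin), nbins = nwin)
  }
  out <- list()
  for (i in seq_len(nrow(spec$chromosomes))) {
    cn <- spec$chromosomes$name[i]; L <- spec$chromosomes$length[i]
    nwin <- ceiling(L / w)
    ws <- (seq_len(nwin) - 1L) * w
    out[[i]] <- data.frame(
      chrom = cn, win_start = ws, win_end = pmin(ws + w, L),
      n_regions = count_mid(regions, cn, nwin),
      n_genes = count_mid(features[features$feature_type == "gene", ,
                                   drop = FALSE], cn, nwin),
      n_tes = count_mid(features[features$feature_type %in% c("TE", "TEG"), ,
                                 drop = FALSE], cn, nwin))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Five-number score summaries by target class and expression stratum
#'
#' Groups gene scores by target class; when log2 expression values are
#' supplied, classes are further split into low/moderate expression strata at
#' `expr_split` (default log2 = 4.2). Quartiles follow the shared percentile
#' convention. Empty groups are omitted.
#'
#' @param calls target-call table.
#' @param expression optional named numeric vector of log2 expression.
#' @param expr_split log2 expression split point.
#' @param classes target classes to summarise.
#' @return data.frame `class`, `stratum`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
score_by_group <- function(calls, expression = NULL, expr_split = 4.2,
                           classes = c("shared", "specific")) {
  rows <- list()
  five <- function(x) c(min = min(x), q1 = pctl(x, 0.25),
                        median = pctl(x, 0.5), q3 = pctl(x, 0.75),
                        max = max(x))
  for (cl in classes) {
    sub <- calls[calls$target_class == cl & !is.na(calls$gene_score), ,
                 drop = FALSE]
    if (nrow(sub) == 0L) next
    strata <- if (is.null(expression)) list(all = rep(TRUE, nrow(sub))) else {
      ex <- expression[sub$feature_id]
      list(low = !is.na(ex) & ex < expr_split,
           moderate = !is.na(ex) & ex >= expr_split)
    }
    for (st in names(strata)) {
      x <- sub$gene_score[strata[[st]]]
      if (length(x) == 0L) next
      f <- five(x)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, stratum = st, n = length(x), min = f[["min"]],
        q1 = f[["q1"]], median = f[["median"]], q3 = f[["q3"]],
        max = f[["max"]])
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(class = character(), stratum = character(),
                      n = integer(), min = numeric(), q1 = numeric(),
                      median = numeric(), q3 = numeric(), max = numeric()))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Plot a metagene profile
#'
#' @param profile output of [metagene_profile()] (optionally a second profile
#'   for comparison, e.g. non-targets).
#' @param comparison optional second profile drawn in black.
#' @param ... passed to [graphics::plot()].
#' @export
plot_metagene_profile <- function(profile, comparison = NULL, ...) {
  graphics::plot(profile$bin, profile$mean_score, type = "l", col = "red",
                 xlab = "bin (5' flank | body | 3' flank)",
                 ylab = "mean score", ...)
  if (!is.null(comparison))
    graphics::lines(comparison$bin, comparison$mean_score, col = "black")
  nf <- sum(profile$zone == "upstream")
  nb <- sum(profile$zone == "body")
  graphics::abline(v = c(nf + 0.5, nf + nb + 0.5), lty = 2, col = "grey")
  invisible(profile)
}
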