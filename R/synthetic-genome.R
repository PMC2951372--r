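#' Genome specification for the synthetic data generator
#'
#' Defines the chromosomes and the centromeric/pericentromeric heterochromatin
#' partition used throughout the pipeline (chromosomal density profiles,
#' heterochromatin fractions of regions and features).
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param heterochromatin data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), non-overlapping per chromosome and within bounds.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes, heterochromatin = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) stopf("chromosome lengths must be > 0")
  if (anyDuplicated(chromosomes$name)) stopf("duplicate chromosome names")
  if (is.null(heterochromatin)) {
    heterochromatin <- data.frame(chrom = character(), start = integer(),
                                  end = integer())
  }
  if (nrow(heterochromatin) > 0L) {
    m <- match(heterochromatin$chrom, chromosomes$name)
    if (anyNA(m)) stopf("heterochromatin interval on unknown chromosome")
    if (any(heterochromatin$start < 0) ||
        any(heterochromatin$end > chromosomes$length[m]))
      stopf("heterochromatin interval outside chromosome bounds")
    if (any(heterochromatin$end <= heterochromatin$start))
      stopf("heterochromatin intervals must satisfy start < end")
    for (cn in unique(heterochromatin$chrom)) {
      h <- heterochromatin[heterochromatin$chrom == cn, , drop = FALSE]
      h <- h[order(h$start), , drop = FALSE]
      if (nrow(h) > 1L && any(h$start[-1L] < h$end[-nrow(h)]))
        stopf("overlapping heterochromatin intervals on %s", cn)
    }
  }
  structure(list(chromosomes = chromosomes,
                 heterochromatin = heterochromatin),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", nrow(x$chromosomes), "chromosome(s),",
      sum(x$chromosomes$length), "bp total,",
      nrow(x$heterochromatin), "heterochromatin interval(s)\n")
  invisible(x)
}

#' Default synthetic genome
#'
#' A scaled-down two-chromosome genome. Each chromosome carries one central
#' heterochromatin block covering `het_fraction` of its length, mimicking the
#' pericentromeric organisation of the Arabidopsis genome at a size small
#' enough for fast end-to-end runs.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome, bp.
#' @param het_fraction fraction of each chromosome occupied by the central
#'   heterochromatin block (the genome-wide TE heterochromatin fraction of
#'   roughly 16 percent motivates the default).
#' @return a [genome_spec()].
#' @export
default_genome_spec <- function(n_chrom = 2L, chrom_length = 2500000L,
                                het_fraction = 0.16) {
  stopifnot(n_chrom >= 1L, chrom_length > 0, het_fraction >= 0,
            het_fraction < 1)
  nm <- paste0("chr", seq_len(n_chrom))
  half <- het_fraction / 2
  het <- data.frame(
    chrom = nm,
    start = as.integer(round(chrom_length * (0.5 - half))),
    end   = as.integer(round(chrom_length * (0.5 + half)))
  )
  het <- het[het$end > het$start, , drop = FALSE]
  genome_spec(data.frame(name = nm,
                         length = rep(as.integer(chrom_length), n_chrom)),
              het)
}

te_superfamily_defaults <- function() {
  c("LTR/GYPSY" = 0.25, "LTR/COPIA" = 0.15, "LINE/L1" = 0.10,
    "SINE/RathE1" = 0.05, "DNA/MuDR" = 0.15, "DNA/EnSpm" = 0.10,
    "RC/Helitron" = 0.15, "DNA/HAT" = 0.05)
}

## sample a feature length (bp) per type; lognormal bodies, floored
sample_feature_length <- function(type, n) {
  meanlog <- switch(type, gene = log(2000), pseudogene = log(900),
                    TE = log(1500), TEG = log(2500))
  pmax(300L, as.integer(round(stats::rlnorm(n, meanlog, 0.45))))
}

#' Generate a synthetic genome annotation
#'
#' Places genes, pseudogenes, transposable elements (TEs) and transposable
#' element genes (TEGs) on the genome without overlap within each feature
#' type. TEs/TEGs land inside heterochromatin with a type-specific bias;
#' genes and pseudogenes are placed in euchromatin, mirroring the gene-poor,
#' TE-rich character of pericentromeric regions.
#'
#' @param spec a [genome_spec()].
#' @param counts named integer vector over `gene`, `pseudogene`, `TE`, `TEG`.
#' @param superfamily_weights named numeric weights for TE/TEG superfamilies
#'   (normalised internally).
#' @param te_heterochromatin_bias probability that a TE (and TEG) is placed in
#'   heterochromatin; a single number or a named vector `c(TE=, TEG=)`.
#'   Defaults mirror the genome-wide values of 16 percent of TEs and
#'   46 percent of TEGs.
#' @param seed integer RNG seed.
#' @param max_tries placement retries per feature before failing.
#' @return data.frame with columns `feature_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `feature_type`, `superfamily` (empty for
#'   genes and pseudogenes).
#' @export
generate_annotation <- function(spec,
                                counts = c(gene = 1100L, pseudogene = 40L,
                                           TE = 400L, TEG = 100L),
                                superfamily_weights = te_superfamily_defaults(),
                                te_heterochromatin_bias = c(TE = 0.16,
                                                            TEG = 0.46),
                                seed = 1L, max_tries = 200L) {
  stopifnot(inherits(spec, "genome_spec"))
  types <- c("gene", "pseudogene", "TE", "TEG")
  cnt <- stats::setNames(integer(4L), types)
  cnt[names(counts)] <- as.integer(counts)
  if (any(cnt < 0)) stopf("feature counts must be >= 0")
  if (length(te_heterochromatin_bias) == 1L && is.null(names(te_heterochromatin_bias)))
    te_heterochromatin_bias <- c(TE = te_heterochromatin_bias,
                                 TEG = te_heterochromatin_bias)
  if (any(te_heterochromatin_bias < 0) || any(te_heterochromatin_bias > 1))
    stopf("te_heterochromatin_bias must lie in [0, 1]")
  set.seed(seed)

  chroms <- spec$chromosomes
  het <- spec$heterochromatin
  ## per-chromosome euchromatin complement
  eu <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    cn <- chroms$name[i]; L <- chroms$length[i]
    h <- het[het$chrom == cn, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    bounds <- c(0L, as.vector(rbind(h$start, h$end)), L)
    s <- bounds[seq(1L, length(bounds), by = 2L)]
    e <- bounds[seq(2L, length(bounds), by = 2L)]
    keep <- e > s
    data.frame(chrom = cn, start = s[keep], end = e[keep])
  }))
  het_iv <- het

  ## place by free-gap bookkeeping: sample a gap that can hold the feature
  ## (weighted by the number of admissible starts), place uniformly inside
  ## it, split the gap — placement only fails when the compartment is full
  place_in_free <- function(free, len) {
    w <- free$end - free$start - len + 1
    ok <- which(w > 0)
    if (length(ok) == 0L) return(NULL)
    j <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = w[ok])
    s <- free$start[j] + sample.int(w[j], 1L) - 1L
    list(chrom = free$chrom[j], start = s, end = s + len, gap = j)
  }
  split_gap <- function(free, j, s, e) {
    g <- free[j, ]
    free <- free[-j, , drop = FALSE]
    if (s > g$start)
      free <- rbind(free, data.frame(chrom = g$chrom, start = g$start,
                                     end = s, domain = g$domain))
    if (e < g$end)
      free <- rbind(free, data.frame(chrom = g$chrom, start = e,
                                     end = g$end, domain = g$domain))
    free
  }

  out <- vector("list", sum(cnt))
  k <- 0L
  for (type in types) {
    n <- cnt[[type]]
    if (n == 0L) next
    free <- rbind(
      if (nrow(eu) > 0L) cbind(eu, domain = "eu"),
      if (type %in% c("TE", "TEG") && nrow(het_iv) > 0L)
        cbind(het_iv[, c("chrom", "start", "end")], domain = "het"))
    for (i in seq_len(n)) {
      len <- sample_feature_length(type, 1L)
      pos <- NULL
      for (try in seq_len(max_tries)) {
        want <- if (type %in% c("TE", "TEG") &&
                    stats::runif(1) < te_heterochromatin_bias[[type]])
          "het" else "eu"
        cand <- place_in_free(free[free$domain == want, , drop = FALSE], len)
        if (is.null(cand))  # fall back to the other compartment
          cand <- place_in_free(free[free$domain != want, , drop = FALSE],
                                len)
        if (!is.null(cand)) {
          j <- which(free$chrom == cand$chrom & free$start <= cand$start &
                       free$end >= cand$end)[1L]
          free <- split_gap(free, j, cand$start, cand$end)
          pos <- cand
          break
        }
        len <- max(300L, len %/% 2L)
      }
      if (is.null(pos))
        stopf("could not place %s feature %d without overlap", type, i)
      k <- k + 1L
      sf <- if (type %in% c("TE", "TEG")) {
        w <- superfamily_weights / sum(superfamily_weights)
        sample(names(w), 1L, prob = w)
      } else ""
      out[[k]] <- data.frame(
        feature_id = sprintf("%s_%05d", type, i),
        chrom = pos$chrom, start = pos$start, end = pos$end,
        strand = sample(c("+", "-"), 1L),
        feature_type = type, superfamily = sf,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    return(data.frame(feature_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), feature_type = character(),
                      superfamily = character(), stringsAsFactors = FALSE))
  }
  ann <- do.call(rbind, out[seq_len(k)])
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Generate a dense tiling-probe layout
#'
#' Probes of fixed length are laid along each chromosome with jittered
#' spacing around `mean_spacing`, each carrying a scalar affinity covariate
#' in `[0, 1]` that stands in for sequence-driven hybridisation bias.
#'
#' @param spec a [genome_spec()].
#' @param mean_spacing mean start-to-start spacing, bp (>= 1).
#' @param probe_length probe length, bp (>= 1).
#' @param seed integer RNG seed.
#' @return data.frame `probe_id`, `chrom`, `start`, `end`, `affinity`,
#'   sorted by (chrom, start).
#' @export
generate_probes <- function(spec, mean_spacing = 25L, probe_length = 25L,
                            seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  if (mean_spacing < 1) stopf("mean_spacing must be >= 1")
  if (probe_length < 1) stopf("probe_length must be >= 1")
  set.seed(seed)
  res <- lapply(seq_len(nrow(spec$chromosomes)), function(i) {
    cn <- spec$chromosomes$name[i]; L <- spec$chromosomes$length[i]
    if (mean_spacing > L) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), affinity = numeric()))
    }
    n_max <- ceiling(L / mean_spacing) + 10L
    gaps <- pmax(1L, as.integer(round(
      stats::runif(n_max, 0.7 * mean_spacing, 1.3 * mean_spacing))))
    starts <- cumsum(c(0L, gaps[-n_max]))
    starts <- starts[starts + probe_length <= L]
    data.frame(chrom = cn, start = as.integer(starts),
               end = as.integer(starts + probe_length),
               affinity = stats::runif(length(starts)))
  })
  probes <- do.call(rbind, res)
  probes <- probes[order(probes$chrom, probes$start), , drop = FALSE]
  probes <- cbind(probe_id = sprintf("p%07d", seq_len(nrow(probes))), probes,
                  stringsAsFactors = FALSE)
  rownames(probes) <- NULL
  probes
}

#' Generate a functional category map
#'
#' Assigns GO-like flat category labels to features. One designated category
#' (by default a transcription-regulation label) is spiked among a supplied
#' feature set so that category enrichment has planted signal to find.
#'
#' @param annotation annotation data.frame.
#' @param n_categories number of background categories.
#' @param mean_per_feature mean number of category labels per feature.
#' @param enriched_ids feature ids to spike with `enriched_label`.
#' @param enriched_label label of the spiked category.
#' @param enriched_rate probability a member of `enriched_ids` carries the
#'   spiked label (background features carry it at `enriched_rate / 10`).
#' @param seed RNG seed.
#' @return two-column data.frame `feature_id`, `category`.
#' @export
generate_category_map <- function(annotation, n_categories = 20L,
                                  mean_per_feature = 2,
                                  enriched_ids = character(),
                                  enriched_label = "transcription_regulation",
                                  enriched_rate = 0.5, seed = 1L) {
  set.seed(seed)
  ids <- annotation$feature_id
  cats <- sprintf("CAT%03d", seq_len(n_categories))
  rows <- lapply(ids, function(id) {
    k <- stats::rpois(1L, mean_per_feature)
    lab <- if (k > 0) sample(cats, min(k, n_categories)) else character()
    p_hit <- if (id %in% enriched_ids) enriched_rate else enriched_rate / 10
    if (stats::runif(1) < p_hit) lab <- c(lab, enriched_label)
    if (length(lab) == 0L) return(NULL)
    data.frame(feature_id = id, category = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(feature_id = character(),
                                      category = character())
  rownames(out) <- NULL
  out
}

#' Generate a reference target list emulating published seedling targets
#'
#' Takes the true endosperm targets, includes a `shared_fraction` of them in
#' the reference list (these become "shared" targets downstream) and pads the
#' list with non-target features (seedling tissues carry many more targets
#' than the endosperm).
#'
#' @param truth a `sim_truth` object from [simulate_truth()].
#' @param annotation annotation data.frame.
#' @param shared_fraction fraction of true targets present in the reference.
#' @param extra_n number of non-target features added to the reference.
#' @param seed RNG seed.
#' @return character vector of feature ids.
#' @export
generate_reference_targets <- function(truth, annotation,
                                       shared_fraction = 0.865,
                                       extra_n = 350L, seed = 1L) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1)
  set.seed(seed)
  targets <- truth$target_ids
  n_in <- round(shared_fraction * length(targets))
  inref <- if (n_in > 0) sample(targets, n_in) else character()
  pool <- setdiff(annotation$feature_id, targets)
  extra <- if (extra_n > 0 && length(pool) > 0)
    sample(pool, min(extra_n, length(pool))) else character()
  sort(unique(c(inref, extra)))
}
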