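## Small fixtures and independent brute-force oracles used across test files.

tiny_spec <- function(n_chrom = 1L, len = 10000L, het = NULL) {
  chroms <- data.frame(name = paste0("chr", seq_len(n_chrom)),
                       length = rep(as.integer(len), n_chrom))
  genome_spec(chroms, het)
}

## a score track from explicit starts/scores (probe length 25)
make_scores <- function(starts, scores, chrom = "chr1", plen = 25L) {
  o <- order(starts)
  data.frame(probe_id = sprintf("p%04d", seq_along(starts)),
             chrom = chrom, start = as.integer(starts[o]),
             end = as.integer(starts[o] + plen), score = scores[o],
             stringsAsFactors = FALSE)
}

## a probe_track with given per-channel intensity vectors (single replicate)
make_track <- function(starts, IP, input = IP, IgG = IP, affinity = NULL,
                       chrom = "chr1", plen = 25L) {
  n <- length(starts)
  if (is.null(affinity)) affinity <- seq(0, 1, length.out = n)
  probes <- data.frame(probe_id = sprintf("p%04d", seq_len(n)),
                       chrom = chrom, start = as.integer(starts),
                       end = as.integer(starts + plen), affinity = affinity,
                       stringsAsFactors = FALSE)
  probe_track(probes, list(IP = matrix(IP, ncol = 1),
                           input = matrix(input, ncol = 1),
                           IgG = matrix(IgG, ncol = 1)))
}

## brute-force windowed trimmed-mean score, probe by probe
brute_mat_score <- function(df, window = 500, trim = 0.10) {
  vapply(seq_len(nrow(df)), function(i) {
    sel <- df$chrom == df$chrom[i] &
      abs(df$start - df$start[i]) <= window / 2
    v <- sort(df$enrichment[sel])
    n <- length(v)
    drop <- floor(trim * n)
    if (drop > 0) v <- v[(drop + 1):(n - drop)]
    mean(v) * sqrt(length(v))
  }, numeric(1))
}

## brute-force region caller: maximal qualifying chains via pairwise links
brute_call_regions <- function(df, threshold = 3.5, min_run = 300,
                               max_gap = 200) {
  out <- list()
  for (cn in unique(df$chrom)) {
    sub <- df[df$chrom == cn, ]
    sub <- sub[order(sub$start), ]
    q <- sub[sub$score >= threshold, , drop = FALSE]
    if (nrow(q) == 0) next
    ## linked when the end-to-start gap of consecutive qualifying probes
    ## is small enough; chains are connected components along the order
    linked <- if (nrow(q) > 1)
      (q$start[-1] - q$end[-nrow(q)]) <= max_gap else logical(0)
    comp <- cumsum(c(1, as.integer(!linked)))
    for (ci in unique(comp)) {
      rows <- q[comp == ci, , drop = FALSE]
      s <- min(rows$start); e <- max(rows$end)
      if (e - s >= min_run)
        out[[length(out) + 1]] <- data.frame(chrom = cn, start = s, end = e,
                                             n_probes = nrow(rows))
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_probes = integer()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

## exact hypergeometric upper tail by enumerating all draws of size n
enum_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the successes
  mean(hits >= k)
}

## random score track on one chromosome
random_track <- function(n, seed, chrom_len = 20000L) {
  set.seed(seed)
  starts <- sort(sample.int(chrom_len, n))
  make_scores(starts, stats::rnorm(n, 1, 2))
}

## a small, fast pipeline configuration
small_config <- function(seed = 1L) {
  cfg <- default_config(seed)
  cfg$genome$chrom_length <- 150000L
  cfg$annotation$counts <- c(gene = 60L, pseudogene = 8L, TE = 30L,
                             TEG = 10L)
  cfg$truth$n_targets <- c(gene = 10L, pseudogene = 1L, TE = 3L, TEG = 3L)
  cfg$reference$extra_n <- 30L
  cfg$expression$n_deregulated <- 15L
  cfg$de$n_permutations <- 200L
  cfg
}
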