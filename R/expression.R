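#' Differential-expression parameters
#'
#' @param fdr_threshold rank-product FDR (percentage of false positives)
#'   cut-off.
#' @param log2_fc_threshold minimum absolute mean log2 fold change.
#' @param n_permutations permutations for the null rank-product distribution
#'   (>= 100).
#' @param seed RNG seed for the permutations.
#' @return object of class `de_params`.
#' @export
de_params <- function(fdr_threshold = 0.1, log2_fc_threshold = 0.6,
                      n_permutations = 1000L, seed = 1L) {
  if (fdr_threshold <= 0 || log2_fc_threshold <= 0)
    stopf("thresholds must be > 0")
  if (n_permutations < 100L) stopf("n_permutations must be >= 100")
  structure(list(fdr_threshold = fdr_threshold,
                 log2_fc_threshold = log2_fc_threshold,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "de_params")
}

#' Rank product statistic
#'
#' Geometric mean of a gene's fold-change ranks across comparisons.
#'
#' @param rank_matrix numeric matrix, genes x comparisons.
#' @return numeric vector of rank products.
#' @export
rank_product <- function(rank_matrix) {
  exp(rowMeans(log(rank_matrix)))
}

#' Rank-product differential expression with permutation FDR
#'
#' Mutant replicates are paired with wild-type replicates to form fold-change
#' comparisons; by default one-to-one (`pairing = "paired"`, k =
#' min(replicates)), so that a gene's ranks are independent across
#' comparisons and the permutation null is exactly calibrated.
#' `pairing = "all"` forms every mutant x wild-type pair instead; comparisons
#' then share replicates, which makes the test anti-conservative under the
#' null (see the methods vignette). Within
#' each pairing genes are ranked by log2 fold change (rank 1 = strongest, in
#' each direction) and the rank product is the geometric mean of a gene's
#' ranks. The null distribution is obtained by independently permuting the
#' ranks within each comparison `n_permutations` times; the p-value of a gene
#' is the fraction of null rank products at or below its observed one, and
#' the FDR at a gene's cut-off is the expected number of false positives
#' (null count / permutations) divided by the number of genes called at that
#' cut-off. Up- and down-regulation are tested as separate one-sided rank
#' products; a gene is significant when either direction passes the FDR
#' threshold and its absolute mean log2 fold change exceeds the fold-change
#' threshold.
#'
#' @param expr numeric matrix of log2 expression, genes x samples, finite.
#' @param mutant,wt column names or indices of the two replicate groups
#'   (>= 2 each).
#' @param params a [de_params()].
#' @param pairing `"paired"` (one-to-one) or `"all"` (full cross).
#' @return data.frame per gene: `gene`, `mean_log2fc`, `rp_up`, `rp_down`,
#'   `p_up`, `p_down`, `fdr_up`, `fdr_down`, `significant`.
#' @export
rank_product_de <- function(expr, mutant, wt, params = de_params(),
                            pairing = c("paired", "all")) {
  stopifnot(inherits(params, "de_params"))
  pairing <- match.arg(pairing)
  if (!all(is.finite(expr))) stopf("expression values must be finite")
  mu <- expr[, mutant, drop = FALSE]
  wm <- expr[, wt, drop = FALSE]
  if (ncol(mu) < 2L || ncol(wm) < 2L)
    stopf("at least two replicates per condition are required")
  n <- nrow(expr)
  pairs <- if (pairing == "paired") {
    kk <- min(ncol(mu), ncol(wm))
    data.frame(m = seq_len(kk), w = seq_len(kk))
  } else {
    expand.grid(m = seq_len(ncol(mu)), w = seq_len(ncol(wm)))
  }
  k <- nrow(pairs)
  fc <- vapply(seq_len(k), function(j) {
    mu[, pairs$m[j]] - wm[, pairs$w[j]]
  }, numeric(n))
  fc <- matrix(fc, nrow = n)
  ranks_up <- apply(-fc, 2L, rank, ties.method = "average")
  ranks_down <- apply(fc, 2L, rank, ties.method = "average")
  rp_up <- rank_product(ranks_up)
  rp_down <- rank_product(ranks_down)

  ## null: permute ranks within each comparison independently; by symmetry the
  ## same null serves both directions
  set.seed(params$seed)
  log_rank <- log(ranks_up)
  B <- params$n_permutations
  null_rp <- numeric(B * n)
  for (b in seq_len(B)) {
    acc <- numeric(n)
    for (j in seq_len(k)) acc <- acc + sample(log_rank[, j])
    null_rp[((b - 1L) * n + 1L):(b * n)] <- exp(acc / k)
  }
  null_sorted <- sort(null_rp)
  count_le <- function(obs) findInterval(obs, null_sorted)
  c_up <- count_le(rp_up)
  c_down <- count_le(rp_down)
  p_up <- c_up / (B * n)
  p_down <- c_down / (B * n)
  fdr_of <- function(cnt, rp) (cnt / B) / rank(rp, ties.method = "max")
  fdr_up <- fdr_of(c_up, rp_up)
  fdr_down <- fdr_of(c_down, rp_down)
  mean_fc <- rowMeans(fc)
  sig <- (fdr_up <= params$fdr_threshold &
            mean_fc > params$log2_fc_threshold) |
    (fdr_down <= params$fdr_threshold &
       mean_fc < -params$log2_fc_threshold)
  genes <- rownames(expr)
  if (is.null(genes)) genes <- as.character(seq_len(n))
  data.frame(gene = genes, mean_log2fc = mean_fc, rp_up = rp_up,
             rp_down = rp_down, p_up = p_up, p_down = p_down,
             fdr_up = fdr_up, fdr_down = fdr_down, significant = sig,
             stringsAsFactors = FALSE)
}

#' Overlap of deregulated sets with the target set
#'
#' Venn counts for two deregulated sets (e.g. two timepoints) and the target
#' set, plus hypergeometric significance of each pairwise overlap.
#'
#' @param dereg_a,dereg_b deregulated gene sets.
#' @param targets target gene set.
#' @param universe all eligible genes; every set must be a subset.
#' @return list with `venn` (named counts, including pairwise and triple
#'   intersections) and `tests` (data.frame of pairwise
#'   [overlap_significance()] results).
#' @export
deregulated_target_overlap <- function(dereg_a, dereg_b, targets, universe) {
  sets <- list(dereg_a = unique(dereg_a), dereg_b = unique(dereg_b),
               targets = unique(targets))
  for (nm in names(sets)) {
    if (!all(sets[[nm]] %in% universe))
      stopf("%s is not a subset of the universe", nm)
  }
  venn <- c(
    n_dereg_a = length(sets$dereg_a),
    n_dereg_b = length(sets$dereg_b),
    n_targets = length(sets$targets),
    ab = length(intersect(sets$dereg_a, sets$dereg_b)),
    a_targets = length(intersect(sets$dereg_a, sets$targets)),
    b_targets = length(intersect(sets$dereg_b, sets$targets)),
    abt = length(Reduce(intersect, sets)))
  combos <- list(c("dereg_a", "dereg_b"), c("dereg_a", "targets"),
                 c("dereg_b", "targets"))
  tests <- do.call(rbind, lapply(combos, function(cb) {
    r <- overlap_significance(sets[[cb[1L]]], sets[[cb[2L]]], universe)
    r$label <- paste(cb, collapse = " vs ")
    r
  }))
  list(venn = venn, tests = tests)
}

#' Efficiency-corrected qPCR expression
#'
#' Converts a raw cycle threshold into expression units `E^(-Ct)` given the
#' primer efficiency `E` (2 = perfect doubling per cycle).
#'
#' @param E primer efficiency in `(1, 2]`.
#' @param ct cycle threshold.
#' @return expression on the `E^(-Ct)` scale.
#' @export
qpcr_efficiency_correct <- function(E, ct) {
  if (any(E <= 1 | E > 2)) stopf("primer efficiency must lie in (1, 2]")
  E^(-ct)
}

#' qPCR relative expression with propagated error
#'
#' Ratio of target to reference expression, `R = x_t / x_r`, with the
#' first-order propagated standard error
#' `se_R = R * sqrt((se_t/x_t)^2 + (se_r/x_r)^2)`.
#'
#' @param x_target,se_target mean and standard error of the target gene
#'   (efficiency-corrected scale; `x_target > 0`).
#' @param x_ref,se_ref mean and standard error of the reference gene
#'   (`x_ref > 0`).
#' @return list with `ratio` and `se`.
#' @export
qpcr_relative_expression <- function(x_target, se_target, x_ref, se_ref) {
  if (x_ref <= 0) stopf("reference expression must be > 0")
  if (x_target <= 0) stopf("target expression must be > 0")
  if (se_target < 0 || se_ref < 0) stopf("standard errors must be >= 0")
  R <- x_target / x_ref
  list(ratio = R,
       se = R * sqrt((se_target / x_target)^2 + (se_ref / x_ref)^2))
}
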