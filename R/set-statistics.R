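#' Hypergeometric tail probability
#'
#' Exact tail of the hypergeometric distribution for drawing `k` successes in
#' a sample of `n` from a population of `N` containing `K` successes.
#' Upper tail is `P(X >= k)` (enrichment), lower tail `P(X <= k)` (depletion).
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n sample size.
#' @param k successes in the sample.
#' @param tail `"upper"` or `"lower"`.
#' @return the tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (k < 0 || k > n || k > K || n > N || K > N)
    stopf("inconsistent hypergeometric arguments (N=%s K=%s n=%s k=%s)",
          N, K, n, k)
  if (tail == "upper") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment `adj_(i) = min_{j >= i} (p_(j) * m / j)` capped at 1,
#' original order restored.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

enrichment_result <- function(label, N, K, n, k) {
  data.frame(label = label, N = N, K = K, n = n, k = k,
             p_enrich = hypergeom_tail(N, K, n, k, "upper"),
             p_deplete = hypergeom_tail(N, K, n, k, "lower"),
             stringsAsFactors = FALSE)
}

#' Transposon superfamily enrichment within a target group
#'
#' Tests each TE/TEG superfamily for over- and under-representation in a
#' target group against the background of all TEs/TEGs probed by the array.
#' BH correction spans the whole analysis family — both tails of every
#' superfamily — so reporting enrichment and depletion together does not
#' double the false-positive budget.
#'
#' @param calls target-call table from [target_calls()].
#' @param group which targets form the test set: `shared`, `specific`, or all
#'   `targets`.
#' @return data.frame with one row per superfamily: counts, both tail
#'   p-values, and BH-adjusted values `p_enrich_adj`, `p_deplete_adj`.
#' @export
superfamily_enrichment <- function(calls,
                                   group = c("shared", "specific",
                                             "targets")) {
  group <- match.arg(group)
  bg <- calls[calls$feature_type %in% c("TE", "TEG"), , drop = FALSE]
  if (nrow(bg) == 0L) stopf("empty TE/TEG background")
  in_group <- switch(group,
                     shared = bg$target_class == "shared",
                     specific = bg$target_class == "specific",
                     targets = bg$is_target)
  fams <- sort(unique(bg$superfamily))
  res <- do.call(rbind, lapply(fams, function(f) {
    enrichment_result(f, N = nrow(bg), K = sum(bg$superfamily == f),
                      n = sum(in_group),
                      k = sum(in_group & bg$superfamily == f))
  }))
  adj <- bh_adjust(c(res$p_enrich, res$p_deplete))
  res$p_enrich_adj <- adj[seq_len(nrow(res))]
  res$p_deplete_adj <- adj[nrow(res) + seq_len(nrow(res))]
  res
}

#' Significance of the overlap of two gene sets
#'
#' Hypergeometric upper tail on the observed intersection size, with
#' `N = |universe|`, `K = |set_a|`, `n = |set_b|`.
#'
#' @param set_a,set_b character vectors, both subsets of `universe`.
#' @param universe character vector of all eligible ids.
#' @return one-row data.frame with the counts and `p_enrich`/`p_deplete`.
#' @export
overlap_significance <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stopf("sets must be subsets of the universe")
  enrichment_result("overlap", N = length(universe), K = length(set_a),
                    n = length(set_b),
                    k = length(intersect(set_a, set_b)))
}

#' Functional category enrichment among targets
#'
#' Hypergeometric upper tail per category against the probed background, BH
#' correction across categories, and filtering at a critical adjusted
#' p-value (default 1e-3). Empty categories are skipped (noted in the
#' `skipped` attribute).
#'
#' @param target_ids character vector of target ids.
#' @param category_map data.frame `feature_id`, `category`.
#' @param background_ids the probed universe; must cover the targets.
#' @param critical_p adjusted-p filter for the `passes` flag.
#' @return data.frame per category with counts, `p_enrich`, `p_adj`,
#'   `passes`.
#' @export
category_enrichment <- function(target_ids, category_map, background_ids,
                                critical_p = 1e-3) {
  target_ids <- unique(target_ids)
  background_ids <- unique(background_ids)
  if (!all(target_ids %in% background_ids))
    stopf("targets must be a subset of the background")
  cm <- category_map[category_map$feature_id %in% background_ids, ,
                     drop = FALSE]
  cats <- sort(unique(category_map$category))
  skipped <- character()
  rows <- list()
  for (cat in cats) {
    members <- unique(cm$feature_id[cm$category == cat])
    if (length(members) == 0L) { skipped <- c(skipped, cat); next }
    rows[[length(rows) + 1L]] <- enrichment_result(
      cat, N = length(background_ids), K = length(members),
      n = length(target_ids), k = sum(target_ids %in% members))
  }
  if (length(rows) == 0L) {
    res <- data.frame(label = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p_enrich = numeric(),
                      p_deplete = numeric(), p_adj = numeric(),
                      passes = logical())
  } else {
    res <- do.call(rbind, rows)
    res$p_adj <- bh_adjust(res$p_enrich)
    res$passes <- res$p_adj <= critical_p
  }
  attr(res, "skipped") <- skipped
  res
}
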