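#' Coverage-weighted methylation level
#'
#' Sum of methylated observations divided by sum of total observations over
#' the sites of one element/context/tissue; absent (`NA`) when the total
#' weight is zero — zero coverage is missing data, not zero methylation.
#'
#' @param methylated,total numeric vectors of per-site weights.
#' @return the weighted level in `[0, 1]`, or `NA_real_`.
#' @export
weighted_level <- function(methylated, total) {
  if (any(total < 0) || any(methylated < 0))
    stopf("weights must be >= 0")
  if (any(methylated > total))
    stopf("methylated weight exceeds total weight")
  tw <- sum(total)
  if (tw == 0) return(NA_real_)
  sum(methylated) / tw
}

#' Collapse site-level methylation records to element level
#'
#' @param records data.frame `feature_id`, `tissue`, `context`,
#'   `methylated_weight`, `total_weight` (possibly several rows per
#'   element/context/tissue).
#' @return one row per (feature_id, tissue, context) with summed weights and
#'   the weighted `level`.
#' @export
aggregate_methylation <- function(records) {
  key <- interaction(records$feature_id, records$tissue, records$context,
                     drop = TRUE)
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(ii) {
    r <- records[ii[1L], c("feature_id", "tissue", "context")]
    r$methylated_weight <- sum(records$methylated_weight[ii])
    r$total_weight <- sum(records$total_weight[ii])
    r$level <- weighted_level(records$methylated_weight[ii],
                              records$total_weight[ii])
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median methylation by target class, context and tissue
#'
#' Reproduces the class-contrast structure: per feature type (TE, TEG, gene),
#' the median weighted methylation level of all elements, shared targets and
#' specific targets, for each context and tissue. CHH is computed but
#' excluded from the default report (it is uniformly low); request it via
#' `contexts`.
#'
#' @param records element-level methylation records (see
#'   [aggregate_methylation()]; a `level` column is required).
#' @param calls target-call table (supplies `target_class` and
#'   `feature_type`).
#' @param contexts contexts to report.
#' @param tissues tissues to report.
#' @return data.frame `feature_type`, `class` (`all`/`shared`/`specific`),
#'   `context`, `tissue`, `n`, `median_level` (absent classes are omitted).
#' @export
median_by_class <- function(records, calls, contexts = c("CG", "CHG"),
                            tissues = c("vegetative", "endosperm")) {
  m <- match(records$feature_id, calls$feature_id)
  if (anyNA(m)) stopf("every record must join to a target call")
  records$target_class <- calls$target_class[m]
  records$feature_type <- calls$feature_type[m]
  rows <- list()
  for (tp in unique(records$feature_type)) {
    for (cl in c("all", "shared", "specific")) {
      for (cx in contexts) for (ts in tissues) {
        sel <- records$feature_type == tp & records$context == cx &
          records$tissue == ts
        if (cl != "all") sel <- sel & records$target_class == cl
        lv <- records$level[sel]
        lv <- lv[!is.na(lv)]
        if (length(lv) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          feature_type = tp, class = cl, context = cx, tissue = ts,
          n = length(lv), median_level = pctl(lv, 0.5))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster expression patterns of a gene set
#'
#' Centroid-based clustering (k-means with restarts) of row-standardized
#' expression, so squared Euclidean distance is monotone in correlation
#' distance. Deterministic given the seed.
#'
#' @param expr numeric matrix, genes x samples (>= k rows).
#' @param k number of clusters (>= 2); 2 reproduces the two-way
#'   expressed/repressed split, 5 the five-cluster tissue-panel analysis.
#' @param seed RNG seed.
#' @param restarts number of random starts.
#' @return list with `cluster` (named integer assignments) and `summary`
#'   (data.frame `cluster`, `n`, `pct`).
#' @export
expression_clusters <- function(expr, k = 2L, seed = 1L, restarts = 25L) {
  if (k < 2L) stopf("k must be >= 2")
  if (nrow(expr) < k) stopf("fewer rows than clusters")
  z <- t(scale(t(expr)))
  z[!is.finite(z)] <- 0  # constant rows carry no pattern
  set.seed(seed)
  distinct <- unique(z)
  if (nrow(distinct) <= k) {
    ## no more patterns than clusters: each distinct pattern is a cluster
    ## (identical rows share one)
    cl <- match(apply(z, 1L, paste, collapse = "\r"),
                apply(distinct, 1L, paste, collapse = "\r"))
    cl <- stats::setNames(as.integer(cl), rownames(expr))
  } else {
    km <- stats::kmeans(z, centers = k, nstart = restarts, iter.max = 100L)
    cl <- stats::setNames(km$cluster, rownames(expr))
  }
  list(cluster = cl, summary = cluster_summary(cl))
}

#' Cluster membership counts and percentages
#'
#' @param assignments vector of cluster labels (one per gene).
#' @return data.frame `cluster`, `n`, `pct` (one-decimal percentage of all
#'   clustered genes).
#' @export
cluster_summary <- function(assignments) {
  tab <- table(assignments)
  data.frame(cluster = names(tab), n = as.integer(tab),
             pct = vapply(as.integer(tab), as_pct, numeric(1),
                          n = length(assignments)),
             stringsAsFactors = FALSE)
}
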