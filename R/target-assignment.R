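## GRanges helpers: in-memory coordinates are 0-based half-open; GRanges is
## 1-based inclusive, so start + 1.
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

#' Gene-level score: 75th percentile of fully contained probe scores
#'
#' Collects the scores of probes lying entirely within the feature's
#' transcribed extent (`feature.start <= probe.start` and
#' `probe.end <= feature.end`) and returns their 75th percentile under the
#' shared interpolation convention; `NA` when no probe qualifies.
#'
#' @param features annotation data.frame (one or more rows).
#' @param scores score track data.frame.
#' @return numeric vector of gene scores, one per feature (NA when absent).
#' @export
gene_score <- function(features, scores) {
  by_chrom <- split(seq_len(nrow(scores)), scores$chrom)
  out <- rep(NA_real_, nrow(features))
  for (cn in unique(features$chrom)) {
    idx <- by_chrom[[cn]]
    if (is.null(idx)) next
    ps <- scores$start[idx]; pe <- scores$end[idx]; sc <- scores$score[idx]
    stopifnot(!is.unsorted(ps))
    fsel <- which(features$chrom == cn)
    ## probes with start >= feature start, narrowed by start index range,
    ## then filtered on containment of the probe end
    lo <- findInterval(features$start[fsel] - 1L, ps) + 1L
    hi <- findInterval(features$end[fsel], ps)
    for (j in seq_along(fsel)) {
      if (lo[j] > hi[j]) next
      rng <- lo[j]:hi[j]
      keep <- pe[rng] <= features$end[fsel[j]]
      if (!any(keep)) next
      out[fsel[j]] <- pctl(sc[rng][keep], 0.75)
    }
  }
  out
}

#' Call features as targets by region overlap
#'
#' A feature is a target when at least one enriched region overlaps its
#' transcribed extent by >= 1 bp (half-open interval intersection; regions
#' that merely abut a feature do not count).
#'
#' @param features annotation data.frame.
#' @param regions regions data.frame from [call_regions()], sorted.
#' @return logical vector `is_target`, one per feature.
#' @export
call_targets <- function(features, regions) {
  if (nrow(features) == 0L) return(logical(0))
  if (nrow(regions) == 0L) return(rep(FALSE, nrow(features)))
  if (is.unsorted(order(regions$chrom, regions$start)))
    stopf("regions must be sorted")
  hits <- GenomicRanges::findOverlaps(as_granges(features),
                                      as_granges(regions),
                                      minoverlap = 1L)
  out <- rep(FALSE, nrow(features))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Classify targets as shared or specific against reference lists
#'
#' A target found in the union of the reference lists (e.g. published
#' seedling H3K27me3 targets) is "shared"; a target absent from all of them
#' is tissue-"specific". Duplicated ids are deduplicated.
#'
#' @param target_ids character vector of target feature ids.
#' @param reference_lists a character vector or list of character vectors of
#'   reference target ids.
#' @return list with `class` (named character vector over the targets:
#'   `shared`/`specific`) and `counts` (data.frame `class`, `n`, `pct`, one
#'   decimal percentages of all targets).
#' @export
classify_targets <- function(target_ids, reference_lists) {
  target_ids <- unique(target_ids)
  if (!is.list(reference_lists)) reference_lists <- list(reference_lists)
  ref <- unique(unlist(reference_lists, use.names = FALSE))
  cls <- ifelse(target_ids %in% ref, "shared", "specific")
  names(cls) <- target_ids
  n <- length(target_ids)
  counts <- data.frame(
    class = c("shared", "specific"),
    n = c(sum(cls == "shared"), sum(cls == "specific")))
  counts$pct <- vapply(counts$n, as_pct, numeric(1), n = n)
  list(class = cls, counts = counts)
}

#' Build the per-feature target-call table
#'
#' Joins gene scores, region-overlap target calls, shared/specific
#' classification and heterochromatin membership (feature midpoint inside a
#' heterochromatin interval) into one table.
#'
#' @param annotation annotation data.frame.
#' @param scores score track data.frame.
#' @param regions regions data.frame.
#' @param reference_lists reference target id lists (see
#'   [classify_targets()]).
#' @param spec a [genome_spec()] (for heterochromatin membership).
#' @return data.frame `feature_id`, `feature_type`, `superfamily`,
#'   `gene_score`, `is_target`, `target_class`, `in_heterochromatin`.
#' @export
target_calls <- function(annotation, scores, regions,
                         reference_lists = character(), spec = NULL) {
  is_t <- call_targets(annotation, regions)
  cls <- rep("non_target", nrow(annotation))
  if (any(is_t)) {
    cc <- classify_targets(annotation$feature_id[is_t], reference_lists)
    cls[is_t] <- unname(cc$class[annotation$feature_id[is_t]])
  }
  mids <- interval_midpoint(annotation$start, annotation$end)
  het <- if (is.null(spec)) rep(FALSE, nrow(annotation)) else
    point_in_intervals(annotation$chrom, mids, spec$heterochromatin)
  data.frame(feature_id = annotation$feature_id,
             feature_type = annotation$feature_type,
             superfamily = annotation$superfamily,
             gene_score = gene_score(annotation, scores),
             is_target = is_t,
             target_class = cls,
             in_heterochromatin = het,
             stringsAsFactors = FALSE)
}

#' Feature-type composition of target groups
#'
#' Tabulates, for each group (all probed features, all targets, shared
#' targets, specific targets), the fraction of each feature type, plus the
#' heterochromatin fraction per type and group.
#'
#' @param calls target-call table from [target_calls()].
#' @return list with `type_composition` (data.frame `group`, `feature_type`,
#'   `n`, `fraction`; fractions sum to 1 within each non-empty group) and
#'   `heterochromatin` (data.frame `group`, `feature_type`, `n`,
#'   `het_fraction`).
#' @export
class_composition <- function(calls) {
  groups <- list(probed = rep(TRUE, nrow(calls)),
                 targets = calls$is_target,
                 shared = calls$target_class == "shared",
                 specific = calls$target_class == "specific")
  types <- c("gene", "pseudogene", "TE", "TEG")
  comp <- list(); het <- list()
  for (g in names(groups)) {
    sub <- calls[groups[[g]], , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (tp in types) {
      k <- sum(sub$feature_type == tp)
      comp[[length(comp) + 1L]] <- data.frame(
        group = g, feature_type = tp, n = k, fraction = k / nrow(sub))
      if (k > 0) {
        hk <- sum(sub$in_heterochromatin[sub$feature_type == tp])
        het[[length(het) + 1L]] <- data.frame(
          group = g, feature_type = tp, n = k, het_fraction = hk / k)
      }
    }
  }
  list(type_composition = do.call(rbind, comp),
       heterochromatin = do.call(rbind, het))
}
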