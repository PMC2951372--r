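#' Simulate a two-genotype expression matrix with spiked deregulation
#'
#' Null genes share their mean across genotypes; genes in `deregulated_set`
#' are shifted by `log2_effect` in the mutant. Values are on the log2 scale,
#' as produced by standard array normalisation.
#'
#' @param features annotation data.frame (genes are profiled; any feature id
#'   set is accepted).
#' @param deregulated_set feature ids to deregulate; must be a subset of the
#'   features.
#' @param log2_effect mutant-minus-wild-type shift applied to deregulated
#'   genes (signed; a vector recycled over the set is accepted).
#' @param n_reps replicates per genotype (>= 2, rank products need
#'   replication).
#' @param noise_sd residual log2 SD.
#' @param baseline_mean,baseline_sd distribution of gene-level baseline
#'   expression (log2).
#' @param seed RNG seed.
#' @return list with `expr` (matrix genes x samples, columns `wt_*` then
#'   `mut_*`), `condition` (character vector per column), and
#'   `deregulated` (the truth labels; empty when `log2_effect == 0`).
#' @export
simulate_expression <- function(features, deregulated_set = character(),
                                log2_effect = 2.0, n_reps = 3L,
                                noise_sd = 0.25, baseline_mean = 6,
                                baseline_sd = 1.5, seed = 1L) {
  if (n_reps < 2L) stopf("n_reps must be >= 2 (rank product needs replicates)")
  ids <- features$feature_id
  if (!all(deregulated_set %in% ids))
    stopf("deregulated_set must be a subset of the features")
  set.seed(seed)
  n <- length(ids)
  base <- stats::rnorm(n, baseline_mean, baseline_sd)
  shift <- numeric(n)
  if (length(deregulated_set) > 0 && any(log2_effect != 0)) {
    shift[match(deregulated_set, ids)] <- rep_len(log2_effect,
                                                  length(deregulated_set))
  }
  wt <- matrix(stats::rnorm(n * n_reps, sd = noise_sd), n, n_reps) + base
  mu <- matrix(stats::rnorm(n * n_reps, sd = noise_sd), n, n_reps) + base +
    shift
  expr <- cbind(wt, mu)
  rownames(expr) <- ids
  colnames(expr) <- c(paste0("wt_", seq_len(n_reps)),
                      paste0("mut_", seq_len(n_reps)))
  dereg <- if (any(shift != 0)) ids[shift != 0] else character()
  list(expr = expr,
       condition = rep(c("wt", "mut"), each = n_reps),
       deregulated = dereg)
}

#' Simulate a tissue-panel expression matrix with planted archetypes
#'
#' Rows follow one of two archetypes — repressed in endosperm tissues or
#' expressed in endosperm tissues — plus noise, mimicking the tissue panels
#' used to cluster endosperm-specific targets.
#'
#' @param feature_ids character vector of row ids.
#' @param archetype named character vector over the ids, values
#'   `"endosperm_repressed"` or `"endosperm_expressed"`.
#' @param tissues column labels; names containing `"endosperm"` form the
#'   endosperm block.
#' @param contrast log2 separation between the blocks.
#' @param noise_sd residual SD.
#' @param seed RNG seed.
#' @return matrix ids x tissues of log2 expression.
#' @export
simulate_tissue_panel <- function(feature_ids, archetype,
                                  tissues = c("seedling", "leaf", "stem",
                                              "root", "flower", "silique",
                                              "seed_torpedo", "seed_green",
                                              "endosperm_preglobular",
                                              "endosperm_globular",
                                              "endosperm_heart"),
                                  contrast = 3, noise_sd = 0.5, seed = 1L) {
  stopifnot(all(feature_ids %in% names(archetype)))
  set.seed(seed)
  endo <- grepl("endosperm", tissues)
  n <- length(feature_ids)
  base <- stats::rnorm(n, 6, 1)
  m <- matrix(stats::rnorm(n * length(tissues), sd = noise_sd), n,
              length(tissues)) + base
  rep_rows <- archetype[feature_ids] == "endosperm_repressed"
  m[rep_rows, endo] <- m[rep_rows, endo] - contrast
  m[!rep_rows, endo] <- m[!rep_rows, endo] + contrast
  rownames(m) <- feature_ids
  colnames(m) <- tissues
  m
}
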