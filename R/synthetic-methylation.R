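#' Default per-class methylation means
#'
#' Mean methylation level per (target class, sequence context, tissue).
#' Shared targets are essentially unmethylated in both tissues; specific
#' targets and background TEs are methylated in vegetative tissue with a
#' reduced level in the endosperm (the endosperm is globally hypomethylated);
#' CHH is low everywhere.
#'
#' @return data.frame `class`, `context`, `tissue`, `mean`.
#' @export
methylation_param_defaults <- function() {
  grid <- expand.grid(class = c("shared", "specific", "background"),
                      context = c("CG", "CHG", "CHH"),
                      tissue = c("vegetative", "endosperm"),
                      stringsAsFactors = FALSE)
  m <- c(
    shared.CG.vegetative = 0.01,  shared.CG.endosperm = 0.01,
    shared.CHG.vegetative = 0.01, shared.CHG.endosperm = 0.01,
    shared.CHH.vegetative = 0.01, shared.CHH.endosperm = 0.01,
    specific.CG.vegetative = 0.85,  specific.CG.endosperm = 0.45,
    specific.CHG.vegetative = 0.60, specific.CHG.endosperm = 0.30,
    specific.CHH.vegetative = 0.08, specific.CHH.endosperm = 0.05,
    background.CG.vegetative = 0.75,  background.CG.endosperm = 0.50,
    background.CHG.vegetative = 0.50, background.CHG.endosperm = 0.35,
    background.CHH.vegetative = 0.06, background.CHH.endosperm = 0.04)
  grid$mean <- m[paste(grid$class, grid$context, grid$tissue, sep = ".")]
  grid
}

#' Simulate two-tissue methylation records per element
#'
#' Draws a per-element true level from a Beta distribution around the class
#' mean, then binomial counts at Poisson coverage, so records carry
#' read-count-like weights whose ratio is the methylation level.
#'
#' @param features annotation data.frame (or any data.frame with
#'   `feature_id`).
#' @param class_map named character vector mapping every feature id to one of
#'   `shared`, `specific`, `background`.
#' @param params data.frame as in [methylation_param_defaults()], means in
#'   `[0, 1]`.
#' @param precision Beta precision (larger = less element-to-element spread).
#' @param coverage mean total weight per element/context/tissue.
#' @param seed RNG seed.
#' @return data.frame `feature_id`, `tissue`, `context`, `methylated_weight`,
#'   `total_weight`, `level`.
#' @export
simulate_methylation <- function(features, class_map,
                                 params = methylation_param_defaults(),
                                 precision = 100, coverage = 80, seed = 1L) {
  ids <- features$feature_id
  if (!all(ids %in% names(class_map)))
    stopf("class_map must cover every feature")
  if (any(params$mean < 0 | params$mean > 1))
    stopf("methylation means must lie in [0, 1]")
  set.seed(seed)
  key <- paste(params$class, params$context, params$tissue, sep = ".")
  mu <- stats::setNames(params$mean, key)
  grid <- expand.grid(feature_id = ids,
                      tissue = c("vegetative", "endosperm"),
                      context = c("CG", "CHG", "CHH"),
                      stringsAsFactors = FALSE)
  cls <- class_map[grid$feature_id]
  m <- mu[paste(cls, grid$context, grid$tissue, sep = ".")]
  if (anyNA(m)) stopf("params missing a (class, context, tissue) combination")
  a <- m * precision; b <- (1 - m) * precision
  lvl <- ifelse(m <= 0, 0,
                ifelse(m >= 1, 1, stats::rbeta(nrow(grid), pmax(a, 1e-8),
                                               pmax(b, 1e-8))))
  lvl <- pmin(pmax(lvl, 0), 1)
  tot <- stats::rpois(nrow(grid), coverage) + 1L
  met <- stats::rbinom(nrow(grid), tot, lvl)
  grid$methylated_weight <- met
  grid$total_weight <- tot
  grid$level <- met / tot
  grid
}
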