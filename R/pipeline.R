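#' Default pipeline configuration
#'
#' All generator and analysis parameters with their defaults: the tiling and
#' scoring geometry (500-bp windows), the region-calling constraints
#' (threshold 3.5, minimum run 300 bp, maximum gap 200 bp), the 75th-percentile
#' gene score, the rank-product thresholds (FDR 0.1, |log2 FC| > 0.6), and
#' the synthetic-genome defaults (a scaled-down two-chromosome genome with
#' embedded enrichment domains of effect 2.0 over feature bodies, at least
#' 600 bp long).
#'
#' @param seed global seed; fans out to stage seeds via [derive_seed()].
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    genome = list(n_chrom = 2L, chrom_length = 2500000L,
                  het_fraction = 0.16),
    annotation = list(counts = c(gene = 1100L, pseudogene = 40L, TE = 400L,
                                 TEG = 100L),
                      te_het_bias = c(TE = 0.16, TEG = 0.46)),
    probes = list(mean_spacing = 25L, probe_length = 25L),
    truth = list(n_targets = c(gene = 55L, pseudogene = 4L, TE = 6L,
                               TEG = 9L),
                 effect = 2.0, min_length = 600L, min_separation = 1000L),
    chip = list(noise_sd = 1.0, affinity_effect = 1.0, n_reps = 3L),
    scoring = list(window_size = 500L, trim_fraction = 0.10,
                   n_affinity_bins = 20L),
    calling = list(score_threshold = 3.5, min_run = 300L, max_gap = 200L),
    reference = list(shared_fraction = 0.865, extra_n = 350L),
    profile = list(body_bins = 20L, flank_bp = 2000L, flank_bin_bp = 100L,
                   density_window_bp = 200000L),
    categories = list(n_categories = 20L, enriched_rate = 0.5),
    expression = list(n_deregulated = 40L, target_fraction = 0.6,
                      log2_effect = 2.0, n_reps = 3L),
    de = list(fdr_threshold = 0.1, log2_fc_threshold = 0.6,
              n_permutations = 1000L),
    clusters = list(k = 2L, restarts = 25L)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config configuration list.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config())
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(cfg[[nm]])) base[[nm]][[k]] <- cfg[[nm]][[k]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  structure(base, class = "pipeline_config")
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline on synthetic data
#'
#' Generates a genome, annotation, probes, ChIP intensities with embedded
#' enrichment domains, methylation and expression tables; scores probes,
#' calls regions, assigns and classifies targets, computes profiles,
#' densities, enrichment statistics, methylation medians and rank-product
#' differential expression; and writes the result bundle (GFF3, BED,
#' bedGraph, TSV tables, summary report) to `outdir` when given.
#'
#' Each stage draws its RNG seed from the global seed and its stage name, so
#' reruns with the same configuration are identical.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @param outdir optional output directory (created if missing).
#' @return (invisibly) a named list with every intermediate and result table,
#'   plus `summary`, `config_hash` and `seed`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  seed <- config$seed
  spec <- default_genome_spec(config$genome$n_chrom,
                              config$genome$chrom_length,
                              config$genome$het_fraction)

  ann <- generate_annotation(spec, counts = unlist(config$annotation$counts),
                             te_heterochromatin_bias =
                               unlist(config$annotation$te_het_bias),
                             seed = derive_seed(seed, "annotation"))
  probes <- generate_probes(spec, config$probes$mean_spacing,
                            config$probes$probe_length,
                            seed = derive_seed(seed, "probes"))
  truth <- simulate_truth(spec, ann,
                          n_targets = unlist(config$truth$n_targets),
                          effect = config$truth$effect,
                          min_length = config$truth$min_length,
                          min_separation = config$truth$min_separation,
                          seed = derive_seed(seed, "truth"))
  track <- simulate_chip(probes, truth, noise_sd = config$chip$noise_sd,
                         affinity_effect = config$chip$affinity_effect,
                         n_reps = config$chip$n_reps,
                         seed = derive_seed(seed, "chip"))

  sp <- scoring_params(config$scoring$window_size,
                       config$scoring$trim_fraction,
                       config$scoring$n_affinity_bins)
  scores <- score_track(track, sp)

  rp <- region_call_params(config$calling$score_threshold,
                           config$calling$min_run, config$calling$max_gap)
  regions <- call_regions(scores, rp)
  reg_summary <- region_summary(regions, spec)

  reference <- generate_reference_targets(truth, ann,
                                          config$reference$shared_fraction,
                                          config$reference$extra_n,
                                          seed = derive_seed(seed, "reference"))
  calls <- target_calls(ann, scores, regions, reference, spec)
  composition <- class_composition(calls)
  target_ids <- calls$feature_id[calls$is_target]
  cls_counts <- if (length(target_ids) > 0)
    classify_targets(target_ids, reference)$counts else NULL

  pp <- profile_params(config$profile$body_bins, config$profile$flank_bp,
                       config$profile$flank_bin_bp,
                       config$profile$density_window_bp)
  genes <- ann[ann$feature_type == "gene", , drop = FALSE]
  gene_targets <- genes[genes$feature_id %in% target_ids, , drop = FALSE]
  gene_nontargets <- genes[!genes$feature_id %in% target_ids, , drop = FALSE]
  profile_targets <- if (nrow(gene_targets) > 0)
    metagene_profile(scores, gene_targets, pp) else NULL
  profile_nontargets <- if (nrow(gene_nontargets) > 0)
    metagene_profile(scores, gene_nontargets, pp) else NULL
  density <- chromosome_density(regions, ann, spec, pp)

  sf_enrich <- superfamily_enrichment(calls, "specific")
  category_map <- generate_category_map(
    ann, n_categories = config$categories$n_categories,
    enriched_ids = target_ids,
    enriched_rate = config$categories$enriched_rate,
    seed = derive_seed(seed, "categories"))
  cat_enrich <- category_enrichment(target_ids, category_map,
                                    ann$feature_id)

  ## methylation stratified by target class
  class_map <- stats::setNames(ifelse(calls$target_class %in%
                                        c("shared", "specific"),
                                      calls$target_class, "background"),
                               calls$feature_id)
  meth <- simulate_methylation(ann, class_map,
                               seed = derive_seed(seed, "methylation"))
  meth_medians <- median_by_class(meth, calls)

  ## differential expression over genes, deregulated set leaning on targets
  set.seed(derive_seed(seed, "deregulated"))
  n_dereg <- min(config$expression$n_deregulated, nrow(genes))
  n_from_targets <- round(config$expression$target_fraction * n_dereg)
  tpool <- gene_targets$feature_id
  npool <- gene_nontargets$feature_id
  dereg <- c(sample(tpool, min(n_from_targets, length(tpool))),
             sample(npool, min(n_dereg - min(n_from_targets, length(tpool)),
                               length(npool))))
  sim_a <- simulate_expression(genes, dereg,
                               log2_effect = config$expression$log2_effect,
                               n_reps = config$expression$n_reps,
                               seed = derive_seed(seed, "expression_3dap"))
  dp <- de_params(config$de$fdr_threshold, config$de$log2_fc_threshold,
                  config$de$n_permutations,
                  seed = derive_seed(seed, "rankproduct"))
  de <- rank_product_de(sim_a$expr, grep("^mut_", colnames(sim_a$expr)),
                        grep("^wt_", colnames(sim_a$expr)), dp)
  sig <- de$gene[de$significant]
  ovl <- overlap_significance(sig, gene_targets$feature_id,
                              genes$feature_id)

  ## cluster the specific targets' tissue panel
  specific_ids <- calls$feature_id[calls$target_class == "specific"]
  clusters <- NULL
  if (length(specific_ids) >= config$clusters$k) {
    set.seed(derive_seed(seed, "archetypes"))
    arch <- stats::setNames(sample(c("endosperm_repressed",
                                     "endosperm_expressed"),
                                   length(specific_ids), replace = TRUE),
                            specific_ids)
    panel <- simulate_tissue_panel(specific_ids, arch,
                                   seed = derive_seed(seed, "panel"))
    clusters <- expression_clusters(panel, k = config$clusters$k,
                                    seed = derive_seed(seed, "kmeans"),
                                    restarts = config$clusters$restarts)
  }

  summary_tab <- data.frame(
    metric = c("n_regions", "total_region_bp", "pct_genome",
               "median_region_length", "pct_heterochromatic_regions",
               "n_targets", "pct_shared", "pct_specific",
               "n_significant_de", "p_overlap_targets_de"),
    value = c(reg_summary$n_regions, reg_summary$total_bp,
              round(100 * reg_summary$genome_fraction, 1),
              reg_summary$median_length, reg_summary$pct_heterochromatic,
              length(target_ids),
              if (!is.null(cls_counts)) cls_counts$pct[1] else NA,
              if (!is.null(cls_counts)) cls_counts$pct[2] else NA,
              length(sig), signif(ovl$p_enrich, 3)))

  bundle <- list(spec = spec, annotation = ann, probes = probes,
                 truth = truth, track = track, scores = scores,
                 regions = regions, region_summary = reg_summary,
                 reference = reference, calls = calls,
                 composition = composition, class_counts = cls_counts,
                 profile_targets = profile_targets,
                 profile_nontargets = profile_nontargets, density = density,
                 superfamily_enrichment = sf_enrich,
                 category_map = category_map,
                 category_enrichment = cat_enrich,
                 methylation = meth, methylation_medians = meth_medians,
                 expression = sim_a, de = de, overlap = ovl,
                 clusters = clusters, summary = summary_tab,
                 config_hash = config_hash(config), seed = seed)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_gff3(ann, p("annotation.gff3"))
    write_bed(spec$heterochromatin, p("heterochromatin.bed"))
    write_bed(truth$domains, p("truth_domains.bed"))
    write_tsv(probes, p("probes.tsv"))
    write_bedgraph(scores, p("scores.bedgraph"))
    write_bed(regions, p("regions.bed"))
    write_tsv(calls, p("target_calls.tsv"))
    if (!is.null(profile_targets))
      write_tsv(profile_targets, p("metagene_targets.tsv"))
    if (!is.null(profile_nontargets))
      write_tsv(profile_nontargets, p("metagene_nontargets.tsv"))
    write_tsv(density, p("chromosome_density.tsv"))
    write_tsv(sf_enrich, p("superfamily_enrichment.tsv"))
    write_tsv(cat_enrich, p("category_enrichment.tsv"))
    write_tsv(meth, p("methylation.tsv"))
    write_tsv(meth_medians, p("methylation_medians.tsv"))
    write_tsv(de, p("differential_expression.tsv"))
    if (!is.null(clusters))
      write_tsv(clusters$summary, p("cluster_summary.tsv"))
    stamp <- rbind(summary_tab,
                   data.frame(metric = c("seed", "config_md5"),
                              value = c(seed, bundle$config_hash)))
    write_tsv(stamp, p("summary.tsv"))
  }
  invisible(bundle)
}
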