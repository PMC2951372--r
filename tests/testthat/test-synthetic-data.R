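spec_big <- genome_spec(
  data.frame(name = "chr1", length = 4000000L),
  data.frame(chrom = "chr1", start = 1600000L, end = 2400000L))

test_that("generate_annotation respects counts, vocabulary and non-overlap", {
  expect_identical(nrow(generate_annotation(tiny_spec(), counts = c(gene = 0L))),
                   0L)

  ann <- generate_annotation(spec_big,
                             counts = c(gene = 80L, pseudogene = 10L,
                                        TE = 40L, TEG = 15L), seed = 7L)
  expect_identical(as.vector(table(ann$feature_type)[c("gene", "pseudogene",
                                                       "TE", "TEG")]),
                   c(80L, 10L, 40L, 15L))
  expect_true(all((ann$superfamily == "") ==
                    (ann$feature_type %in% c("gene", "pseudogene"))))
  expect_true(all(ann$start < ann$end))
  for (tp in unique(ann$feature_type)) {
    sub <- ann[ann$feature_type == tp, ]
    sub <- sub[order(sub$chrom, sub$start), ]
    same <- sub$chrom[-1] == sub$chrom[-nrow(sub)]
    expect_true(all(sub$start[-1][same] >= sub$end[-nrow(sub)][same]))
  }

  again <- generate_annotation(spec_big,
                               counts = c(gene = 80L, pseudogene = 10L,
                                          TE = 40L, TEG = 15L), seed = 7L)
  expect_identical(ann, again)
})

test_that("TE heterochromatin placement matches the requested bias", {
  fracs <- vapply(1:3, function(s) {
    ann <- generate_annotation(spec_big, counts = c(TE = 1000L),
                               te_heterochromatin_bias = 0.16, seed = s)
    mids <- floor((ann$start + ann$end) / 2)
    mean(mids >= 1600000 & mids < 2400000)
  }, numeric(1))
  expect_true(all(abs(fracs - 0.16) <= 0.03))
})

test_that("generate_probes tiles chromosomes with jittered spacing", {
  sp <- tiny_spec(len = 10000L)
  pr <- generate_probes(sp, mean_spacing = 35L, probe_length = 25L, seed = 3L)
  expect_true(abs(nrow(pr) - floor(10000 / 35)) <= 20)
  expect_true(all(pr$start >= 0 & pr$end <= 10000))
  expect_false(is.unsorted(pr$start))
  expect_identical(pr, generate_probes(sp, 35L, 25L, seed = 3L))
  expect_error(generate_probes(sp, 35L, 0L), "probe_length")
  none <- generate_probes(tiny_spec(len = 10L), mean_spacing = 100L,
                          probe_length = 5L)
  expect_identical(nrow(none), 0L)
})

test_that("simulate_chip embeds domain effects in the IP channel only", {
  sp <- tiny_spec(len = 50000L)
  pr <- generate_probes(sp, seed = 1L)

  ## null signal: no domains, negligible noise, no affinity effect
  quiet <- simulate_chip(pr, NULL, noise_sd = 1e-4, affinity_effect = 0,
                         n_reps = 1L, seed = 1L)
  expect_true(max(abs(quiet$intensity$IP - quiet$intensity$input)) < 0.01)

  truth <- structure(list(domains = data.frame(chrom = "chr1",
                                               start = 20000L, end = 30000L,
                                               effect = 2.0),
                          target_ids = character(),
                          target_flag = logical(0)),
                     class = "sim_truth")
  ch <- simulate_chip(pr, truth, noise_sd = 1, n_reps = 3L, seed = 2L)
  expect_identical(ncol(ch$intensity$IP), 3L)
  mids <- floor((pr$start + pr$end) / 2)
  inside <- mids >= 20000 & mids < 30000
  d <- rowMeans(ch$intensity$IP - ch$intensity$input)[inside]
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 2.0), 3 * se)

  bad <- truth
  bad$domains$chrom <- "chrX"
  expect_error(simulate_chip(pr, bad, seed = 1L), "outside")
  expect_error(simulate_chip(pr, NULL, n_reps = 0L), "n_reps")
})

test_that("simulate_methylation reproduces the class/tissue structure", {
  feats <- data.frame(feature_id = sprintf("TE_%03d", 1:150))
  cls <- setNames(rep(c("shared", "specific", "background"), each = 50),
                  feats$feature_id)
  rec <- simulate_methylation(feats, cls, seed = 5L)

  shared_cg <- rec$level[cls[rec$feature_id] == "shared" &
                           rec$context == "CG"]
  expect_lt(median(shared_cg), 0.05)
  expect_gt(mean(shared_cg < 0.05), 0.95)

  sp_cg <- rec[cls[rec$feature_id] == "specific" & rec$context == "CG", ]
  veg <- sp_cg$level[sp_cg$tissue == "vegetative"]
  endo <- sp_cg$level[sp_cg$tissue == "endosperm"]
  names(veg) <- sp_cg$feature_id[sp_cg$tissue == "vegetative"]
  names(endo) <- sp_cg$feature_id[sp_cg$tissue == "endosperm"]
  expect_gte(mean(veg[names(endo)] > endo), 0.95)

  zero <- methylation_param_defaults()
  zero$mean <- 0
  rec0 <- simulate_methylation(feats, cls, params = zero, seed = 1L)
  expect_true(all(rec0$methylated_weight == 0))

  bad <- methylation_param_defaults(); bad$mean[1] <- 1.5
  expect_error(simulate_methylation(feats, cls, params = bad), "\\[0, 1\\]")
  expect_error(simulate_methylation(feats, cls[-1]), "cover")
})

test_that("simulate_expression spikes the deregulated set", {
  feats <- data.frame(feature_id = sprintf("g%04d", 1:500))
  null_sim <- simulate_expression(feats, feats$feature_id[1:10],
                                  log2_effect = 0, seed = 1L)
  expect_identical(null_sim$deregulated, character(0))

  sim <- simulate_expression(feats, feats$feature_id[1:100],
                             log2_effect = 2.0, n_reps = 3L, seed = 2L)
  d <- rowMeans(sim$expr[1:100, 4:6]) - rowMeans(sim$expr[1:100, 1:3])
  expect_lt(abs(mean(d) - 2.0), 3 * sd(d) / sqrt(100))

  expect_identical(sim$expr,
                   simulate_expression(feats, feats$feature_id[1:100],
                                       2.0, 3L, seed = 2L)$expr)
  expect_error(simulate_expression(feats, n_reps = 1L), "replicates")
  expect_error(simulate_expression(feats, "missing_id"), "subset")
})

test_that("expected_seed_fraction enumerates Mendelian seed classes", {
  double_het <- cross_spec(
    mother = list(FIS2 = c("fis2", "FIS2"), MET1 = c("met1", "MET1")),
    predicate = list(FIS2 = list(type = "maternal", allele = "fis2"),
                     MET1 = list(type = "zygotic_homozygous",
                                 allele = "met1")))
  expect_identical(expected_seed_fraction(double_het), 0.125)

  homo <- cross_spec(
    mother = list(FIS2 = c("fis2", "fis2"), MET1 = c("met1", "met1")),
    predicate = list(FIS2 = list(type = "maternal", allele = "fis2"),
                     MET1 = list(type = "zygotic_homozygous",
                                 allele = "met1")))
  expect_identical(expected_seed_fraction(homo), 1)

  mat_only <- cross_spec(
    mother = list(FIS2 = c("fis2", "FIS2")),
    predicate = list(FIS2 = list(type = "maternal", allele = "fis2")))
  expect_identical(expected_seed_fraction(mat_only), 0.5)

  expect_error(cross_spec(mother = list(FIS2 = c("fis2", "FIS2")),
                          predicate = list(MET1 = list(
                            type = "maternal", allele = "met1"))),
               "missing locus")
})

test_that("expected_seed_fraction agrees with Monte-Carlo cross simulation", {
  mother <- list(A = c("a", "A"), B = c("b", "b"))
  cross <- cross_spec(mother,
                      predicate = list(
                        A = list(type = "zygotic_homozygous", allele = "a"),
                        B = list(type = "maternal", allele = "b")))
  exact <- expected_seed_fraction(cross)

  set.seed(99)
  n <- 1e5
  hits <- replicate(n, {
    mA <- sample(mother$A, 1); pA <- sample(mother$A, 1)
    mB <- sample(mother$B, 1)
    mA == "a" && pA == "a" && mB == "b"
  })
  p_hat <- mean(hits)
  se <- sqrt(p_hat * (1 - p_hat) / n)
  expect_lt(abs(p_hat - exact), 3 * se)
})
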