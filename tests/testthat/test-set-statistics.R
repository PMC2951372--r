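test_that("hypergeometric tails are exact", {
  ## drawing all 5 successes in 5 draws from 5/10: 1/choose(10,5) = 1/252
  expect_equal(hypergeom_tail(10, 5, 5, 5, "upper"), 1 / 252)
  ## upper tail at k = 0 is the certain event
  expect_equal(hypergeom_tail(10, 5, 5, 0, "upper"), 1)
  ## lower tail at k = 0 equals the point mass at 0
  expect_equal(hypergeom_tail(20, 8, 6, 0, "lower"),
               choose(12, 6) / choose(20, 6))
  expect_error(hypergeom_tail(10, 12, 5, 2), "inconsistent")
  expect_error(hypergeom_tail(10, 5, 5, 6), "inconsistent")
})

test_that("upper and lower tails are complementary", {
  set.seed(71)
  for (i in 1:50) {
    N <- sample(5:60, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    rng <- max(0, n + K - N):min(K, n)
    k <- rng[sample.int(length(rng), 1)]
    up <- hypergeom_tail(N, K, n, k, "upper")
    lo <- if (k >= 1) hypergeom_tail(N, K, n, k - 1, "lower") else 0
    expect_equal(up + lo, 1)
  }
})

test_that("BH adjustment follows the step-up rule and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(72)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("overlap significance matches exhaustive enumeration (N <= 12)", {
  universe <- letters[1:12]
  cases <- list(c(K = 5, n = 4), c(K = 7, n = 6), c(K = 3, n = 9))
  for (cs in cases) {
    set_a <- universe[seq_len(cs[["K"]])]
    for (k_obs in 0:min(cs[["K"]], cs[["n"]])) {
      ## exact tail from scratch over all draws of size n
      exact <- enum_hyper_upper(12, cs[["K"]], cs[["n"]], k_obs)
      got <- hypergeom_tail(12, cs[["K"]], cs[["n"]], k_obs, "upper")
      expect_equal(got, exact)
    }
    ## overlap_significance wires the counts correctly
    set_b <- c(universe[seq_len(min(2, cs[["n"]]))],
               rev(universe)[seq_len(cs[["n"]] - min(2, cs[["n"]]))])
    r <- overlap_significance(set_a, set_b, universe)
    expect_identical(r$k, length(intersect(set_a, set_b)))
    expect_equal(r$p_enrich,
                 enum_hyper_upper(12, length(set_a), length(set_b), r$k))
  }

  ## boundary behavior
  disj <- overlap_significance(letters[1:3], letters[4:6], letters[1:12])
  expect_gt(disj$p_enrich, 0.5)
  nested <- overlap_significance(letters[1:6], letters[1:3], letters[1:12])
  expect_equal(nested$p_enrich, phyper(2, 6, 6, 3, lower.tail = FALSE))
  expect_error(overlap_significance(c("a", "zz"), "a", letters), "subset")
})

test_that("the overlap-test calibration design has near-nominal size", {
  ## analytic achieved size of the nominal-0.05 upper-tail test for the
  ## design used by the calibration checks (universe 1000, sets of 150)
  k <- 0:150
  pu <- phyper(k - 1, 150, 850, 150, lower.tail = FALSE)
  size <- max(pu[pu <= 0.05])
  expect_gt(size, 0.03)
  expect_lt(size, 0.07)
  expect_equal(round(size, 3), 0.044)
})

test_that("superfamily enrichment detects a planted overrepresentation", {
  set.seed(73)
  fams <- c("LTR/GYPSY", "LTR/COPIA", "LINE/L1", "DNA/MuDR", "RC/Helitron")
  n_bg <- 500
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    sf <- sample(fams, n_bg, replace = TRUE)
    ## targets sample LTR/COPIA five times more often than the rest
    w <- ifelse(sf == "LTR/COPIA", 5, 1)
    target <- seq_len(n_bg) %in% sample.int(n_bg, 100, prob = w)
    calls <- data.frame(feature_id = paste0("te", 1:n_bg),
                        feature_type = "TE", superfamily = sf,
                        gene_score = NA, is_target = target,
                        target_class = ifelse(target, "specific",
                                              "non_target"),
                        in_heterochromatin = FALSE, stringsAsFactors = FALSE)
    res <- superfamily_enrichment(calls, "specific")
    if (res$p_enrich_adj[res$label == "LTR/COPIA"] < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 18L)

  expect_error(superfamily_enrichment(
    data.frame(feature_id = "g", feature_type = "gene", superfamily = "",
               gene_score = 1, is_target = TRUE, target_class = "shared",
               in_heterochromatin = FALSE)), "background")
})

test_that("category enrichment filters at the critical adjusted p-value", {
  bg <- paste0("g", 1:500)
  targets <- paste0("g", 1:25)
  cmap <- rbind(
    data.frame(feature_id = targets, category = "perfect"),
    data.frame(feature_id = sample(bg, 200), category = "noise"))
  res <- category_enrichment(targets, cmap, bg)
  expect_true(res$passes[res$label == "perfect"])

  ## an empty category (no member in the background) is skipped with a note
  cmap2 <- rbind(cmap, data.frame(feature_id = "not_probed",
                                  category = "ghost"))
  res2 <- category_enrichment(targets, cmap2, bg)
  expect_false("ghost" %in% res2$label)
  expect_identical(attr(res2, "skipped"), "ghost")
})
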