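feat <- function(id, start, end, chrom = "chr1", type = "gene",
                 strand = "+") {
  data.frame(feature_id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, feature_type = type,
             superfamily = "", stringsAsFactors = FALSE)
}

test_that("gene_score is the 75th percentile of contained probe scores", {
  g <- feat("g1", 0, 1000)
  sc <- make_scores(c(100, 300, 500, 700), c(1, 2, 3, 4))
  ## h = (4-1)*0.75 = 2.25 -> 3 + 0.25 * (4 - 3) = 3.25
  expect_equal(gene_score(g, sc), 3.25)

  single <- make_scores(500, 5.1)
  expect_equal(gene_score(g, single), 5.1)

  ## feature shorter than any probe -> no contained probe -> absent
  tiny <- feat("g2", 100, 110)
  expect_true(is.na(gene_score(tiny, sc)))

  ## containment requires the whole probe inside the transcribed extent
  edge <- feat("g3", 0, 520)  # probe at 500 ends at 525: excluded
  expect_equal(gene_score(edge, sc), pctl(c(1, 2), 0.75))
})

test_that("gene_score is invariant to probe order and coordinate translation", {
  set.seed(41)
  g <- rbind(feat("a", 100, 2000), feat("b", 2500, 6000))
  sc <- make_scores(sort(sample.int(7000, 150)), rnorm(150))
  base <- gene_score(g, sc)

  sc_shift <- sc
  sc_shift$start <- sc$start + 10000L
  sc_shift$end <- sc$end + 10000L
  g_shift <- g
  g_shift$start <- g$start + 10000L
  g_shift$end <- g$end + 10000L
  expect_equal(gene_score(g_shift, sc_shift), base)
})

test_that("region overlap defines targets with half-open semantics", {
  regions <- data.frame(region_id = "r1", chrom = "chr1", start = 100L,
                        end = 400L, n_probes = 5L, region_score = 4)
  expect_true(call_targets(feat("g1", 399, 800), regions))   # 1-bp overlap
  expect_false(call_targets(feat("g2", 400, 800), regions))  # abutment
  expect_false(call_targets(feat("g3", 500, 800), regions))

  ## random features and regions match the brute-force intersection
  set.seed(42)
  for (rep in 1:20) {
    fs <- sample.int(50000, 40)
    features <- do.call(rbind, lapply(seq_along(fs), function(i)
      feat(paste0("f", i), fs[i], fs[i] + sample(200:3000, 1))))
    rs <- sort(sample.int(50000, 15))
    regions <- data.frame(chrom = "chr1", start = rs,
                          end = rs + sample(300:2000, 15, replace = TRUE))
    got <- call_targets(features, regions)
    want <- vapply(seq_len(nrow(features)), function(i) {
      any(pmax(features$start[i], regions$start) <
            pmin(features$end[i], regions$end))
    }, logical(1))
    expect_identical(got, want)
  }
})

test_that("classification against reference lists partitions the targets", {
  cl <- classify_targets(c("a", "b", "c"), c("b", "c", "d"))
  expect_identical(unname(cl$class[c("a", "b", "c")]),
                   c("specific", "shared", "shared"))
  expect_equal(cl$counts$pct[cl$counts$class == "shared"], 66.7)

  allspec <- classify_targets(c("a", "b"), character())
  expect_true(all(allspec$class == "specific"))

  ## duplicated ids are deduplicated; shared + specific = targets
  dup <- classify_targets(c("a", "a", "b"), list(c("b"), c("b", "z")))
  expect_identical(sum(dup$counts$n), 2L)
  for (s in 1:10) {
    set.seed(s)
    t_ids <- sample(letters, sample(5:20, 1))
    ref <- sample(letters, sample(0:20, 1))
    cc <- classify_targets(t_ids, ref)
    expect_identical(sum(cc$counts$n), length(unique(t_ids)))
  }
})

test_that("composition fractions sum to one per group", {
  calls <- data.frame(
    feature_id = paste0("f", 1:8),
    feature_type = rep(c("gene", "pseudogene", "TE", "TEG"), 2),
    superfamily = "",
    gene_score = 1,
    is_target = c(rep(TRUE, 4), rep(FALSE, 4)),
    target_class = c(rep("shared", 2), rep("specific", 2),
                     rep("non_target", 4)),
    in_heterochromatin = c(TRUE, rep(FALSE, 7)),
    stringsAsFactors = FALSE)
  comp <- class_composition(calls)
  tc <- comp$type_composition
  expect_equal(tc$fraction[tc$group == "targets"], rep(0.25, 4))
  for (g in unique(tc$group)) {
    expect_equal(sum(tc$fraction[tc$group == g]), 1)
  }
  het <- comp$heterochromatin
  expect_equal(het$het_fraction[het$group == "probed" &
                                  het$feature_type == "gene"], 0.5)

  ## no targets: probed column still populated
  none <- calls
  none$is_target <- FALSE
  none$target_class <- "non_target"
  comp2 <- class_composition(none)
  expect_true(all(comp2$type_composition$group == "probed"))
})

test_that("target_calls joins scores, classes and heterochromatin", {
  spec <- tiny_spec(len = 10000L,
                    het = data.frame(chrom = "chr1", start = 6000L,
                                     end = 9000L))
  ann <- rbind(feat("g1", 100, 1500), feat("g2", 3000, 4200),
               feat("te1", 6500, 7800, type = "TE"))
  ann$superfamily[3] <- "LTR/COPIA"
  sc <- make_scores(seq(0, 9000, by = 50), rep(1, 181))
  sc$score[sc$start >= 100 & sc$start < 1500] <- 5
  regions <- call_regions(sc, region_call_params())
  calls <- target_calls(ann, sc, regions, reference_lists = "g1", spec)
  expect_identical(calls$is_target, c(TRUE, FALSE, FALSE))
  expect_identical(calls$target_class, c("shared", "non_target",
                                         "non_target"))
  expect_identical(calls$in_heterochromatin, c(FALSE, FALSE, TRUE))
  expect_true(calls$gene_score[1] > calls$gene_score[2])
})
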