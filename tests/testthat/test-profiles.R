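gene_row <- function(id, start, end, strand = "+", chrom = "chr1") {
  data.frame(feature_id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, feature_type = "gene",
             superfamily = "", stringsAsFactors = FALSE)
}

test_that("a flat score field gives a flat metagene profile", {
  sc <- make_scores(seq(0, 30000, by = 40), rep(0, 751))
  sc$score <- rep(2.5, 751)
  genes <- rbind(gene_row("g1", 5000, 9000),
                 gene_row("g2", 14000, 20000, strand = "-"))
  prof <- metagene_profile(sc, genes)
  expect_identical(nrow(prof), 60L)  # 20 + 20 body + 20
  expect_true(all(abs(prof$mean_score - 2.5) < 1e-12))
  expect_identical(sum(prof$n_probes > 0L), 60L)
})

test_that("body bins are strand-aware (5' to 3')", {
  ## minus-strand gene with signal only in its 5'-most 10 percent, which in
  ## genomic coordinates is the right-hand end of the body
  g <- gene_row("g", 10000, 20000, strand = "-")
  sc <- make_scores(seq(6000, 24000, by = 50), rep(0, 361))
  hot <- sc$start >= 19000 & sc$start < 20000
  sc$score[hot] <- 10
  prof <- metagene_profile(sc, g)
  body <- prof[prof$zone == "body", ]
  peak_bins <- body$bin[which(body$mean_score > 5)] - 20L
  expect_true(all(peak_bins %in% 1:2))
  expect_true(all(body$mean_score[body$bin - 20L >= 3] < 1))
})

test_that("metagene averaging equals a naive per-gene recomputation", {
  set.seed(51)
  sc <- make_scores(seq(0, 100000, by = 35), rep(0, 2858))
  sc$score <- rnorm(nrow(sc))
  genes <- do.call(rbind, lapply(1:50, function(i) {
    s <- sample.int(90000, 1)
    gene_row(paste0("g", i), s, s + sample(1000:5000, 1),
             strand = sample(c("+", "-"), 1))
  }))
  params <- profile_params()
  prof <- metagene_profile(sc, genes, params)

  nf <- params$flank_bp / params$flank_bin_bp
  sums <- numeric(60); counts <- integer(60)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    for (j in seq_len(nrow(sc))) {
      p <- sc$start[j]
      len <- g$end - g$start
      b <- NA
      if (g$strand == "+") {
        if (p >= g$start - 2000 && p < g$start)
          b <- (p - (g$start - 2000)) %/% 100 + 1
        else if (p >= g$start && p < g$end)
          b <- nf + min(20, floor((p - g$start) / len * 20) + 1)
        else if (p >= g$end && p < g$end + 2000)
          b <- nf + 20 + (p - g$end) %/% 100 + 1
      } else {
        if (p >= g$end && p < g$end + 2000)
          b <- (g$end + 2000 - 1 - p) %/% 100 + 1
        else if (p >= g$start && p < g$end)
          b <- nf + min(20, floor((g$end - 1 - p) / len * 20) + 1)
        else if (p >= g$start - 2000 && p < g$start)
          b <- nf + 20 + (g$start - 1 - p) %/% 100 + 1
      }
      if (!is.na(b)) {
        sums[b] <- sums[b] + sc$score[j]
        counts[b] <- counts[b] + 1L
      }
    }
  }
  naive <- ifelse(counts > 0, sums / pmax(counts, 1), NA)
  expect_equal(prof$mean_score, naive)
  expect_identical(prof$n_probes, counts)
})

test_that("empty gene sets are rejected", {
  sc <- make_scores(c(0, 100), c(1, 1))
  expect_error(metagene_profile(sc, gene_row("g", 1, 2)[0, ]), "non-empty")
})

test_that("chromosome density counts elements by midpoint window", {
  spec <- genome_spec(data.frame(name = c("chr1", "chr2"),
                                 length = c(600000L, 600000L)))
  ## one region with midpoint at 250 kb -> second 200-kb window
  regions <- data.frame(chrom = "chr1", start = 249000L, end = 251000L)
  d <- chromosome_density(regions,
                          data.frame(feature_id = character(),
                                     chrom = character(), start = integer(),
                                     end = integer(),
                                     feature_type = character()),
                          spec)
  expect_identical(d$n_regions[d$chrom == "chr1"], c(0L, 1L, 0L))
  ## empty chromosome keeps its all-zero rows
  expect_identical(d$n_regions[d$chrom == "chr2"], c(0L, 0L, 0L))

  set.seed(61)
  st <- sample.int(590000, 200)
  ann <- data.frame(feature_id = paste0("f", 1:200), chrom = "chr1",
                    start = st, end = st + 1000L,
                    feature_type = sample(c("gene", "TE", "TEG"), 200,
                                          replace = TRUE))
  d2 <- chromosome_density(regions, ann, spec)
  expect_identical(sum(d2$n_genes), sum(ann$feature_type == "gene"))
  expect_identical(sum(d2$n_tes), sum(ann$feature_type %in% c("TE", "TEG")))
})

test_that("score summaries use the shared quartile convention", {
  calls <- data.frame(feature_id = paste0("g", 1:6),
                      feature_type = "gene", superfamily = "",
                      gene_score = c(1, 2, 3, 4, 5, 9),
                      is_target = TRUE,
                      target_class = c(rep("shared", 5), "specific"),
                      in_heterochromatin = FALSE, stringsAsFactors = FALSE)
  s <- score_by_group(calls)
  shared <- s[s$class == "shared", ]
  expect_equal(c(shared$q1, shared$median, shared$q3), c(2, 3, 4))
  single <- s[s$class == "specific", ]
  expect_true(all(unlist(single[c("min", "q1", "median", "q3", "max")]) == 9))

  ## expression stratification at log2 = 4.2
  expr <- setNames(c(1, 2, 3, 5, 6, 2), calls$feature_id)
  s2 <- score_by_group(calls, expression = expr)
  expect_identical(s2$n[s2$class == "shared" & s2$stratum == "low"], 3L)
  expect_identical(s2$n[s2$class == "shared" & s2$stratum == "moderate"], 2L)

  ## empty classes are omitted
  none <- score_by_group(calls[calls$target_class == "shared", ])
  expect_false("specific" %in% none$class)
})
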