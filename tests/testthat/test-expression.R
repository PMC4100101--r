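test_that("hypergeometric tail probabilities match exhaustive enumeration", {
  # N = 20, K = 5, n = 10: enumerate all C(20,10) draws
  bg <- sprintf("g%02d", 1:20)
  fg <- bg[1:10]
  map <- data.frame(gene = bg[1:5], term = "T1")
  res <- hypergeom_enrich(fg, bg, map)
  k <- res$k[res$term == "T1"]
  expect_equal(res$p[res$term == "T1"],
               oracle_hyper_tail(20, 5, 10, k), tolerance = 1e-12)
  # a second configuration with a different overlap
  fg2 <- bg[c(1, 6:12)]
  res2 <- hypergeom_enrich(fg2, bg, map)
  expect_equal(res2$p, oracle_hyper_tail(20, 5, 8, res2$k),
               tolerance = 1e-12)
})

test_that("a term drawn at the background proportion is not enriched", {
  bg <- sprintf("g%03d", 1:100)
  map <- data.frame(gene = bg[1:20], term = "T1")   # 20% of background
  fg <- c(bg[1:4], bg[21:36])                        # 20% of foreground
  res <- hypergeom_enrich(fg, bg, map)
  expect_gt(res$p, 0.05)
  expect_false(res$enriched)
})

test_that("zero overlap gives p = 1 and missing terms warn", {
  bg <- sprintf("g%02d", 1:30)
  map <- data.frame(gene = bg[1:6], term = "T1")
  res <- hypergeom_enrich(bg[7:16], bg, map)
  expect_equal(res$p, 1)
  map2 <- rbind(map, data.frame(gene = "notInBackground", term = "orphan"))
  expect_warning(hypergeom_enrich(c(bg[1:3], "notInBackground"), bg, map2),
                 "orphan")
})

test_that("BH adjustment is monotone, bounded and above raw p", {
  set.seed(91)
  counts <- simulate_counts(300, c(1e6, 1e6), dispersion = 0, seed = 92)$counts
  degs <- call_degs(counts)
  expect_true(all(degs$q >= degs$p - 1e-12))
  expect_true(all(degs$q <= 1))
  o <- order(degs$p)
  expect_true(all(diff(degs$q[o]) >= -1e-12))
})

test_that("equal counts with equal libraries are null genes", {
  counts <- data.frame(gene = c("a", "b"), count_a = c(500, 0),
                       count_b = c(500, 0))
  degs <- call_degs(counts, lib_sizes = c(1e6, 1e6))
  expect_equal(degs$log2_fold[1], 0)
  expect_false(degs$is_deg[1])
  expect_equal(degs$p[2], 1)        # all-zero gene
  expect_true(degs$all_zero[2])
  expect_false(degs$is_deg[2])
})

test_that("DEG calling is label-symmetric", {
  sim <- simulate_counts(200, c(1.2e6, 0.8e6),
                         planted = data.frame(gene = 1:10, fold = 8),
                         dispersion = 0, seed = 93, base_means = 300)
  counts <- sim$counts
  fwd <- call_degs(counts, lib_sizes = c(1.2e6, 0.8e6))
  swapped <- data.frame(gene = counts$gene, count_a = counts$count_b,
                        count_b = counts$count_a)
  rev <- call_degs(swapped, lib_sizes = c(0.8e6, 1.2e6))
  expect_equal(fwd$p, rev$p, tolerance = 1e-9)
  ok <- is.finite(fwd$log2_fold)
  expect_equal(fwd$log2_fold[ok], -rev$log2_fold[ok], tolerance = 1e-9)
  expect_identical(fwd$is_deg, rev$is_deg)
})

test_that("planted-truth recovery on expected counts: exactly folds >= 4", {
  # noise-free expected counts isolate the decision rule at the cutoffs;
  # under sampling noise a gene at exactly the 4-fold boundary is a coin
  # flip by construction (see the methods vignette)
  folds <- c(1, 2, 4, 8, 16)
  counts <- data.frame(gene = sprintf("f%g", folds),
                       count_a = rep(500, 5),
                       count_b = 500 * folds)
  pad <- data.frame(gene = sprintf("null%d", 1:50),
                    count_a = rep(500, 50), count_b = rep(500, 50))
  degs <- call_degs(rbind(counts, pad), lib_sizes = c(1e6, 1e6))
  called <- degs$gene[degs$is_deg]
  expect_setequal(called, c("f4", "f8", "f16"))
})

test_that("null tables stay below the FDR budget", {
  sim <- simulate_counts(2000, c(1e6, 1e6), dispersion = 0, seed = 94,
                         base_means = 200)
  degs <- call_degs(sim$counts, lib_sizes = c(1e6, 1e6))
  expect_lte(sum(degs$is_deg), 2)
})

test_that("expression groups separate high-both from one-sided DEGs", {
  degs <- data.frame(gene = c("both", "aOnly", "bOnly"),
                     cpm_a = c(900, 800, 5), cpm_b = c(300, 5, 800),
                     log2_fold = c(-1.58, -7.3, 7.3),
                     p = c(1e-10, 1e-10, 1e-10), q = c(1e-9, 1e-9, 1e-9),
                     is_deg = TRUE, all_zero = FALSE)
  g <- group_degs(degs, high_threshold = 100)
  got <- setNames(g$groups$group, g$groups$gene)
  expect_identical(unname(got[c("both", "aOnly", "bOnly")]),
                   c("I", "II-a", "II-b"))
  expect_match(g$dendrogram_newick, "^\\(")
})

test_that("a single DEG forms its own trivial cluster", {
  degs <- data.frame(gene = "solo", cpm_a = 800, cpm_b = 5,
                     log2_fold = -7.3, p = 1e-10, q = 1e-9,
                     is_deg = TRUE, all_zero = FALSE)
  g <- group_degs(degs)
  expect_identical(g$groups$gene, "solo")
  expect_null(g$hclust)
})

test_that("ddCq folds follow the closed form and calibrator folds are 1", {
  cq <- rbind(
    data.frame(gene = "g1", group = "dip", cq_target = c(20, 20, 20),
               cq_reference = c(15, 15, 15)),
    data.frame(gene = "g1", group = "tri", cq_target = c(18, 18, 18),
               cq_reference = c(15, 15, 15)),
    data.frame(gene = "g2", group = "dip", cq_target = c(22, 22),
               cq_reference = c(15, 15)),
    data.frame(gene = "g2", group = "tri", cq_target = c(23, 23),
               cq_reference = c(15, 15)))
  res <- ddcq(cq, calibrator = "dip")
  f <- res$folds
  expect_equal(f$fold[f$gene == "g1" & f$group == "dip"], 1)   # ddCq = 0
  expect_equal(f$fold[f$gene == "g1" & f$group == "tri"], 4)   # ddCq = -2
  expect_equal(f$fold[f$gene == "g2" & f$group == "tri"], 0.5) # ddCq = +1
})

test_that("ddCq validates reference measurements and runs the group test", {
  cq <- data.frame(gene = "g1", group = c("dip", "tri"),
                   cq_target = c(20, 18), cq_reference = c(15, NA))
  expect_error(ddcq(cq, calibrator = "dip"), "missing reference Cq for gene g1")
  set.seed(95)
  cq2 <- data.frame(gene = "g1",
                    group = rep(c("dip", "tri"), each = 3),
                    cq_target = c(20.1, 20.0, 19.9, 18.2, 18.0, 17.8),
                    cq_reference = rep(15, 6))
  res <- ddcq(cq2, calibrator = "dip")
  expect_equal(nrow(res$tests), 1)
  expect_lt(res$tests$p, 0.01)
})
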