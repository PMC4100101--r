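test_that("a query identical to a target is its best hit with score = length", {
  set.seed(51)
  t1 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  t2 <- paste(sample(c("A", "C", "G", "T"), 380, TRUE), collapse = "")
  hits <- all_pairs_best_hits(c(q = t1), c(t1 = t1, t2 = t2))
  expect_identical(hits$ab$target, "t1")
  expect_equal(hits$ab$score, 400)
  expect_equal(hits$ab$aln_len, 400)
})

test_that("best-hit maps equal a brute-force alignment oracle on a 3x3 set", {
  set.seed(52)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  base <- mk(160)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  set_a <- c(a1 = base, a2 = mutate(base, 25), a3 = mk(160))
  set_b <- c(b1 = mutate(base, 4), b2 = mutate(base, 35), b3 = mk(160))
  hits <- all_pairs_best_hits(set_a, set_b)
  for (q in names(set_a)) {
    oracle_scores <- vapply(set_b, function(t)
      oracle_local_score(set_a[[q]], t), numeric(1))
    got <- hits$ab[hits$ab$query == q, ]
    expect_equal(got$score, max(oracle_scores))
    if (sum(oracle_scores == max(oracle_scores)) == 1L) {
      # score ties are resolved by alignment length, invisible to the
      # score-only oracle
      expect_identical(got$target, names(which.max(oracle_scores)))
    }
  }
  for (q in names(set_b)) {
    oracle_scores <- vapply(set_a, function(t)
      oracle_local_score(set_b[[q]], t), numeric(1))
    got <- hits$ba[hits$ba$query == q, ]
    expect_equal(got$score, max(oracle_scores))
  }
})

test_that("reciprocal best hits require mutuality and 300 bp of alignment", {
  ab <- data.frame(query = c("a1", "a2", "a3"),
                   target = c("b1", "b2", "b3"),
                   score = c(350, 260, 300),
                   aln_len = c(350, 250, 310))
  ba <- data.frame(query = c("b1", "b2", "b3"),
                   target = c("a1", "a2", "a1"),
                   score = c(350, 260, 200),
                   aln_len = c(350, 250, 200))
  rbh <- reciprocal_best_hits(ab, ba, min_aln = 300)
  # a1/b1 mutual and long enough; a2/b2 mutual but 250 bp; a3->b3 not mutual
  expect_identical(rbh$id_a, "a1")
  expect_identical(rbh$id_b, "b1")
})

test_that("RBH output is symmetric in the two transcript sets", {
  set.seed(53)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  g1 <- mk(350); g2 <- mk(340)
  set_a <- c(x1 = g1, x2 = g2, x3 = mk(330))
  set_b <- c(y1 = mutate(g1, 10), y2 = mutate(g2, 12))
  h1 <- all_pairs_best_hits(set_a, set_b)
  h2 <- all_pairs_best_hits(set_b, set_a)
  r1 <- reciprocal_best_hits(h1$ab, h1$ba, min_aln = 300)
  r2 <- reciprocal_best_hits(h2$ab, h2$ba, min_aln = 300)
  p1 <- sort(paste(r1$id_a, r1$id_b))
  p2 <- sort(paste(r2$id_b, r2$id_a))
  expect_identical(p1, p2)
  expect_gt(nrow(r1), 0)
})

test_that("codon alignment of identical CDS has no gaps and full counts", {
  cds <- random_cds(40, seed = 61)
  aln <- build_codon_alignment(cds, cds)
  expect_false(any(aln$codons == "---"))
  st <- ng86_stats(aln)
  expect_equal(st$n_codons, 40)
  expect_equal(st$S + st$N, 120)
})

test_that("a single inserted codon becomes exactly one codon gap column", {
  cds <- random_cds(40, seed = 62)
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  ins <- paste(append(cods, "GAA", after = 20), collapse = "")
  aln <- build_codon_alignment(cds, ins)
  expect_identical(sum(aln$codons[1, ] == "---"), 1L)
  expect_identical(sum(aln$codons[2, ] == "---"), 0L)
})

test_that("back-threaded codons re-translate to the protein alignment", {
  for (seed in c(63, 64, 65)) {
    set.seed(seed)
    a <- random_cds(35, seed = seed)
    cods <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
    # drop a codon and add point changes to make a realistic partner
    cods_b <- cods[-sample(35, 1)]
    b <- paste(cods_b, collapse = "")
    aln <- build_codon_alignment(a, b)
    tr <- function(row) vapply(row, function(cod) {
      if (cod == "---") "-" else GC_TAB[[cod]]
    }, character(1))
    pa <- paste(tr(aln$codons[1, ]), collapse = "")
    pb <- paste(tr(aln$codons[2, ]), collapse = "")
    # re-translated rows must be gapped versions of the input proteins
    expect_identical(gsub("-", "", pa),
                     paste(GC_TAB[cods], collapse = ""))
    expect_identical(gsub("-", "", pb),
                     paste(GC_TAB[cods_b], collapse = ""))
    expect_identical(nchar(pa), nchar(pb))
  }
})

test_that("internal stop codons are rejected with the offending id", {
  good <- random_cds(20, seed = 66)
  bad <- paste0(substr(good, 1, 30), "TAA", substr(good, 34, 60))
  expect_error(build_codon_alignment(bad, good, id_a = "brokenSeq"),
               "internal stop codon in brokenSeq")
})

test_that("NG86 distances are zero for identical sequences", {
  cds <- random_cds(30, seed = 67)
  st <- ng86_stats(cds, cds)
  expect_equal(st$Sd, 0)
  expect_equal(st$Nd, 0)
  expect_equal(st$Ks, 0)
  expect_equal(st$Ka, 0)
})

test_that("NG86 statistics are symmetric in the two sequences", {
  for (seed in 1:8) {
    p <- evolve_ortholog_pair(60, 0.1, omega = 0.3, seed = 700 + seed)
    s1 <- ng86_stats(p$seq_a, p$seq_b)
    s2 <- ng86_stats(p$seq_b, p$seq_a)
    expect_equal(s1$S, s2$S)
    expect_equal(s1$Sd, s2$Sd)
    expect_equal(s1$Nd, s2$Nd)
    expect_equal(s1$Ks, s2$Ks)
  }
})

test_that("site and difference counts match the brute-force oracle exactly", {
  # every single-codon alignment of sense codons
  for (c1 in SENSE_CODONS) {
    for (c2 in SENSE_CODONS) {
      st <- ng86_stats(matrix(c(c1, c2), nrow = 2))
      oc <- oracle_ng86(c1, c2)
      if (abs(st$S - oc$S) > 1e-9 || abs(st$Sd - oc$Sd) > 1e-9 ||
          abs(st$Nd - oc$Nd) > 1e-9) {
        fail(sprintf("NG86 mismatch for %s/%s", c1, c2))
      }
    }
  }
  succeed()
})

test_that("multi-codon alignments match the oracle (additivity)", {
  set.seed(71)
  for (rep in 1:40) {
    k <- sample(2:3, 1)
    c1 <- sample(SENSE_CODONS, k, TRUE)
    c2 <- sample(SENSE_CODONS, k, TRUE)
    st <- ng86_stats(matrix(c(c1, c2), nrow = 2, byrow = TRUE))
    oc <- oracle_ng86(c1, c2)
    expect_equal(st$S, oc$S, tolerance = 1e-12)
    expect_equal(st$N, oc$N, tolerance = 1e-12)
    expect_equal(st$Sd, oc$Sd, tolerance = 1e-12)
    expect_equal(st$Nd, oc$Nd, tolerance = 1e-12)
  }
})

test_that("gapped and ambiguous columns are excluded from counting", {
  m <- matrix(c("ATG", "---", "GGN", "CCT",
                "ATG", "AAA", "GGA", "CCC"), nrow = 2)
  st <- ng86_stats(m)
  expect_equal(st$n_codons, 2)    # ATG and CCT/CCC columns only
  m2 <- matrix(c("---", "---"), nrow = 2)
  expect_error(ng86_stats(m2), "no ungapped")
})

test_that("Ks is monotone in pS below saturation", {
  ps <- seq(0, 0.7, by = 0.05)
  ks <- -3 / 4 * log(1 - 4 / 3 * ps)
  expect_true(all(diff(ks) > 0))
  # and the estimator flags saturation
  st <- ng86_stats("TTA", "CTG")   # Leu/Leu, heavily synonymous
  expect_false(st$ks_defined)
  expect_true(is.na(st$Ks))
})

test_that("Ks histogram bins are half-open with left-edge labels", {
  h <- ks_histogram(c(0.0081, 0.0085, 0.0033), bin_width = 0.002)
  expect_equal(h$peak_ks, 0.008)
  expect_equal(unname(h$counts[c("0.002", "0.008")]), c(1L, 2L))
  expect_equal(sum(h$counts), 3)
  # exact boundary value falls into the bin it opens
  expect_equal(ks_histogram(0.008, 0.002)$peak_ks, 0.008)
  expect_equal(ks_histogram(0.006, 0.002)$peak_ks, 0.006)
})

test_that("undefined Ks values are counted apart and empty input degrades", {
  h <- ks_histogram(c(0.001, NA, NA), 0.002)
  expect_equal(h$n_undefined, 2)
  expect_equal(h$n_pairs, 3)
  expect_equal(sum(h$counts) + h$n_undefined, h$n_pairs)
  h0 <- ks_histogram(numeric(0), 0.002)
  expect_true(is.na(h0$peak_ks))
  expect_equal(h0$n_pairs, 0)
})

test_that("clock dating reproduces the published times by truncation", {
  d <- date_divergence(0.008, 3.51e-9, mode_interval = c(0.006, 0.01))
  expect_equal(d$t_my, 2.2)
  expect_equal(d$t_low_my, 1.7)
  expect_equal(d$t_high_my, 2.8)
  expect_equal(d$t_years, 0.008 / 3.51e-9)
  expect_equal(date_divergence(0, 3.51e-9)$t_my, 0)
  expect_error(date_divergence(0.008, 0), "rate")
})

test_that("divergence time is linear in the Ks peak", {
  r <- 3.51e-9
  expect_equal(date_divergence(0.016, r)$t_years,
               2 * date_divergence(0.008, r)$t_years)
})

test_that("mean Ks recovery is within 10% of the planted divergence", {
  for (target in c(0.005, 0.008, 0.02, 0.05)) {
    est <- vapply(1:200, function(i) {
      p <- evolve_ortholog_pair(1000, target, omega = 0,
                                seed = 40000 + round(target * 1e5) + i)
      ng86_stats(p$seq_a, p$seq_b)$Ks
    }, numeric(1))
    expect_lt(abs(mean(est) - target) / target, 0.1)
  }
})

test_that("the modal Ks bin brackets a mid-bin planted divergence", {
  # 4000-codon pairs make the count lattice much finer than the bin width,
  # so the modal bin is statistically stable; see the methods vignette for
  # why edge-aligned targets are not asserted here
  target <- 0.005
  est <- vapply(1:300, function(i) {
    p <- evolve_ortholog_pair(4000, target, omega = 0, seed = 50000 + i)
    ng86_stats(p$seq_a, p$seq_b)$Ks
  }, numeric(1))
  h <- ks_histogram(est, 0.002)
  expect_equal(h$peak_ks, 0.004)
  expect_true(target >= h$peak_ks && target < h$peak_ks + 0.002)
})
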