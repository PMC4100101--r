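# Functional-category enrichment, differential expression without replicates,
# expression-pattern grouping, and 2^-ddCq relative quantification.

#' Hypergeometric over-representation of functional categories
#'
#' For each term, the probability of drawing at least `k` in-term genes in
#' `n` draws (the foreground) from an urn of `N` background genes of which
#' `K` carry the term. Terms with raw `p < 0.05` are flagged enriched, the
#' convention of category-enrichment tables in comparative transcriptomics; a
#' Benjamini-Hochberg column is provided alongside for stricter use.
#'
#' @param fg character vector of foreground gene ids.
#' @param bg character vector of background gene ids (the urn; foreground
#'   genes should be contained in it).
#' @param categories data frame with columns `gene`, `term` (a gene may carry
#'   several terms).
#' @param alpha enrichment threshold on the raw p-value.
#' @return data frame sorted by `p`: `term`, `k`, `n`, `K`, `N`, `p`, `q`
#'   (BH-adjusted), `enriched`.
#' @export
hypergeom_enrich <- function(fg, bg, categories, alpha = 0.05) {
  stopifnot(length(fg) > 0, length(bg) > 0)
  fg <- unique(fg); bg <- unique(bg)
  N <- length(bg); n <- length(fg)
  cat_bg <- categories[categories$gene %in% bg, , drop = FALSE]
  orphan <- setdiff(unique(categories$term[categories$gene %in% fg]),
                    unique(cat_bg$term))
  if (length(orphan)) {
    warning("skipping term(s) absent from background: ",
            paste(orphan, collapse = ", "))
  }
  terms <- unique(cat_bg$term)
  rows <- lapply(terms, function(tm) {
    genes_tm <- unique(cat_bg$gene[cat_bg$term == tm])
    K <- length(genes_tm)
    k <- length(intersect(genes_tm, fg))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$p < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call differentially expressed genes between two pooled libraries
#'
#' Without biological replicates, each gene's two counts are compared with an
#' exact two-sided binomial test conditional on their sum, with success
#' probability `lib_sizes[1] / sum(lib_sizes)` under the null of equal
#' relative expression. P-values are Benjamini-Hochberg adjusted across
#' genes; expression is normalised to counts per million; a gene is a DEG
#' when `q <= fdr` and its absolute log2 fold change reaches
#' `log2(min_fold)`. Genes with zero counts in both conditions get `p = 1`
#' and are flagged.
#'
#' @param counts data frame with columns `gene`, `count_a`, `count_b`
#'   (nonnegative integers).
#' @param lib_sizes length-2 library sizes; defaults to the column sums.
#' @param fdr adjusted-p cutoff.
#' @param min_fold minimum fold change (>= 1).
#' @return data frame: `gene`, `cpm_a`, `cpm_b`, `log2_fold` (condition B
#'   over condition A), `p`, `q`, `is_deg`, `all_zero`.
#' @export
call_degs <- function(counts, lib_sizes = NULL, fdr = 0.001, min_fold = 4) {
  stopifnot(all(counts$count_a >= 0), all(counts$count_b >= 0), min_fold >= 1)
  a <- counts$count_a; b <- counts$count_b
  if (is.null(lib_sizes)) lib_sizes <- c(sum(a), sum(b))
  stopifnot(length(lib_sizes) == 2L, all(lib_sizes > 0))
  p_null <- lib_sizes[1] / sum(lib_sizes)
  tot <- a + b
  p <- vapply(seq_along(a), function(i) {
    if (tot[i] == 0L) return(1)
    stats::binom.test(a[i], tot[i], p = p_null)$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  cpm_a <- a / lib_sizes[1] * 1e6
  cpm_b <- b / lib_sizes[2] * 1e6
  log2_fold <- log2(cpm_b) - log2(cpm_a)   # +-Inf when one side is zero
  all_zero <- tot == 0L
  log2_fold[all_zero] <- NA_real_
  is_deg <- !all_zero & q <= fdr & abs(log2_fold) >= log2(min_fold)
  data.frame(gene = counts$gene, cpm_a = cpm_a, cpm_b = cpm_b,
             log2_fold = log2_fold, p = p, q = q, is_deg = is_deg,
             all_zero = all_zero, stringsAsFactors = FALSE)
}

#' Group DEGs by expression pattern
#'
#' Average-linkage hierarchical clustering of DEGs on their log2(CPM+1)
#' profiles, with threshold-based group labels: Group I genes are highly
#' expressed (above `high_threshold` CPM) in both conditions; Group II genes
#' are high in one condition only, split into II-a (high in condition A) and
#' II-b (high in condition B).
#'
#' @param degs data frame from [call_degs()]; only rows with `is_deg` are
#'   grouped.
#' @param high_threshold CPM above which expression counts as high.
#' @return list with `groups` (data frame gene/group), `hclust` (`NULL` for
#'   fewer than 2 DEGs) and `dendrogram_newick`.
#' @export
group_degs <- function(degs, high_threshold = 100) {
  stopifnot(nrow(degs) > 0)
  d <- degs[degs$is_deg, , drop = FALSE]
  if (!nrow(d)) {
    return(list(groups = data.frame(gene = character(0), group = character(0)),
                hclust = NULL, dendrogram_newick = NA_character_))
  }
  high_a <- d$cpm_a >= high_threshold
  high_b <- d$cpm_b >= high_threshold
  group <- ifelse(high_a & high_b, "I",
                  ifelse(high_a, "II-a", ifelse(high_b, "II-b", "none")))
  hc <- NULL
  nwk <- NA_character_
  if (nrow(d) >= 2L) {
    prof <- cbind(log2(d$cpm_a + 1), log2(d$cpm_b + 1))
    rownames(prof) <- d$gene
    hc <- stats::hclust(stats::dist(prof), method = "average")
    nwk <- ape::write.tree(ape::as.phylo(hc))
  }
  list(groups = data.frame(gene = d$gene, group = group,
                           stringsAsFactors = FALSE),
       hclust = hc, dendrogram_newick = nwk)
}

#' Relative quantification by the comparative Cq (2^-ddCq) method
#'
#' Per replicate, `dCq = Cq_target - Cq_reference`; per gene and group,
#' `ddCq = mean dCq(group) - mean dCq(calibrator)` and the fold change is
#' `2^-ddCq` (so the calibrator group's fold is 1 by construction). Genes
#' measured in exactly two groups additionally get a two-sided Welch t test
#' on their per-replicate dCq values.
#'
#' @param measurements data frame with columns `gene`, `group`, `cq_target`,
#'   `cq_reference` (replicate rows allowed).
#' @param calibrator calibrator group label.
#' @return list with `folds` (gene, group, mean_dcq, ddcq, fold) and `tests`
#'   (gene, t, p) for two-group genes.
#' @export
ddcq <- function(measurements, calibrator) {
  m <- measurements
  if (any(is.na(m$cq_reference))) {
    stop("missing reference Cq for gene ",
         m$gene[which(is.na(m$cq_reference))[1]])
  }
  if (any(is.na(m$cq_target))) {
    stop("missing target Cq for gene ", m$gene[which(is.na(m$cq_target))[1]])
  }
  stopifnot(calibrator %in% m$group)
  m$dcq <- m$cq_target - m$cq_reference
  folds <- list(); tests <- list()
  for (g in unique(m$gene)) {
    sub <- m[m$gene == g, , drop = FALSE]
    if (!calibrator %in% sub$group) {
      stop("gene ", g, " has no measurements in calibrator group")
    }
    mean_dcq <- tapply(sub$dcq, sub$group, mean)
    dd <- mean_dcq - mean_dcq[[calibrator]]
    folds[[g]] <- data.frame(gene = g, group = names(mean_dcq),
                             mean_dcq = as.numeric(mean_dcq),
                             ddcq = as.numeric(dd),
                             fold = 2^(-as.numeric(dd)),
                             stringsAsFactors = FALSE)
    grps <- unique(sub$group)
    if (length(grps) == 2L && min(table(sub$group)) >= 2L) {
      tt <- tryCatch(stats::t.test(dcq ~ group, data = sub),
                     error = function(e) NULL)  # e.g. zero-variance replicates
      if (!is.null(tt)) {
        tests[[g]] <- data.frame(gene = g, t = unname(tt$statistic),
                                 p = tt$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  folds <- do.call(rbind, folds)
  rownames(folds) <- NULL
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(gene = character(0), t = numeric(0), p = numeric(0))
  rownames(tests) <- NULL
  list(folds = folds, tests = tests)
}
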