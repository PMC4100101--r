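# Synthetic-data generators. Every pipeline input can be produced here with a
# known ground truth, so estimator behaviour can be checked against planted
# values rather than against sequencing data.

#' Evolve a pair of orthologous coding sequences from a common ancestor
#'
#' The ancestor is a sequence of `n_codons` sense codons drawn uniformly (the
#' standard equal-frequency default of codon-evolution simulators). Divergence
#' is split evenly across the two lineages, as under a molecular clock. In
#' each lineage the number of synonymous events is Poisson with mean
#' `target_ks/2` per synonymous site (synonymous site content measured on the
#' ancestor, Nei-Gojobori fractional sites with stop neighbours excluded from
#' denominators); events land on positions with probability proportional to
#' the position's synonymous-site fraction and replace the codon with a
#' uniformly chosen synonymous neighbour. Nonsynonymous events are generated
#' the same way at a rate scaled by `omega`, choosing uniformly among
#' non-stop nonsynonymous neighbours. No substitution can create a stop
#' codon. Base exchangeability is uniform (no transition/transversion bias):
#' at the divergence depths this generator is used for, the counting
#' estimator under test is insensitive to kappa.
#'
#' @param n_codons number of codons in the ancestor (>= 10).
#' @param target_ks expected synonymous substitutions per synonymous site
#'   across the pair.
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param seed integer seed.
#' @return a list with `ancestor`, `seq_a`, `seq_b` (nucleotide strings),
#'   `true_syn` and `true_nonsyn` (counts of substitution events actually
#'   applied across both lineages), and `syn_sites_anc` (ancestral
#'   synonymous-site count).
#' @export
evolve_ortholog_pair <- function(n_codons, target_ks, omega = 0, seed = 1L) {
  stopifnot(n_codons >= 10, target_ks >= 0, omega >= 0)
  set.seed(seed)
  sense <- .codontab$sense
  syn_frac <- .codontab$syn_frac
  anc <- sample(sense, n_codons, replace = TRUE)

  pos_syn <- as.vector(t(syn_frac[anc, , drop = FALSE]))   # length 3n
  S_anc <- sum(pos_syn)
  N_anc <- 3 * n_codons - S_anc
  pos_nonsyn <- 1 - pos_syn

  evolve_lineage <- function(codons) {
    n_syn <- stats::rpois(1L, target_ks / 2 * S_anc)
    n_non <- if (omega > 0) stats::rpois(1L, omega * target_ks / 2 * N_anc)
             else 0L
    applied <- c(syn = 0L, nonsyn = 0L)
    apply_events <- function(n_ev, weights, kind) {
      if (n_ev == 0L) return()
      at <- sample.int(3L * n_codons, n_ev, replace = TRUE, prob = weights)
      for (pos in at) {
        ci <- (pos - 1L) %/% 3L + 1L
        p <- (pos - 1L) %% 3L + 1L
        nb <- .codontab$neighbours[[codons[ci], p]][[kind]]
        if (!length(nb)) next
        codons[ci] <<- if (length(nb) == 1L) nb else sample(nb, 1L)
        applied[kind] <<- applied[kind] + 1L
      }
    }
    apply_events(n_syn, pos_syn, "syn")
    apply_events(n_non, pos_nonsyn, "nonsyn")
    list(codons = codons, applied = applied)
  }
  a <- evolve_lineage(anc)
  b <- evolve_lineage(anc)
  list(ancestor = paste(anc, collapse = ""),
       seq_a = paste(a$codons, collapse = ""),
       seq_b = paste(b$codons, collapse = ""),
       true_syn = unname(a$applied["syn"] + b$applied["syn"]),
       true_nonsyn = unname(a$applied["nonsyn"] + b$applied["nonsyn"]),
       syn_sites_anc = S_anc)
}

#' Simulate read pileups from planted genotypes
#'
#' Per site, the realised read count is Poisson with mean `coverage`; each
#' read is drawn from one chromosome copy uniformly (expected proportion
#' 1/ploidy per copy), and sequencing errors replace the read base with a
#' uniformly chosen other base at rate `error_rate`.
#'
#' @param genotypes data frame with columns `transcript`, `pos` (0-based) and
#'   `alleles`, the planted allele multiset as a string of bases whose length
#'   equals the ploidy (e.g. `"AAG"` for an AAB-type triploid site).
#' @param coverage mean reads per site.
#' @param error_rate per-base error fraction in [0, 0.25).
#' @param seed integer seed.
#' @param individual individual label used in the pileup.
#' @return a list with `pileup` (class `pileup`, as [read_pileup()] returns)
#'   and `truth` (planted allele count and realised coverage per site).
#' @export
simulate_pileup <- function(genotypes, coverage, error_rate = 0, seed = 1L,
                            individual = "ind1") {
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 0.25)
  set.seed(seed)
  n <- nrow(genotypes)
  allele_list <- strsplit(genotypes$alleles, "")
  ploidy <- lengths(allele_list)
  stopifnot(all(unlist(allele_list) %in% DNA_BASES))
  depth <- stats::rpois(n, coverage)
  counts <- matrix(0L, nrow = n, ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  for (i in seq_len(n)) {
    if (depth[i] == 0L) next
    per_copy <- stats::rmultinom(1L, depth[i],
                                 rep(1 / ploidy[i], ploidy[i]))[, 1]
    base_counts <- tapply(per_copy, factor(allele_list[[i]],
                                           levels = DNA_BASES), sum)
    base_counts[is.na(base_counts)] <- 0L
    if (error_rate > 0) {
      for (b in which(base_counts > 0)) {
        err <- stats::rbinom(1L, base_counts[b], error_rate)
        if (err > 0L) {
          base_counts[b] <- base_counts[b] - err
          dest <- stats::rmultinom(1L, err, rep(1 / 3, 3L))[, 1]
          base_counts[-b] <- base_counts[-b] + dest
        }
      }
    }
    counts[i, ] <- base_counts
  }
  per_ind <- data.frame(transcript = genotypes$transcript,
                        pos = genotypes$pos,
                        individual = individual,
                        counts, stringsAsFactors = FALSE)
  per_ind <- per_ind[order(per_ind$transcript, per_ind$pos), , drop = FALSE]
  rownames(per_ind) <- NULL
  pooled <- per_ind[, c("transcript", "pos", "A", "C", "G", "T")]
  pooled$coverage <- rowSums(pooled[, DNA_BASES])
  truth <- data.frame(transcript = genotypes$transcript,
                      pos = genotypes$pos,
                      alleles = vapply(allele_list, function(a)
                        paste(sort(unique(a)), collapse = ""), character(1)),
                      n_alleles = vapply(allele_list, function(a)
                        length(unique(a)), integer(1)),
                      ploidy = ploidy,
                      coverage = depth,
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$transcript, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(pileup = structure(list(per_individual = per_ind, pooled = pooled),
                          class = "pileup"),
       truth = truth)
}

#' Plant perfect microsatellites in random transcripts
#'
#' Each specification entry becomes one transcript containing a single exact
#' tandem array embedded in random flanks; remaining transcripts (if
#' `n_transcripts` exceeds the number of entries) are repeat-free background.
#' Flank bases adjacent to the array are constrained so the planted array is
#' maximal, and flanks are regenerated if they accidentally contain an array
#' passing the detection thresholds.
#'
#' @param n_transcripts number of transcripts to emit.
#' @param spec list of entries `list(motif=, repeats=, flank_left=,
#'   flank_right=)`.
#' @param seed integer seed.
#' @param thresholds,min_flank detection thresholds used to annotate the truth
#'   table (defaults from [pipeline_config()]).
#' @return list with `transcripts` (named character vector) and `truth`
#'   (planted coordinates, 0-based half-open, and detectability flags).
#' @export
plant_microsatellites <- function(n_transcripts, spec, seed = 1L,
                                  thresholds = pipeline_config()$ssr_thresholds,
                                  min_flank = pipeline_config()$ssr_min_flank) {
  stopifnot(n_transcripts >= length(spec))
  set.seed(seed)
  rand_seq <- function(len) {
    if (len <= 0L) return("")
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }
  clean_flank <- function(len) {
    repeat {
      fl <- rand_seq(len)
      if (len < 2L * min(thresholds)) return(fl)
      hits <- find_microsatellites(c(x = fl), thresholds = thresholds,
                                   min_flank = 0L)
      if (nrow(hits) == 0L) return(fl)
    }
  }
  seqs <- character(n_transcripts)
  truth <- vector("list", length(spec))
  for (i in seq_len(n_transcripts)) {
    id <- sprintf("msat_tx%03d", i)
    if (i <= length(spec)) {
      e <- spec[[i]]
      motif <- toupper(e$motif)
      u <- nchar(motif)
      stopifnot(u >= 2L, u <= 6L, e$repeats >= 1L,
                e$flank_left >= 0L, e$flank_right >= 0L)
      array <- strrep(motif, e$repeats)
      left <- clean_flank(e$flank_left)
      right <- clean_flank(e$flank_right)
      # keep the array maximal: flank bases must not extend the period
      last <- substr(motif, u, u); first <- substr(motif, 1L, 1L)
      if (nzchar(left) && substr(left, nchar(left), nchar(left)) == last) {
        substr(left, nchar(left), nchar(left)) <-
          sample(setdiff(DNA_BASES, last), 1L)
      }
      if (nzchar(right) && substr(right, 1L, 1L) == first) {
        substr(right, 1L, 1L) <- sample(setdiff(DNA_BASES, first), 1L)
      }
      seqs[i] <- paste0(left, array, right)
      primitive <- .primitive_motif(motif)
      truth[[i]] <- data.frame(
        transcript = id, motif = motif, unit = u, repeats = e$repeats,
        start = nchar(left), end = nchar(left) + u * e$repeats,
        flank_left = e$flank_left, flank_right = e$flank_right,
        detectable = primitive && e$repeats >= thresholds[[as.character(u)]],
        passes_flank = e$flank_left > min_flank && e$flank_right > min_flank,
        stringsAsFactors = FALSE)
    } else {
      seqs[i] <- clean_flank(200L)
    }
    names(seqs)[i] <- id
  }
  list(transcripts = seqs, truth = do.call(rbind, truth))
}

#' Simulate a two-condition count table with planted fold changes
#'
#' Counts follow a negative-binomial law with variance
#' `mu * (1 + dispersion * mu)`; `dispersion = 0` gives Poisson counts.
#' Condition-B means are condition-A means times the planted fold change
#' times the library-size ratio.
#'
#' @param n_genes number of genes.
#' @param lib_sizes length-2 numeric vector of library sizes.
#' @param planted data frame with columns `gene` (index or "g<i>" name) and
#'   `fold`; genes not listed have fold 1.
#' @param dispersion negative-binomial overdispersion (>= 0).
#' @param seed integer seed.
#' @param base_means per-gene condition-A means; a scalar is recycled, `NULL`
#'   draws log-normal means (median 100).
#' @return list with `counts` (gene, count_a, count_b) and `truth` (planted
#'   fold and base mean per gene).
#' @export
simulate_counts <- function(n_genes, lib_sizes, planted = NULL,
                            dispersion = 0, seed = 1L, base_means = NULL) {
  stopifnot(length(lib_sizes) == 2L, all(lib_sizes > 0), dispersion >= 0)
  set.seed(seed)
  genes <- sprintf("g%d", seq_len(n_genes))
  if (is.null(base_means)) {
    base_means <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1)
  } else {
    base_means <- rep_len(base_means, n_genes)
  }
  fold <- rep(1, n_genes)
  if (!is.null(planted) && nrow(planted)) {
    idx <- if (is.numeric(planted$gene)) planted$gene
           else match(planted$gene, genes)
    stopifnot(!anyNA(idx), all(planted$fold > 0))
    fold[idx] <- planted$fold
  }
  mu_a <- base_means
  mu_b <- base_means * fold * (lib_sizes[2] / lib_sizes[1])
  draw <- function(mu) {
    if (dispersion == 0) stats::rpois(n_genes, mu)
    else stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  counts <- data.frame(gene = genes, count_a = draw(mu_a),
                       count_b = draw(mu_b), stringsAsFactors = FALSE)
  truth <- data.frame(gene = genes, base_mean = base_means, fold = fold,
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

#' Write a truth table as TSV
#'
#' Truth tables open with a `# truth` line so they cannot be mistaken for
#' pipeline output.
#'
#' @param truth data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# truth", con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
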