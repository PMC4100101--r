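# Polymorphic-site calling and allele-multiplicity classification from pooled
# pileups, plus per-transcript diversity summaries and microsatellite
# genotyping.

#' Classify allele multiplicity at pileup sites
#'
#' Sites with pooled coverage below `min_coverage` are excluded. A base
#' counts as an allele when its pooled read count is at least
#' `allele_min_reads` and at least `allele_min_fraction` of the coverage (the
#' support filters suppress sequencing-error alleles, which would otherwise
#' dominate tri-allelic calls). The allele-set size gives the multiplicity
#' class: monomorphic, di-allelic, tri-allelic, or higher.
#'
#' @param pileup a `pileup` object from [read_pileup()] or
#'   [simulate_pileup()], or its pooled data frame.
#' @param min_coverage minimum pooled coverage.
#' @param allele_min_reads minimum reads supporting an allele.
#' @param allele_min_fraction minimum fraction of coverage supporting an
#'   allele.
#' @return data frame of retained sites with `alleles` (supported bases,
#'   alphabetical), `n_alleles` and `class`.
#' @export
call_sites <- function(pileup, min_coverage = 5L, allele_min_reads = 2L,
                       allele_min_fraction = 0.1) {
  stopifnot(min_coverage > 0, allele_min_reads > 0, allele_min_fraction > 0)
  pooled <- if (inherits(pileup, "pileup")) pileup$pooled else pileup
  keep <- pooled$coverage >= min_coverage
  sites <- pooled[keep, , drop = FALSE]
  if (!nrow(sites)) {
    sites$alleles <- character(0)
    sites$n_alleles <- integer(0)
    sites$class <- character(0)
    return(sites)
  }
  cnt <- as.matrix(sites[, DNA_BASES])
  support <- cnt >= allele_min_reads &
    cnt >= allele_min_fraction * sites$coverage
  sites$alleles <- apply(support, 1L, function(ok)
    paste(DNA_BASES[ok], collapse = ""))
  sites$n_alleles <- rowSums(support)
  sites$class <- cut(sites$n_alleles, breaks = c(-Inf, 0, 1, 2, 3, Inf),
                     labels = c(NA, "monomorphic", "di-allelic", "tri-allelic",
                                "higher"))
  sites$class <- as.character(sites$class)
  rownames(sites) <- NULL
  sites
}

#' Per-transcript and global polymorphism summary
#'
#' A polymorphic site carries at least two supported alleles. The global
#' average is total polymorphic sites divided by the number of transcripts
#' containing at least one polymorphic site, reported to one decimal (see
#' [diversity_average()]).
#'
#' @param sites classified sites from [call_sites()].
#' @return list with `per_transcript` (data frame transcript/n_polymorphic),
#'   `n_polymorphic`, `n_transcripts`, `average`, and `no_polymorphism` flag.
#' @export
diversity_summary <- function(sites) {
  poly <- sites[!is.na(sites$n_alleles) & sites$n_alleles >= 2L, ,
                drop = FALSE]
  if (!nrow(poly)) {
    return(list(per_transcript = data.frame(transcript = character(0),
                                            n_polymorphic = integer(0)),
                n_polymorphic = 0L, n_transcripts = 0L, average = 0,
                no_polymorphism = TRUE))
  }
  per_tx <- stats::aggregate(list(n_polymorphic = poly$pos),
                             by = list(transcript = poly$transcript),
                             FUN = length)
  list(per_transcript = per_tx,
       n_polymorphic = nrow(poly),
       n_transcripts = nrow(per_tx),
       average = diversity_average(nrow(poly), nrow(per_tx)),
       no_polymorphism = FALSE)
}

#' Average polymorphic sites per transcript
#'
#' @param n_sites total polymorphic sites.
#' @param n_transcripts transcripts containing at least one polymorphic site.
#' @return the average, rounded to one decimal.
#' @export
#' @examples
#' diversity_average(509699, 22463)  # 22.7
#' diversity_average(628711, 21615)  # 29.1
diversity_average <- function(n_sites, n_transcripts) {
  stopifnot(n_transcripts > 0)
  round(n_sites / n_transcripts, 1)
}

#' Genotype a microsatellite locus from allele-length observations
#'
#' Per individual, the number of distinct observed allele lengths gives the
#' genotype class: homozygous (1), di-allelic heterozygous (2, e.g. AAB in a
#' triploid) or tri-allelic heterozygous (3, ABC). The locus is tri-allelic
#' when any individual shows three alleles; otherwise di-allelic when any
#' individual is heterozygous; otherwise homozygous.
#'
#' @param observations data frame with columns `individual` and `length`
#'   (observed allele lengths, replicate observations allowed).
#' @param ploidy 2 or 3.
#' @param locus locus label.
#' @return list with `locus`, `calls` (per-individual data frame) and
#'   `locus_class`.
#' @export
genotype_msat <- function(observations, ploidy, locus = "locus") {
  stopifnot(nrow(observations) > 0, ploidy %in% c(2L, 3L))
  by_ind <- split(observations$length, observations$individual)
  classes <- c("homozygous", "di-allelic heterozygous",
               "tri-allelic heterozygous")
  calls <- lapply(names(by_ind), function(ind) {
    k <- length(unique(by_ind[[ind]]))
    if (k > ploidy) {
      stop("individual ", ind, " at ", locus, " shows ", k,
           " distinct alleles, exceeding ploidy ", ploidy,
           ": probable genotyping artifact")
    }
    data.frame(individual = ind, n_alleles = k, class = classes[k],
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  locus_class <- classes[max(calls$n_alleles)]
  list(locus = locus, calls = calls, locus_class = locus_class)
}

#' Population summary over genotyped microsatellite loci
#'
#' @param genotyped list of results from [genotype_msat()].
#' @return data frame with one row per class: number and fraction of loci.
#' @export
msat_population_summary <- function(genotyped) {
  classes <- c("homozygous", "di-allelic heterozygous",
               "tri-allelic heterozygous")
  lc <- factor(vapply(genotyped, `[[`, character(1), "locus_class"),
               levels = classes)
  tab <- table(lc)
  data.frame(class = classes, n_loci = as.integer(tab),
             fraction = as.numeric(tab) / length(lc),
             stringsAsFactors = FALSE)
}
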