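#' Pipeline configuration
#'
#' Builds the flat configuration object holding every tunable constant of the
#' pipeline. Defaults are the analysis constants of the study this package
#' operationalises: a 50-amino-acid minimum for an intact ORF, splice-variant
#' collapse at 100% identity over 100 bp, reciprocal-best-hit orthologs
#' aligned over 300 bp, a 0.002-wide Ks histogram bin, a molecular clock of
#' 3.51e-9 substitutions per synonymous site per year, a minimum read
#' coverage of 5 for polymorphic-site calling, microsatellite repeat-count
#' thresholds of 8/5/5/5/5 for unit lengths 2-6 with >50 bp flanks, and DEG
#' cutoffs of FDR 0.001 with a minimum fold change of 4.
#'
#' @param min_orf_aa minimum ORF length in amino acids (initiator Met
#'   excluded) for a transcript to be called protein-coding.
#' @param dedup_identity required identity fraction for splice-variant
#'   collapse (only 1, exact identity, is supported).
#' @param dedup_min_overlap minimum length (bp) of the shared identical block.
#' @param rbh_min_aln minimum alignment length (bp) for an ortholog pair.
#' @param aln_match,aln_mismatch,aln_gap_open,aln_gap_extend BLASTN-like local
#'   alignment scores used for best-hit searches. Gap penalties are positive
#'   costs; a gap of length L costs `aln_gap_open + L * aln_gap_extend`.
#' @param ks_bin_width Ks histogram bin width.
#' @param clock_rate substitutions per synonymous site per year.
#' @param min_coverage minimum pooled read coverage for site classification.
#' @param allele_min_reads minimum pooled reads supporting an allele.
#' @param allele_min_fraction minimum fraction of coverage supporting an
#'   allele.
#' @param ssr_thresholds named integer vector, minimum repeat counts for motif
#'   unit lengths "2".."6".
#' @param ssr_min_flank both flanks must be strictly longer than this (bp).
#' @param deg_fdr Benjamini-Hochberg adjusted p-value cutoff for DEGs.
#' @param deg_min_fold minimum fold change for DEGs (fold units, >= 1).
#' @param deg_high_cpm counts-per-million threshold above which a gene counts
#'   as highly expressed when assigning expression groups.
#' @param rng_seed integer seed used by stochastic stages started from the
#'   command line.
#' @return an object of class `gibeltx_config` (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$clock_rate
pipeline_config <- function(min_orf_aa = 50L,
                            dedup_identity = 1,
                            dedup_min_overlap = 100L,
                            rbh_min_aln = 300L,
                            aln_match = 1,
                            aln_mismatch = -2,
                            aln_gap_open = 5,
                            aln_gap_extend = 2,
                            ks_bin_width = 0.002,
                            clock_rate = 3.51e-9,
                            min_coverage = 5L,
                            allele_min_reads = 2L,
                            allele_min_fraction = 0.1,
                            ssr_thresholds = c(`2` = 8L, `3` = 5L, `4` = 5L,
                                               `5` = 5L, `6` = 5L),
                            ssr_min_flank = 50L,
                            deg_fdr = 0.001,
                            deg_min_fold = 4,
                            deg_high_cpm = 100,
                            rng_seed = 1L) {
  cfg <- list(min_orf_aa = as.integer(min_orf_aa),
              dedup_identity = dedup_identity,
              dedup_min_overlap = as.integer(dedup_min_overlap),
              rbh_min_aln = as.integer(rbh_min_aln),
              aln_match = aln_match, aln_mismatch = aln_mismatch,
              aln_gap_open = aln_gap_open, aln_gap_extend = aln_gap_extend,
              ks_bin_width = ks_bin_width, clock_rate = clock_rate,
              min_coverage = as.integer(min_coverage),
              allele_min_reads = as.integer(allele_min_reads),
              allele_min_fraction = allele_min_fraction,
              ssr_thresholds = ssr_thresholds,
              ssr_min_flank = as.integer(ssr_min_flank),
              deg_fdr = deg_fdr, deg_min_fold = deg_min_fold,
              deg_high_cpm = deg_high_cpm,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "gibeltx_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a `gibeltx_config` object.
#' @return `cfg`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "gibeltx_config"))
  pos_fields <- c("min_orf_aa", "dedup_identity", "dedup_min_overlap",
                  "rbh_min_aln", "aln_match", "ks_bin_width", "clock_rate",
                  "min_coverage", "allele_min_reads", "allele_min_fraction",
                  "ssr_min_flank", "deg_fdr", "deg_min_fold", "deg_high_cpm")
  for (f in pos_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a single strictly positive number")
    }
  }
  if (!identical(sort(names(cfg$ssr_thresholds)), c("2", "3", "4", "5", "6"))) {
    stop("ssr_thresholds must have exactly the unit lengths 2,3,4,5,6")
  }
  if (any(cfg$ssr_thresholds <= 0)) {
    stop("ssr_thresholds must be strictly positive")
  }
  if (cfg$deg_min_fold < 1) stop("deg_min_fold must be >= 1")
  invisible(cfg)
}

#' Read a flat key-value configuration file
#'
#' The file is TSV-style: one `key<TAB>value` pair per line, `#` comments and
#' blank lines ignored. The five `ssr_thresholds` entries are given as
#' `ssr_threshold_2` .. `ssr_threshold_6`. Values present in the file override
#' the package defaults; anything not mentioned keeps its default.
#'
#' @param path file path.
#' @return a `gibeltx_config` object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\t|=", perl = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "")),
                 character(1))
  args <- list()
  thresholds <- pipeline_config()$ssr_thresholds
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (grepl("^ssr_threshold_[2-6]$", k)) {
      thresholds[sub("ssr_threshold_", "", k)] <- as.integer(vals[i])
    } else {
      args[[k]] <- as.numeric(vals[i])
    }
  }
  args$ssr_thresholds <- thresholds
  do.call(pipeline_config, args)
}

#' @export
print.gibeltx_config <- function(x, ...) {
  cat("gibeltx pipeline configuration\n")
  for (f in setdiff(names(x), "ssr_thresholds")) {
    cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  }
  cat(sprintf("  %-20s %s\n", "ssr_thresholds",
              paste(names(x$ssr_thresholds), x$ssr_thresholds,
                    sep = ":", collapse = " ")))
  invisible(x)
}
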