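# Reciprocal-best-hit orthology, codon alignment via protein back-threading,
# NG86 Ks/Ka estimation, Ks histogram binning and molecular-clock dating.

.local_score_matrix <- function(set_a, set_b, cfg) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = cfg$aln_match,
                                                  mismatch = cfg$aln_mismatch,
                                                  baseOnly = TRUE)
  a_ids <- names(set_a); b_ids <- names(set_b)
  bset <- Biostrings::DNAStringSet(unname(set_b))
  scores <- matrix(NA_real_, length(set_a), length(set_b),
                   dimnames = list(a_ids, b_ids))
  lens <- scores
  for (i in seq_along(set_a)) {
    aln <- Biostrings::pairwiseAlignment(bset,
                                         Biostrings::DNAString(set_a[[i]]),
                                         type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = cfg$aln_gap_open,
                                         gapExtension = cfg$aln_gap_extend)
    scores[i, ] <- Biostrings::score(aln)
    # alignment length including gap columns
    lens[i, ] <- nchar(as.character(Biostrings::pattern(aln)))
  }
  list(scores = scores, lengths = lens)
}

.best_of <- function(scores, lengths) {
  # highest score; ties -> longer alignment, then lexicographic target id
  targets <- colnames(scores)
  out <- lapply(rownames(scores), function(q) {
    sc <- scores[q, ]; ln <- lengths[q, ]
    ord <- order(-sc, -ln, targets)[1]
    data.frame(query = q, target = targets[ord], score = sc[ord],
               aln_len = ln[ord], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Best local-alignment hits in both directions
#'
#' Scores every pair with a BLASTN-like local alignment (match +1, mismatch
#' -2, gap open 5 and extension 2 as positive costs) and records, for each
#' query in either set, the best-scoring target in the other set. Ties are
#' broken by longer alignment, then lexicographically smaller target id.
#'
#' @param set_a,set_b named character vectors of transcript sequences.
#' @param cfg a [pipeline_config()] object supplying the scoring constants.
#' @return list with data frames `ab` (queries from `set_a`) and `ba`, each
#'   with columns `query`, `target`, `score`, `aln_len`.
#' @export
all_pairs_best_hits <- function(set_a, set_b, cfg = pipeline_config()) {
  stopifnot(length(set_a) > 0, length(set_b) > 0)
  m <- .local_score_matrix(set_a, set_b, cfg)
  list(ab = .best_of(m$scores, m$lengths),
       ba = .best_of(t(m$scores), t(m$lengths)))
}

#' Reciprocal best hits
#'
#' A pair is an ortholog candidate when each sequence is the other's best hit
#' and the alignment spans at least `min_aln` bp.
#'
#' @param hits_ab,hits_ba best-hit data frames from [all_pairs_best_hits()].
#' @param min_aln minimum alignment length (bp).
#' @return data frame with columns `id_a`, `id_b`, `aln_len`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, min_aln = 300L) {
  back <- stats::setNames(hits_ba$target, hits_ba$query)
  keep <- !is.na(back[hits_ab$target]) &
    back[hits_ab$target] == hits_ab$query &
    hits_ab$aln_len >= min_aln
  out <- data.frame(id_a = hits_ab$query[keep],
                    id_b = hits_ab$target[keep],
                    aln_len = hits_ab$aln_len[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.translate_checked <- function(cds, id) {
  if (nchar(cds) %% 3L != 0L) {
    stop("coding sequence length of ", id, " is not a multiple of 3")
  }
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- .codontab$aa[codons]
  if (length(codons) && aa[length(codons)] %in% "*") {  # trim terminal stop
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  if (any(is.na(aa))) stop("ambiguous codon in ", id)
  if (any(aa == "*")) stop("internal stop codon in ", id)
  list(codons = codons, protein = paste(aa, collapse = ""))
}

#' Build a codon alignment by protein-alignment back-threading
#'
#' The two coding sequences are translated, the proteins aligned globally
#' (BLOSUM62, affine gap costs: open 10, extension 1), and the protein
#' alignment threaded back onto codons: every aligned residue becomes its
#' source codon and every gap a `---` column.
#'
#' @param cds_a,cds_b in-frame coding sequences (terminal stop codons are
#'   trimmed; internal stops are an error).
#' @param id_a,id_b sequence labels used in messages and output.
#' @return object of class `codon_alignment`: list with `id_a`, `id_b` and
#'   `codons`, a 2-row character matrix of codon columns.
#' @export
build_codon_alignment <- function(cds_a, cds_b, id_a = "a", id_b = "b") {
  ta <- .translate_checked(toupper(cds_a), id_a)
  tb <- .translate_checked(toupper(cds_b), id_b)
  B62 <- get_blosum62()
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(ta$protein),
                                       Biostrings::AAString(tb$protein),
                                       type = "global",
                                       substitutionMatrix = B62,
                                       gapOpening = 10, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  thread <- function(chars, codons, id) {
    out <- character(length(chars))
    j <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") {
        out[i] <- "---"
      } else {
        j <- j + 1L
        out[i] <- codons[j]
      }
    }
    if (j != length(codons)) {
      stop("back-threading length mismatch for ", id)
    }
    out
  }
  codmat <- rbind(thread(pa, ta$codons, id_a), thread(pb, tb$codons, id_b))
  rownames(codmat) <- c(id_a, id_b)
  structure(list(id_a = id_a, id_b = id_b, codons = codmat),
            class = "codon_alignment")
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' NG86 synonymous/nonsynonymous statistics for a codon alignment
#'
#' Counting estimator of Nei and Gojobori (1986). Per codon, the synonymous
#' site fraction at each position is the synonymous share of its non-stop
#' single-base neighbours; site counts are averaged over the two sequences.
#' Codons differing at several positions contribute differences averaged over
#' all orderings of single-base pathways, excluding pathways through stop
#' codons. Proportions are corrected with the Jukes-Cantor formula
#' `K = -3/4 log(1 - 4/3 p)`; `Ks` is flagged undefined when `pS >= 3/4`.
#' Columns containing gaps or `N` are excluded from all counts.
#'
#' @param x a `codon_alignment`, a 2-row codon character matrix, or an
#'   in-frame nucleotide sequence (then `y` must be its equal-length partner
#'   and columns pair positionally).
#' @param y optional second in-frame sequence.
#' @return object of class `ng86`: list with `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `Ks`, `Ka`, `ks_defined`, `ka_defined`, `n_codons` (ungapped
#'   columns counted).
#' @export
ng86_stats <- function(x, y = NULL) {
  if (!is.null(y)) {
    split3 <- function(s) {
      s <- toupper(s)
      stopifnot(nchar(s) %% 3L == 0L)
      substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    }
    c1 <- split3(x); c2 <- split3(y)
    if (length(c1) != length(c2)) stop("sequences differ in codon length")
  } else if (inherits(x, "codon_alignment")) {
    c1 <- x$codons[1, ]; c2 <- x$codons[2, ]
  } else if (is.matrix(x) && nrow(x) == 2L) {
    c1 <- x[1, ]; c2 <- x[2, ]
  } else {
    stop("unsupported alignment representation")
  }
  usable <- !grepl("[-N]", c1) & !grepl("[-N]", c2)
  c1 <- c1[usable]; c2 <- c2[usable]
  if (!length(c1)) stop("alignment has no ungapped codon columns")
  aa <- .codontab$aa
  if (any(is.na(aa[c1])) || any(aa[c1] == "*")) {
    stop("internal stop or invalid codon in first sequence")
  }
  if (any(is.na(aa[c2])) || any(aa[c2] == "*")) {
    stop("internal stop or invalid codon in second sequence")
  }
  syn_sites <- .codontab$syn_sites
  S <- (sum(syn_sites[c1]) + sum(syn_sites[c2])) / 2
  N <- 3 * length(c1) - S
  Sd <- 0; Nd <- 0
  for (i in which(c1 != c2)) {
    d <- codon_pair_diffs(c1[i], c2[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p <= 0) 0 else -3 / 4 * log(1 - 4 / 3 * p)
  ks_defined <- pS < 3 / 4
  ka_defined <- pN < 3 / 4
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = if (ks_defined) jc(pS) else NA_real_,
                 Ka = if (ka_defined) jc(pN) else NA_real_,
                 ks_defined = ks_defined, ka_defined = ka_defined,
                 n_codons = length(c1)),
            class = "ng86")
}

#' @export
print.ng86 <- function(x, ...) {
  cat(sprintf(
    "NG86: S=%.2f N=%.2f Sd=%.2f Nd=%.2f pS=%.5f pN=%.5f Ks=%s Ka=%s (%d codons)\n",
    x$S, x$N, x$Sd, x$Nd, x$pS, x$pN,
    if (x$ks_defined) sprintf("%.5f", x$Ks) else "undefined",
    if (x$ka_defined) sprintf("%.5f", x$Ka) else "undefined",
    x$n_codons))
  invisible(x)
}

#' Bin Ks values into a histogram
#'
#' Half-open bins `[k*w, (k+1)*w)` labelled by their left edge. Undefined
#' (`NA`) values are excluded from the bins and reported in `n_undefined`.
#' The peak is the left edge of the modal bin, ties resolved toward the lower
#' edge.
#'
#' @param ks_values numeric vector of Ks estimates (`NA` = undefined).
#' @param bin_width bin width in Ks units.
#' @return object of class `ks_distribution`: list with `bin_width`, `counts`
#'   (named by left edge, contiguous from 0), `peak_ks`, `n_pairs`,
#'   `n_undefined`.
#' @export
ks_histogram <- function(ks_values, bin_width = 0.002) {
  stopifnot(bin_width > 0)
  n_pairs <- length(ks_values)
  ok <- ks_values[!is.na(ks_values)]
  n_undefined <- n_pairs - length(ok)
  if (!length(ok)) {
    out <- list(bin_width = bin_width, counts = stats::setNames(integer(0),
                                                                character(0)),
                peak_ks = NA_real_, n_pairs = n_pairs,
                n_undefined = n_undefined)
    class(out) <- "ks_distribution"
    return(out)
  }
  if (any(ok < 0)) stop("negative Ks value")
  idx <- floor(ok / bin_width + 1e-9)
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  edges <- (seq_along(counts) - 1L) * bin_width
  names(counts) <- format(edges, trim = TRUE, scientific = FALSE)
  peak <- edges[which.max(counts)]   # which.max takes the first (lower) edge
  out <- list(bin_width = bin_width, counts = counts, peak_ks = peak,
              n_pairs = n_pairs, n_undefined = n_undefined)
  class(out) <- "ks_distribution"
  out
}

#' @export
print.ks_distribution <- function(x, ...) {
  cat(sprintf("Ks distribution: %d pairs (%d undefined), bin width %g\n",
              x$n_pairs, x$n_undefined, x$bin_width))
  if (!is.na(x$peak_ks)) {
    cat(sprintf("  modal bin left edge: %g (count %d)\n", x$peak_ks,
                max(x$counts)))
  }
  invisible(x)
}

#' @export
plot.ks_distribution <- function(x, ...) {
  edges <- as.numeric(names(x$counts))
  graphics::barplot(x$counts, names.arg = format(edges, digits = 3),
                    xlab = "Ks (bin left edge)", ylab = "ortholog pairs",
                    border = NA, space = 0, las = 2, ...)
  invisible(x)
}

#' Convert a Ks peak into a divergence time under a molecular clock
#'
#' `T = peak_ks / rate` years. Times are additionally reported in millions of
#' years truncated (not rounded) to one decimal, the convention that
#' reproduces the printed 2.2 (range 1.7-2.8) My from peaks 0.008 (0.006,
#' 0.01) at 3.51e-9 substitutions per synonymous site per year.
#'
#' @param peak_ks modal Ks (>= 0).
#' @param rate substitutions per synonymous site per year (> 0).
#' @param mode_interval optional length-2 Ks interval around the peak.
#' @return object of class `dating_result`: list with `peak_ks`, `rate`,
#'   `t_years`, `t_my`, and when an interval is given `t_low_years`,
#'   `t_high_years`, `t_low_my`, `t_high_my`.
#' @export
date_divergence <- function(peak_ks, rate, mode_interval = NULL) {
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  stopifnot(peak_ks >= 0)
  trunc_my <- function(t_years) floor(t_years / 1e5 + 1e-9) / 10
  t <- peak_ks / rate
  out <- list(peak_ks = peak_ks, rate = rate, t_years = t, t_my = trunc_my(t))
  if (!is.null(mode_interval)) {
    lo <- min(mode_interval) / rate
    hi <- max(mode_interval) / rate
    out$t_low_years <- lo; out$t_high_years <- hi
    out$t_low_my <- trunc_my(lo); out$t_high_my <- trunc_my(hi)
  }
  class(out) <- "dating_result"
  out
}

#' @export
print.dating_result <- function(x, ...) {
  cat(sprintf("divergence dating: peak Ks %g / rate %g per year\n",
              x$peak_ks, x$rate))
  cat(sprintf("  T = %.0f years (%.1f million years)\n", x$t_years, x$t_my))
  if (!is.null(x$t_low_years)) {
    cat(sprintf("  mode interval: %.1f - %.1f million years\n",
                x$t_low_my, x$t_high_my))
  }
  invisible(x)
}
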