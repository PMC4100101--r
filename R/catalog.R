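# Transcript catalog: longest-ORF protein-coding classification and collapse
# of putative splice variants sharing an exact block of >= 100 bp.

#' Find the best open reading frame in a transcript
#'
#' All six frames are scanned for intact ORFs (ATG through an in-frame stop
#' with no intervening stop and no ambiguous codon); the longest is returned,
#' with ties broken in favour of the forward strand and then the lowest start
#' coordinate. Coordinates are 0-based half-open on the reported strand and
#' span the initiator ATG through the last sense codon (the stop codon is
#' excluded), so `length_aa = (end - start)/3 - 1` counts amino acids without
#' the initiator Met. A transcript is protein-coding when `length_aa >=
#' min_aa` (default 50, the 150-nt rule). Codons containing `N` terminate any
#' open frame.
#'
#' @param seq nucleotide sequence (ACGTN alphabet, length >= 3).
#' @param min_aa coding cutoff in amino acids.
#' @return an object of class `orf_call`: list with `frame` (+1..+3, -1..-3),
#'   `start`, `end`, `length_aa`, `is_coding`. If no intact ORF exists,
#'   `length_aa` is 0 and `is_coding` is `FALSE`.
#' @export
find_best_orf <- function(seq, min_aa = 50L) {
  seq <- chartr("U", "T", toupper(seq))
  stopifnot(nchar(seq) >= 3L)
  if (grepl("[^ACGTN]", seq)) stop("sequence alphabet must be ACGTN")
  aa <- .codontab$aa
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  best <- NULL
  strands <- list(`+` = seq, `-` = revcomp(seq))
  for (sgn in c("+", "-")) {
    s <- strands[[sgn]]
    n <- nchar(s)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      if (ncod < 2L) next
      starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(s, starts, starts + 2L)
      kind <- ifelse(grepl("N", codons, fixed = TRUE), "bad",
                     ifelse(aa[codons] == "*", "stop",
                            ifelse(codons == "ATG", "atg", "sense")))
      open_from <- NA_integer_  # index of earliest ATG in the open stretch
      for (i in seq_len(ncod)) {
        k <- kind[i]
        if (k == "stop") {
          if (!is.na(open_from)) {
            len_aa <- i - open_from - 1L
            cand <- list(frame = as.integer(paste0(sgn, off + 1L)),
                         strand = sgn,
                         start = starts[open_from] - 1L,
                         end = starts[i] - 1L,
                         length_aa = len_aa)
            if (is.null(best) || len_aa > best$length_aa ||
                (len_aa == best$length_aa &&
                 (cand$strand < best$strand ||
                  (cand$strand == best$strand && cand$start < best$start)))) {
              best <- cand
            }
          }
          open_from <- NA_integer_
        } else if (k == "bad") {
          open_from <- NA_integer_
        } else if (k == "atg" && is.na(open_from)) {
          open_from <- i
        }
      }
    }
  }
  if (is.null(best)) {
    out <- list(frame = NA_integer_, start = NA_integer_, end = NA_integer_,
                length_aa = 0L, is_coding = FALSE)
  } else {
    out <- list(frame = best$frame, start = best$start, end = best$end,
                length_aa = best$length_aa,
                is_coding = best$length_aa >= min_aa)
  }
  class(out) <- "orf_call"
  out
}

#' @export
print.orf_call <- function(x, ...) {
  if (is.na(x$frame)) {
    cat("orf_call: no intact ORF\n")
  } else {
    cat(sprintf("orf_call: frame %+d, [%d,%d) on reported strand, %d aa, %s\n",
                x$frame, x$start, x$end, x$length_aa,
                if (x$is_coding) "coding" else "non-coding"))
  }
  invisible(x)
}

#' ORF table for a transcript collection
#'
#' @param transcripts named character vector of sequences.
#' @param min_aa coding cutoff in amino acids.
#' @return data frame with one row per transcript.
#' @export
orf_table <- function(transcripts, min_aa = 50L) {
  rows <- lapply(names(transcripts), function(id) {
    o <- find_best_orf(transcripts[[id]], min_aa = min_aa)
    data.frame(transcript = id, frame = o$frame, start = o$start,
               end = o$end, length_aa = o$length_aa, is_coding = o$is_coding,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Collapse putative splice variants
#'
#' Two transcripts sharing an exact common substring of at least
#' `min_overlap` bp (the operational reading of "100% identity over 100 bp")
#' are considered splice variants of one gene. Sharing is transitive:
#' connected components of the sharing graph collapse to their longest member
#' (ties broken by lexicographically smallest id). Blocks containing `N` never
#' match.
#'
#' @param transcripts named character vector of sequences.
#' @param min_overlap minimum shared identical block (bp).
#' @return list with `representatives` (named character vector, a subset of
#'   the input) and `cluster_map` (data frame member -> representative).
#' @export
dedup_splice_variants <- function(transcripts, min_overlap = 100L) {
  stopifnot(length(transcripts) > 0, !is.null(names(transcripts)))
  ids <- names(transcripts)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  # a shared substring >= k bp implies a shared k-mer and vice versa
  k <- as.integer(min_overlap)
  kmer_owner <- new.env(parent = emptyenv(), size = 4096L)
  for (i in seq_len(n)) {
    s <- toupper(transcripts[[i]])
    L <- nchar(s)
    if (L < k) next
    km <- unique(substring(s, 1:(L - k + 1L), k:L))
    km <- km[!grepl("N", km, fixed = TRUE)]
    for (m in km) {
      o <- kmer_owner[[m]]
      if (is.null(o)) kmer_owner[[m]] <- i else if (o != i) unite(o, i)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  rep_of <- integer(n)
  for (g in unique(comp)) {
    members <- which(comp == g)
    lens <- nchar(transcripts[members])
    cand <- members[lens == max(lens)]
    rep_of[members] <- cand[order(ids[cand])][1]
  }
  reps <- sort(unique(rep_of))
  list(representatives = transcripts[reps],
       cluster_map = data.frame(member = ids,
                                representative = ids[rep_of],
                                stringsAsFactors = FALSE))
}
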