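# Readers and writers for the on-disk formats used by the pipeline. FASTA goes
# through Biostrings; tabular formats are plain TSV. All coordinates are
# 0-based half-open internally and 1-based closed in written reports.

#' Read transcripts from a FASTA file
#'
#' Sequences are uppercased and RNA `U` is normalised to `T`. Record order is
#' preserved. Duplicate identifiers and empty sequences are hard errors.
#'
#' @param path FASTA file path.
#' @return a named character vector of sequences (names are transcript ids).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[1])
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id ", ids[which(!nzchar(seqs))[1]])
  }
  seqs
}

#' Write transcripts to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a pileup table
#'
#' Expects tab-separated columns `transcript, position, individual, countA,
#' countC, countG, countT` with 1-based positions; lines starting with `#` are
#' ignored, as is an optional header line. Positions are converted to 0-based
#' internally and counts are aggregated per individual and pooled across
#' individuals.
#'
#' @param path TSV file path.
#' @param transcript_lengths optional named vector of transcript lengths used
#'   to validate positions.
#' @return an object of class `pileup`: a list with `per_individual` and
#'   `pooled` data frames (`pos` is 0-based; pooled rows carry `coverage`).
#' @export
read_pileup <- function(path, transcript_lengths = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) != 7L) stop("pileup must have 7 tab-separated columns")
  if (!is.numeric(raw[[2]])) {  # header line present
    raw <- raw[-1, , drop = FALSE]
    for (j in c(2, 4:7)) raw[[j]] <- as.numeric(raw[[j]])
  }
  names(raw) <- c("transcript", "position", "individual", "A", "C", "G", "T")
  counts <- as.matrix(raw[, c("A", "C", "G", "T")])
  if (any(counts < 0)) stop("negative base count in pileup")
  if (any(raw$position < 1)) stop("pileup positions must be 1-based (>= 1)")
  if (!is.null(transcript_lengths)) {
    len <- transcript_lengths[raw$transcript]
    bad <- which(!is.na(len) & raw$position > len)
    if (length(bad)) {
      stop("position ", raw$position[bad[1]], " exceeds length of transcript ",
           raw$transcript[bad[1]])
    }
  }
  per_ind <- data.frame(transcript = raw$transcript,
                        pos = raw$position - 1L,
                        individual = raw$individual,
                        raw[, c("A", "C", "G", "T")],
                        stringsAsFactors = FALSE)
  per_ind <- stats::aggregate(per_ind[, c("A", "C", "G", "T")],
                              by = per_ind[, c("transcript", "pos",
                                               "individual")],
                              FUN = sum)
  per_ind <- per_ind[order(per_ind$transcript, per_ind$pos,
                           per_ind$individual), , drop = FALSE]
  rownames(per_ind) <- NULL
  pooled <- stats::aggregate(per_ind[, c("A", "C", "G", "T")],
                             by = per_ind[, c("transcript", "pos")],
                             FUN = sum)
  pooled <- pooled[order(pooled$transcript, pooled$pos), , drop = FALSE]
  pooled$coverage <- rowSums(pooled[, c("A", "C", "G", "T")])
  rownames(pooled) <- NULL
  structure(list(per_individual = per_ind, pooled = pooled), class = "pileup")
}

#' Read a two-condition count table
#'
#' Tab-separated `gene<TAB>countA<TAB>countB`; `#` comments and an optional
#' header line are ignored.
#'
#' @param path TSV file path.
#' @return data frame with columns `gene`, `count_a`, `count_b`.
#' @export
read_counts <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) != 3L) stop("count table must have 3 tab-separated columns")
  if (!is.numeric(raw[[2]])) {
    raw <- raw[-1, , drop = FALSE]
    raw[[2]] <- as.numeric(raw[[2]]); raw[[3]] <- as.numeric(raw[[3]])
  }
  names(raw) <- c("gene", "count_a", "count_b")
  if (any(raw$count_a < 0 | raw$count_b < 0)) stop("negative count")
  rownames(raw) <- NULL
  raw
}

#' Read a gene-to-category map
#'
#' Tab-separated `gene<TAB>term`, one pair per line; genes may carry several
#' terms on separate lines.
#'
#' @param path TSV file path.
#' @return data frame with columns `gene`, `term`.
#' @export
read_category_map <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("gene", "term"))
  raw
}

#' Read a qPCR Cq table
#'
#' Tab-separated `gene<TAB>group<TAB>Cq_target<TAB>Cq_reference`; replicate
#' rows are allowed.
#'
#' @param path TSV file path.
#' @return data frame with columns `gene`, `group`, `cq_target`,
#'   `cq_reference`.
#' @export
read_cq_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) != 4L) stop("Cq table must have 4 tab-separated columns")
  if (!is.numeric(raw[[3]])) {
    raw <- raw[-1, , drop = FALSE]
    raw[[3]] <- as.numeric(raw[[3]]); raw[[4]] <- as.numeric(raw[[4]])
  }
  names(raw) <- c("gene", "group", "cq_target", "cq_reference")
  raw
}

#' Write a data frame as a TSV report
#'
#' Every report starts with commented header lines naming the tool version and
#' any parameter values passed in `params`.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param params named list of parameter values recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, params = list()) {
  ver <- as.character(utils::packageVersion("gibeltx"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# gibeltx ", ver), con)
  for (p in names(params)) {
    writeLines(paste0("# ", p, " = ", paste(format(params[[p]]),
                                            collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ploidy ratio from flow-cytometry DNA contents
#'
#' The ratio of mean DNA content of a putative polyploid to a diploid
#' reference; a triploid is expected at 1.5.
#'
#' @param content_poly mean DNA content of the test population.
#' @param content_ref mean DNA content of the diploid reference.
#' @return the ratio, rounded to one decimal.
#' @export
#' @examples
#' dna_content_ratio(480, 320)  # 1.5
dna_content_ratio <- function(content_poly, content_ref) {
  stopifnot(content_poly > 0, content_ref > 0)
  round(content_poly / content_ref, 1)
}
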