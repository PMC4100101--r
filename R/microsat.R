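# Perfect-microsatellite detection: maximal exact tandem arrays of unit
# length 2-6 on the forward strand, with unit-specific repeat-count
# thresholds and a both-sides flank rule.

.primitive_motif <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        strrep(substr(motif, 1L, d), u %/% d) == motif) return(FALSE)
  }
  TRUE
}

.canonical_motif <- function(motif) {
  u <- nchar(motif)
  rot <- vapply(seq_len(u), function(i)
    paste0(substr(motif, i, u), substr(motif, 1L, i - 1L)), character(1))
  min(rot)
}

#' Detect perfect microsatellites
#'
#' Finds maximal perfect tandem arrays with unit lengths 2-6 on the forward
#' strand (transcripts are oriented). Arrays whose motif is a power of a
#' shorter motif are reported once, at the shortest unit; homopolymers are
#' excluded. Only arrays reaching the unit-specific repeat-count threshold
#' are candidates; overlapping candidates are resolved leftmost-first, longer
#' array first at equal starts. Repeat counts cover complete units only.
#' `passes_flank` is true when both flanks are strictly longer than
#' `min_flank`.
#'
#' @param transcripts named character vector of sequences.
#' @param thresholds named vector of minimum repeat counts for unit lengths
#'   "2".."6".
#' @param min_flank flank rule (bp), strict on both sides.
#' @return data frame of loci: `transcript`, `motif` (as found), `canonical`
#'   (lexicographic minimum over rotations), `unit`, `repeats`, `start`,
#'   `end` (0-based half-open), `flank_left`, `flank_right`, `passes_flank`.
#' @export
find_microsatellites <- function(transcripts,
                                 thresholds = pipeline_config()$ssr_thresholds,
                                 min_flank = pipeline_config()$ssr_min_flank) {
  stopifnot(identical(sort(names(thresholds)), c("2", "3", "4", "5", "6")))
  empty <- data.frame(transcript = character(0), motif = character(0),
                      canonical = character(0), unit = integer(0),
                      repeats = integer(0), start = integer(0),
                      end = integer(0), flank_left = integer(0),
                      flank_right = integer(0), passes_flank = logical(0),
                      stringsAsFactors = FALSE)
  out <- list(empty)
  for (id in names(transcripts)) {
    s <- toupper(transcripts[[id]])
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    cand <- list()
    for (u in 2:6) {
      if (n < 2L * u) next
      eq <- chars[seq_len(n - u)] == chars[(u + 1L):n] &
        chars[seq_len(n - u)] %in% DNA_BASES &
        chars[(u + 1L):n] %in% DNA_BASES
      r <- rle(eq)
      ends_at <- cumsum(r$lengths)
      for (j in which(r$values & r$lengths >= u)) {
        start <- ends_at[j] - r$lengths[j] + 1L          # 1-based
        span <- r$lengths[j] + u                          # full periodic run
        repeats <- span %/% u
        if (repeats < thresholds[[as.character(u)]]) next
        motif <- substr(s, start, start + u - 1L)
        if (!.primitive_motif(motif)) next
        cand[[length(cand) + 1L]] <- list(start = start, unit = u,
                                          repeats = repeats, motif = motif)
      }
    }
    if (!length(cand)) next
    starts <- vapply(cand, `[[`, integer(1), "start")
    lens <- vapply(cand, function(x) x$unit * x$repeats, integer(1))
    cand <- cand[order(starts, -lens)]
    taken_end <- 0L
    for (cd in cand) {
      if (cd$start <= taken_end) next   # overlaps an accepted array
      len <- cd$unit * cd$repeats
      taken_end <- cd$start + len - 1L
      start0 <- cd$start - 1L
      end0 <- start0 + len
      out[[length(out) + 1L]] <- data.frame(
        transcript = id, motif = cd$motif,
        canonical = .canonical_motif(cd$motif), unit = cd$unit,
        repeats = cd$repeats, start = start0, end = end0,
        flank_left = start0, flank_right = n - end0,
        passes_flank = start0 > min_flank && (n - end0) > min_flank,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write microsatellite loci as BED
#'
#' 0-based half-open intervals; the name field is `canonical_motif.repeats`.
#'
#' @param loci data frame from [find_microsatellites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ssr_bed <- function(loci, path) {
  bed <- data.frame(chrom = loci$transcript, start = loci$start,
                    end = loci$end,
                    name = paste0(loci$canonical, ".", loci$repeats))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
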