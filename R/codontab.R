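# Genetic-code lookup tables shared by the codon evolver and the NG86
# estimator. Everything is derived once, at load time, from the standard code
# shipped with Biostrings.

DNA_BASES <- c("A", "C", "G", "T")

.codontab <- new.env(parent = emptyenv())

.init_codontab <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  names(aa) <- codons
  sense <- codons[aa != "*"]

  # syn_frac[codon, pos]: fraction of non-stop single-base neighbours at that
  # position that are synonymous (stop neighbours are dropped from the
  # denominator, so each position still contributes one full site).
  syn_frac <- matrix(0, nrow = length(sense), ncol = 3,
                     dimnames = list(sense, NULL))
  neighbours <- vector("list", length(sense) * 3L)
  dim(neighbours) <- c(length(sense), 3L)
  dimnames(neighbours) <- list(sense, NULL)
  for (cod in sense) {
    sp <- strsplit(cod, "")[[1]]
    for (p in 1:3) {
      alt <- DNA_BASES[DNA_BASES != sp[p]]
      muts <- vapply(alt, function(b) {
        m <- sp; m[p] <- b; paste(m, collapse = "")
      }, character(1))
      keep <- aa[muts] != "*"
      valid <- muts[keep]
      syn <- valid[aa[valid] == aa[cod]]
      syn_frac[cod, p] <- if (length(valid)) length(syn) / length(valid) else 0
      neighbours[[cod, p]] <- list(valid = valid, syn = syn,
                                   nonsyn = setdiff(valid, syn))
    }
  }
  .codontab$aa <- aa
  .codontab$sense <- sense
  .codontab$syn_frac <- syn_frac
  .codontab$syn_sites <- rowSums(syn_frac)      # S per codon, in [0,3]
  .codontab$neighbours <- neighbours
  .codontab$pair_cache <- new.env(parent = emptyenv())
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  .init_codontab()
}

.codon_aa <- function(codon) .codontab$aa[codon]

.is_stop <- function(codon) .codontab$aa[codon] == "*"

#' Synonymous and nonsynonymous difference counts for one codon pair
#'
#' Implements the Nei-Gojobori (1986) pathway average: codons differing at
#' `k` positions are connected by `k!` orderings of single-base steps; each
#' step is synonymous when it preserves the encoded amino acid. Pathways that
#' pass through a stop codon are excluded from the average. In the degenerate
#' case where every pathway is blocked by a stop, all pathways are used and a
#' step into a stop codon is counted as nonsynonymous.
#'
#' @param c1,c2 three-letter sense codons (uppercase DNA alphabet).
#' @return numeric vector `c(sd, nd)` of fractional synonymous and
#'   nonsynonymous differences (`sd + nd` equals the number of differing
#'   positions).
#' @keywords internal
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0(c1, c2)
  cache <- .codontab$pair_cache
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)

  aa <- .codontab$aa
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  pos <- which(s1 != s2)
  paths <- .permutations(pos)
  tally <- function(order, allow_stop) {
    cur <- s1
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- s2[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (aa[to] == "*") {
        if (!allow_stop) return(NULL)
        nd <- nd + 1
      } else if (aa[from] == aa[to]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(paths, tally, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) res <- lapply(paths, tally, allow_stop = TRUE)
  m <- do.call(rbind, res)
  out <- c(sd = mean(m[, 1]), nd = mean(m[, 2]))
  cache[[key]] <- out
  out
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}
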