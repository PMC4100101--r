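# Independent brute-force oracles used to validate the estimators. These are
# deliberately naive re-derivations from first principles: they share no code
# with the package internals.

GC_TAB <- Biostrings::GENETIC_CODE

# --- NG86 oracle -----------------------------------------------------------

# Synonymous site count of one codon: per position, the synonymous share of
# its non-stop single-base neighbours.
oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  total <- 0
  for (p in 1:3) {
    syn <- 0; valid <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == ch[p]) next
      mut <- ch; mut[p] <- b
      mut <- paste(mut, collapse = "")
      if (GC_TAB[[mut]] == "*") next
      valid <- valid + 1
      if (GC_TAB[[mut]] == GC_TAB[[codon]]) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# All orderings of a vector, by naive recursion.
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  res <- list()
  for (i in seq_along(v)) {
    for (tail in oracle_perms(v[-i])) res[[length(res) + 1]] <- c(v[i], tail)
  }
  res
}

# Pathway-averaged synonymous/nonsynonymous differences between two codons:
# walk every ordering of the differing positions, drop pathways through
# stops; if none survives, use all pathways with stop steps as nonsynonymous.
oracle_pair_diffs <- function(c1, c2) {
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  diffpos <- which(ch1 != ch2)
  if (!length(diffpos)) return(c(0, 0))
  walk <- function(order, allow_stop) {
    cur <- ch1; sd <- 0; nd <- 0
    for (p in order) {
      prev <- paste(cur, collapse = "")
      cur[p] <- ch2[p]
      now <- paste(cur, collapse = "")
      if (GC_TAB[[now]] == "*") {
        if (!allow_stop) return(NULL)
        nd <- nd + 1
      } else if (GC_TAB[[prev]] == GC_TAB[[now]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
    }
    c(sd, nd)
  }
  paths <- oracle_perms(diffpos)
  done <- Filter(Negate(is.null), lapply(paths, walk, allow_stop = FALSE))
  if (!length(done)) done <- lapply(paths, walk, allow_stop = TRUE)
  Reduce(`+`, done) / length(done)
}

# Full NG86 statistics of a gap-free codon alignment given as two codon
# vectors.
oracle_ng86 <- function(cod1, cod2) {
  S <- (sum(vapply(cod1, oracle_syn_sites, 0)) +
          sum(vapply(cod2, oracle_syn_sites, 0))) / 2
  N <- 3 * length(cod1) - S
  d <- Reduce(`+`, Map(oracle_pair_diffs, cod1, cod2), accumulate = FALSE)
  list(S = S, N = N, Sd = d[1], Nd = d[2])
}

SENSE_CODONS <- names(GC_TAB)[GC_TAB != "*"]

# --- SSR regex oracle ------------------------------------------------------

oracle_is_primitive <- function(motif) {
  u <- nchar(motif)
  !any(vapply(seq_len(u - 1), function(d) {
    u %% d == 0 && paste(rep(substr(motif, 1, d), u / d),
                         collapse = "") == motif
  }, logical(1)))
}

# Regex-based perfect-microsatellite finder: per unit length, a backreference
# pattern anchored at the repeat-count threshold; candidates pooled across
# unit lengths, primitive motifs only, resolved leftmost-first (longer first
# at equal starts).
oracle_ssr <- function(seq, thresholds = c(`2` = 8, `3` = 5, `4` = 5,
                                           `5` = 5, `6` = 5),
                       min_flank = 50) {
  n <- nchar(seq)
  cand <- list()
  for (u in 2:6) {
    thr <- thresholds[[as.character(u)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, thr - 1)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (j in seq_along(m)) {
      start <- m[j]
      len <- attr(m, "match.length")[j]
      len <- (len %/% u) * u
      motif <- substr(seq, start, start + u - 1)
      if (!oracle_is_primitive(motif)) next
      cand[[length(cand) + 1]] <- data.frame(
        start0 = start - 1, end0 = start - 1 + len, unit = u,
        repeats = len %/% u, motif = motif)
    }
  }
  if (!length(cand)) {
    return(data.frame(start0 = numeric(0), end0 = numeric(0),
                      unit = numeric(0), repeats = numeric(0),
                      motif = character(0), passes_flank = logical(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start0, -(cand$end0 - cand$start0)), , drop = FALSE]
  kept <- list()
  last_end <- 0
  for (i in seq_len(nrow(cand))) {
    if (cand$start0[i] < last_end) next
    kept[[length(kept) + 1]] <- cand[i, ]
    last_end <- cand$end0[i]
  }
  kept <- do.call(rbind, kept)
  kept$passes_flank <- kept$start0 > min_flank & (n - kept$end0) > min_flank
  rownames(kept) <- NULL
  kept
}

# --- Affine local alignment oracle -----------------------------------------

# Smith-Waterman with affine gaps (first gap base costs open + ext), scores
# only.
oracle_local_score <- function(a, b, match = 1, mismatch = -2,
                               open = 5, ext = 2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)   # gap in y (consume x)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                                Iy[i - 1, j - 1]))
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- Hypergeometric enumeration oracle -------------------------------------

# Exact upper-tail probability by enumerating every n-subset of an urn of N
# balls of which K are marked.
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# --- misc helpers ----------------------------------------------------------

random_cds <- function(n_codons, seed) {
  set.seed(seed)
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}
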