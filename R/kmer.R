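# Exact canonical k-mer counting at desk scale.
#
# A canonical k-mer is the lexicographic minimum of a k-mer and its reverse
# complement; with odd k the two always differ, so canonicalization is
# strand-unambiguous. Counting is exact and in-memory — appropriate for the
# simulated genome sizes this package targets (no probabilistic sketches).

# all canonical k-mers of a character vector of sequences, one element per
# k-mer occurrence (not deduplicated)
canonical_kmers <- function(seqs, k) {
  if (k %% 2L == 0L) stop("k must be odd (strand-unambiguous canonicalization)")
  seqs <- seqs[nchar(seqs) >= k]
  if (!length(seqs)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  lens <- nchar(seqs)
  out <- vector("list", length(seqs))
  for (g in split(seq_along(seqs), lens)) {
    L <- lens[g[1L]]
    n_k <- L - k + 1L
    fwd <- vapply(seq_len(n_k), function(i)
      substring(seqs[g], i, i + k - 1L), character(length(g)))
    rev <- vapply(seq_len(n_k), function(i)
      substring(rc[g], L - i - k + 2L, L - i + 1L), character(length(g)))
    can <- pmin(fwd, rev)
    dim(can) <- NULL
    # row r of the implicit matrix = sequence g[r]; flatten per sequence
    m <- matrix(can, nrow = length(g))
    for (r in seq_along(g)) out[[g[r]]] <- m[r, ]
  }
  unlist(out, use.names = FALSE)
}

#' Exact canonical k-mer depth profile of a read set
#'
#' @param seqs character vector of read sequences (or a data.table with a
#'   `seq` column).
#' @param k odd k-mer size, at most the read length.
#' @return data.table with columns kmer, count.
#' @export
kmer_depth_profile <- function(seqs, k = 31L) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  if (length(seqs) && k > max(nchar(seqs))) {
    stop("k exceeds the read length")
  }
  km <- canonical_kmers(seqs, k)
  if (!length(km)) return(data.table(kmer = character(), count = integer()))
  dt <- data.table(kmer = km)[, .(count = .N), by = kmer]
  setkey(dt, kmer)
  dt[]
}

#' Normalize a read pool by k-mer depth (two-pass)
#'
#' Pass 1 counts canonical k-mers over the whole pool; pass 2 computes each
#' read's median k-mer count m and keeps the read with probability
#' min(1, target_depth / m). Reads whose median depth is already at or below
#' the target are always retained, so normalization only ever removes reads
#' from over-amplified regions — the MDA signature this step is designed to
#' flatten.
#'
#' @param reads data.table with read_id and seq columns (extra columns pass
#'   through).
#' @param k odd k-mer size (default 31).
#' @param target_depth desired k-mer depth after normalization (>= 1).
#' @param seed integer seed for the retention draws.
#' @return the retained subset of `reads` (same columns, original order),
#'   with a `median_kmer_depth` column appended.
#' @export
normalize_by_kmer_depth <- function(reads, k = 31L, target_depth, seed = 1L) {
  stopifnot(is.data.frame(reads), target_depth >= 1)
  reads <- as.data.table(reads)
  if (!nrow(reads)) {
    reads[, m := numeric(0)]
    setnames(reads, "m", "median_kmer_depth")
    return(reads[])
  }
  profile <- kmer_depth_profile(reads$seq, k)
  n_k <- nchar(reads$seq) - k + 1L
  km <- canonical_kmers(reads$seq, k)
  idx <- rep(seq_len(nrow(reads)), times = n_k)
  cnt <- profile[data.table(kmer = km), count, on = "kmer"]
  med <- data.table(i = idx, count = cnt)[, .(m = median(count)), by = i]
  med <- med[order(i)]
  set.seed(as.integer(seed))
  p_keep <- pmin(1, target_depth / med$m)
  keep <- runif(nrow(reads)) < p_keep
  out <- reads[keep]
  out[, median_kmer_depth := med$m[keep]]
  out[]
}
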