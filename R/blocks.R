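# Per-cell haplotype blocks and crossovers.
#
# Each QC-passing gamete cell is compared with the consensus haplotypes: at
# every non-missing locus it matches haplotype A or haplotype B (never both,
# by complementarity). A two-state HMM over these match calls absorbs isolated
# genotype errors — the motivation for block-level rather than SNP-level read
# partitioning — and its most-probable state path defines the cell's haplotype
# blocks; each change of state within a phase set is one crossover.

#' Per-locus match profile of one or more cells against the consensus
#'
#' @param gm a `genotype_matrix` (same loci, same order as `consensus`).
#' @param consensus a [majority_vote_phase()] result.
#' @return integer matrix, cells x loci: 1 = matches haplotype A, 2 = matches
#'   haplotype B, NA = missing genotype.
#' @export
genotype_match_profile <- function(gm, consensus) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(consensus) != ncol(gm$geno) ||
      !identical(consensus$chrom, gm$panel$chrom) ||
      !identical(as.integer(consensus$pos), as.integer(gm$panel$pos))) {
    stop("locus order mismatch between genotype matrix and consensus")
  }
  hapA_code <- ifelse(consensus$hapA_is_ref, 0L, 1L)
  prof <- sweep(gm$geno, 2L, hapA_code, function(g, h) {
    ifelse(is.na(g), NA_integer_, ifelse(g == h, 1L, 2L))
  })
  dimnames(prof) <- dimnames(gm$geno)
  prof
}

# Viterbi decode of the two-state haplotype HMM over one run of informative
# loci. states 1 = A, 2 = B; emission error epsilon; switch probability
# between consecutive loci at distance d: tau(d) = 1 - exp(-rate * d).
viterbi_decode <- function(match_codes, pos, epsilon, rate) {
  n <- length(match_codes)
  stopifnot(n >= 1L, epsilon > 0, epsilon < 0.5)
  le <- log(epsilon)
  lm <- log1p(-epsilon)
  # emission log-liks: rows = loci, cols = state A, B
  emis <- cbind(ifelse(match_codes == 1L, lm, le),
                ifelse(match_codes == 2L, lm, le))
  if (n == 1L) {
    return(list(states = which.max(emis[1L, ]), logp = max(emis[1L, ]) + log(0.5)))
  }
  d <- diff(pos)
  tau <- pmin(pmax(1 - exp(-rate * d), 1e-12), 1 - 1e-12)
  lsw <- log(tau)
  lst <- log1p(-tau)
  v <- matrix(-Inf, n, 2L)
  bp <- matrix(1L, n, 2L)
  v[1L, ] <- log(0.5) + emis[1L, ]
  for (t in 2:n) {
    for (s in 1:2) {
      from_same <- v[t - 1L, s] + lst[t - 1L]
      from_other <- v[t - 1L, 3L - s] + lsw[t - 1L]
      if (from_same >= from_other) {
        v[t, s] <- from_same + emis[t, s]
        bp[t, s] <- s
      } else {
        v[t, s] <- from_other + emis[t, s]
        bp[t, s] <- 3L - s
      }
    }
  }
  states <- integer(n)
  states[n] <- which.max(v[n, ])
  for (t in (n - 1L):1L) states[t] <- bp[t + 1L, states[t + 1L]]
  list(states = states, logp = max(v[n, ]))
}

# log-probability of one explicit state path (shared by tests/oracle)
path_logprob <- function(states, match_codes, pos, epsilon, rate) {
  le <- log(epsilon); lm <- log1p(-epsilon)
  emis <- ifelse(match_codes == states, lm, le)
  lp <- log(0.5) + sum(emis)
  if (length(states) > 1L) {
    tau <- pmin(pmax(1 - exp(-rate * diff(pos)), 1e-12), 1 - 1e-12)
    sw <- diff(states) != 0L
    lp <- lp + sum(ifelse(sw, log(tau), log1p(-tau)))
  }
  lp
}

# decode + iterative absorption of runs shorter than min_block_snps:
# short-run loci are dropped and the remaining loci re-decoded, so isolated
# MDA/genotype artifacts cannot spawn micro-blocks. Returns states for the
# kept loci (indices into the input vectors).
decode_with_absorption <- function(match_codes, pos, epsilon, rate,
                                   min_block_snps) {
  keep <- seq_along(match_codes)
  repeat {
    dec <- viterbi_decode(match_codes[keep], pos[keep], epsilon, rate)
    r <- rle(dec$states)
    if (length(r$lengths) == 1L || all(r$lengths >= min_block_snps)) {
      return(list(keep = keep, states = dec$states))
    }
    ok <- rep(r$lengths >= min_block_snps, r$lengths)
    if (!any(ok)) {
      # nothing survives: collapse to the single majority state
      maj <- if (sum(dec$states == 1L) >= sum(dec$states == 2L)) 1L else 2L
      return(list(keep = keep, states = rep(maj, length(keep))))
    }
    keep <- keep[ok]
  }
}

#' Call per-cell haplotype blocks and crossovers with a two-state HMM
#'
#' For every cell and chromosome the match profile against the consensus is
#' decoded with a two-state Viterbi HMM (emission error `epsilon`,
#' distance-scaled switch probability `1 - exp(-rate * d)` between loci at
#' distance d, so SNP deserts do not inflate per-junction crossover
#' probability). State runs shorter than `min_block_snps` are absorbed by
#' re-decoding without them. Block boundaries sit at the midpoint between the
#' flanking informative loci of adjacent blocks (the true breakpoint is
#' unidentifiable inside that interval); chromosome ends extend to the
#' sequence ends. Phase-set boundaries of the consensus force block breaks
#' without emitting a crossover, since haplotype labels are not comparable
#' across phase sets.
#'
#' @param gm a QC-filtered `genotype_matrix`.
#' @param consensus a [majority_vote_phase()] result on the same loci.
#' @param chrom_lengths named vector of chromosome lengths (bases).
#' @param epsilon per-SNP genotype error rate of the HMM (must be < 0.5);
#'   default 0.02, deliberately above typical simulated error so isolated
#'   miscalls are absorbed.
#' @param crossover_rate_per_bp switch rate r per base (default 1e-8, about
#'   1 cM/Mb).
#' @param min_block_snps minimum informative loci per block (default 5);
#'   shorter runs are treated as artifacts and absorbed.
#' @return list with `blocks` (data.table: cell, chrom, start, end — 0-based
#'   half-open, origin "A"/"B", n_snps, mean_match, phase_set) and
#'   `crossovers` (data.table: cell, chrom, left_snp_pos, right_snp_pos,
#'   midpoint).
#' @export
viterbi_blocks <- function(gm, consensus, chrom_lengths, epsilon = 0.02,
                           crossover_rate_per_bp = 1e-8, min_block_snps = 5L) {
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must be in (0, 0.5)")
  prof <- genotype_match_profile(gm, consensus)
  panel <- gm$panel
  block_list <- list()
  co_list <- list()
  for (cl in gm$cells) {
    for (chrom in unique(panel$chrom)) {
      cols <- which(panel$chrom == chrom)
      L <- chrom_lengths[[chrom]]
      inf <- cols[!is.na(prof[cl, cols])]
      if (!length(inf)) next
      # decode each phase set independently
      ps_ids <- consensus$phase_set[inf]
      seg_states <- integer(0)
      seg_loci <- integer(0)
      for (p in unique(ps_ids)) {
        idx <- inf[ps_ids == p]
        dec <- decode_with_absorption(prof[cl, idx], panel$pos[idx],
                                      epsilon, crossover_rate_per_bp,
                                      min_block_snps)
        seg_loci <- c(seg_loci, idx[dec$keep])
        seg_states <- c(seg_states, dec$states)
      }
      if (!length(seg_loci)) next
      ps <- consensus$phase_set[seg_loci]
      # block id advances on state change or phase-set change
      brk <- c(TRUE, diff(seg_states) != 0L | diff(ps) != 0L)
      bid <- cumsum(brk)
      first <- which(brk)
      last <- c(first[-1L] - 1L, length(seg_loci))
      n_blocks <- length(first)
      pos_first <- panel$pos[seg_loci[first]]
      pos_last <- panel$pos[seg_loci[last]]
      # 0-based boundaries: midpoints between flanking informative loci
      inner <- if (n_blocks > 1L) {
        (pos_last[-n_blocks] + pos_first[-1L]) %/% 2L
      } else integer(0)
      starts <- c(0L, inner)
      ends <- c(inner, L)
      # count ALL informative loci falling inside each block (absorbed ones
      # included) for n_snps / mean_match
      blk_of_locus <- findInterval(panel$pos[inf] - 1L, starts)
      st <- seg_states[first]
      n_snps_v <- tabulate(blk_of_locus, nbins = n_blocks)
      match_origin <- prof[cl, inf] == st[blk_of_locus]
      mean_match_v <- vapply(seq_len(n_blocks), function(b) {
        sel <- blk_of_locus == b
        if (!any(sel)) NA_real_ else mean(match_origin[sel])
      }, numeric(1L))
      block_list[[length(block_list) + 1L]] <- data.table(
        cell = cl, chrom = chrom, start = starts, end = ends,
        origin = c("A", "B")[st], n_snps = n_snps_v,
        mean_match = mean_match_v, phase_set = ps[first]
      )
      # crossovers: adjacent blocks within one phase set
      if (n_blocks > 1L) {
        same_ps <- ps[first][-n_blocks] == ps[first][-1L]
        if (any(same_ps)) {
          lf <- pos_last[-n_blocks][same_ps]
          rt <- pos_first[-1L][same_ps]
          co_list[[length(co_list) + 1L]] <- data.table(
            cell = cl, chrom = chrom, left_snp_pos = lf, right_snp_pos = rt,
            midpoint = (lf + rt) / 2
          )
        }
      }
    }
  }
  empty_blocks <- data.table(cell = character(), chrom = character(),
                             start = integer(), end = integer(),
                             origin = character(), n_snps = integer(),
                             mean_match = numeric(), phase_set = integer())
  empty_co <- data.table(cell = character(), chrom = character(),
                         left_snp_pos = integer(), right_snp_pos = integer(),
                         midpoint = numeric())
  list(
    blocks = if (length(block_list)) rbindlist(block_list) else empty_blocks,
    crossovers = if (length(co_list)) rbindlist(co_list) else empty_co
  )
}
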