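# Evaluation against simulator truth: hapmer-based PPV for read pools or
# contigs, switch error / Hamming accuracy for the consensus haplotypes, and
# precision/recall of crossover detection.

#' Compute haplotype-specific k-mers (hapmers)
#'
#' A hapmer is a canonical k-mer occurring in exactly one of the two truth
#' haplotypes. Any sequence or read pool can then be attributed to a
#' haplotype by counting which hapmer set it hits.
#'
#' @param hapA_seqs,hapB_seqs character vectors of haplotype sequences (one
#'   per chromosome, or contigs).
#' @param k odd k-mer size; default 21, the usual genome-survey size.
#' @return a `hapmer_sets` list: `k`, `hap1_only`, `hap2_only` (character
#'   vectors of canonical k-mers).
#' @export
compute_hapmers <- function(hapA_seqs, hapB_seqs, k = 21L) {
  set1 <- unique(canonical_kmers(as.character(hapA_seqs), k))
  set2 <- unique(canonical_kmers(as.character(hapB_seqs), k))
  structure(
    list(k = as.integer(k),
         hap1_only = setdiff(set1, set2),
         hap2_only = setdiff(set2, set1)),
    class = "hapmer_sets"
  )
}

#' Score sequence pools against hapmer sets (PPV)
#'
#' Counts, per pool, the occurrences of hapmers from each haplotype; the
#' positive predictive value is the dominant haplotype's count over the total,
#' so PPV is in [0.5, 1] whenever any marker is present and is invariant to
#' haplotype label swap. Pools with markers from both haplotypes above
#' `chimera_frac` of the total are flagged chimeric. The "ALL" row aggregates
#' per-pool PPVs weighted by marker counts — like per-contig scoring, each
#' pool keeps its own best-label orientation, so units from different
#' chromosomes (whose phase-set labels are independent conventions) do not
#' cancel each other.
#'
#' @param pools named list of character vectors of sequences (reads or
#'   contigs).
#' @param hapmers a [compute_hapmers()] result.
#' @param chimera_frac minority-fraction threshold for the chimera flag.
#' @return data.table with pool, n_hap1_markers, n_hap2_markers, ppv (NA when
#'   no markers), chimeric; the aggregate row "ALL" weights pools by marker
#'   count.
#' @export
score_pool <- function(pools, hapmers, chimera_frac = 0.05) {
  stopifnot(inherits(hapmers, "hapmer_sets"))
  rows <- lapply(names(pools), function(nm) {
    seqs <- as.character(pools[[nm]])
    km <- canonical_kmers(seqs, hapmers$k)
    n1 <- sum(km %in% hapmers$hap1_only)
    n2 <- sum(km %in% hapmers$hap2_only)
    data.table(pool = nm, n_hap1_markers = n1, n_hap2_markers = n2)
  })
  sc <- rbindlist(rows)
  sc[, ppv := ifelse(n_hap1_markers + n_hap2_markers > 0,
                     pmax(n_hap1_markers, n_hap2_markers) /
                       (n_hap1_markers + n_hap2_markers), NA_real_)]
  sc[, chimeric := !is.na(ppv) &
       pmin(n_hap1_markers, n_hap2_markers) >
       chimera_frac * (n_hap1_markers + n_hap2_markers)]
  # aggregate: per-pool PPVs weighted by marker counts (each pool keeps its
  # own best-label orientation, as in per-contig scoring)
  w <- sc$n_hap1_markers + sc$n_hap2_markers
  agg <- data.table(
    pool = "ALL",
    n_hap1_markers = sum(sc$n_hap1_markers),
    n_hap2_markers = sum(sc$n_hap2_markers),
    ppv = if (sum(w) > 0) sum(sc$ppv[w > 0] * w[w > 0]) / sum(w) else NA_real_,
    chimeric = NA
  )
  rbindlist(list(sc, agg))[]
}

#' Switch error and Hamming accuracy of the consensus haplotypes
#'
#' Within each phase set the consensus is compared to the truth haplotypes
#' under the better of the two global label assignments (the per-phase-set
#' anchoring convention is not an error). Switch errors are adjacent phased
#' locus pairs whose relative orientation disagrees with truth; they are
#' counted independently of the global labels.
#'
#' @param consensus a [majority_vote_phase()] result.
#' @param snp_truth simulator truth loci (chrom, pos, ref = haplotype-A
#'   allele, alt = haplotype-B allele).
#' @return list with `switch_error_rate`, `hamming_accuracy`, `n_pairs`,
#'   `n_switches`, `per_phase_set` table.
#' @export
switch_error <- function(consensus, snp_truth) {
  truth <- as.data.table(snp_truth)
  if (nrow(truth) != nrow(consensus) ||
      !identical(truth$chrom, consensus$chrom) ||
      !identical(as.integer(truth$pos), as.integer(consensus$pos))) {
    stop("consensus and truth loci differ")
  }
  # agreement indicator: consensus hapA carries the truth haplotype-A allele
  agree <- consensus$hapA == truth$ref
  dt <- data.table(chrom = consensus$chrom, ps = consensus$phase_set,
                   agree = agree)
  per_ps <- dt[, {
    n <- .N
    sw <- if (n > 1L) sum(agree[-1L] != agree[-n]) else 0L
    acc <- max(mean(agree), 1 - mean(agree))
    .(n_loci = n, n_pairs = n - 1L, n_switches = sw, hamming_accuracy = acc)
  }, by = .(chrom, ps)]
  n_pairs <- sum(per_ps$n_pairs)
  n_sw <- sum(per_ps$n_switches)
  list(
    switch_error_rate = if (n_pairs > 0) n_sw / n_pairs else NA_real_,
    hamming_accuracy = sum(per_ps$hamming_accuracy * per_ps$n_loci) /
      sum(per_ps$n_loci),
    n_pairs = n_pairs, n_switches = n_sw,
    per_phase_set = per_ps[]
  )
}

#' Precision/recall of detected crossovers against truth
#'
#' Matches detected events to truth breakpoints one-to-one, greedily by
#' increasing distance between the detected midpoint and the truth position,
#' within `tolerance` bases (per cell and chromosome). Also reports how many
#' matched truth breakpoints fall inside the detected flanking-locus interval
#' and localization-error quantiles.
#'
#' @param detected crossover table from [viterbi_blocks()].
#' @param truth_crossovers simulator truth (cell, chrom, pos).
#' @param tolerance maximum midpoint-to-truth distance for a match (bases).
#' @return list with precision (NA when nothing was detected), recall,
#'   n_detected, n_truth, n_matched, frac_in_interval, loc_error_quantiles.
#' @export
crossover_recovery <- function(detected, truth_crossovers, tolerance) {
  det <- as.data.table(detected)
  tru <- as.data.table(truth_crossovers)
  n_det <- nrow(det)
  n_tru <- nrow(tru)
  matched_err <- numeric(0)
  n_in_interval <- 0L
  if (n_det && n_tru) {
    det[, id := .I]
    tru[, id := .I]
    cand <- merge(det[, .(cell, chrom, did = id, midpoint,
                          left_snp_pos, right_snp_pos)],
                  tru[, .(cell, chrom, tid = id, tpos = pos)],
                  by = c("cell", "chrom"), allow.cartesian = TRUE)
    cand[, dist := abs(midpoint - tpos)]
    cand <- cand[dist <= tolerance][order(dist)]
    used_d <- logical(n_det)
    used_t <- logical(n_tru)
    for (r in seq_len(nrow(cand))) {
      d <- cand$did[r]; t <- cand$tid[r]
      if (!used_d[d] && !used_t[t]) {
        used_d[d] <- TRUE
        used_t[t] <- TRUE
        matched_err <- c(matched_err, cand$dist[r])
        if (cand$tpos[r] >= cand$left_snp_pos[r] &&
            cand$tpos[r] <= cand$right_snp_pos[r]) {
          n_in_interval <- n_in_interval + 1L
        }
      }
    }
  }
  n_match <- length(matched_err)
  list(
    precision = if (n_det > 0) n_match / n_det else NA_real_,
    recall = if (n_tru > 0) n_match / n_tru else NA_real_,
    n_detected = n_det, n_truth = n_tru, n_matched = n_match,
    frac_in_interval = if (n_match > 0) n_in_interval / n_match else NA_real_,
    loc_error_quantiles = if (n_match > 0) {
      quantile(matched_err, c(0.5, 0.9, 1))
    } else setNames(rep(NA_real_, 3L), c("50%", "90%", "100%"))
  )
}
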