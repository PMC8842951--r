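# Haplotype-block-based read partitioning.
#
# A read is attributed to a parental haplotype only when its mapped interval
# is fully contained in a haplotype block of its own cell — containment, not
# overlap-majority, because boundary-straddling reads are precisely the ones
# whose wrong-haplotype k-mers would contaminate downstream trio-binning, and
# the pipeline can afford to discard them.

#' Partition gamete-cell reads into two parental pools
#'
#' Assigns each read to origin A or B when its placement interval is fully
#' contained in a same-origin haplotype block of its own cell; reads
#' straddling block boundaries, falling in inter-block gaps, or from cells
#' without blocks are unassigned. For read pairs (via `mate_id`): mates that
#' disagree (one A, one B) are both unassigned; a pair with one assigned and
#' one unassigned mate takes the assigned origin.
#'
#' @param placements data.table with read_id, cell, chrom, start, end
#'   (0-based half-open) and optionally mate_id.
#' @param blocks block table from [viterbi_blocks()].
#' @return list with `assignments` (placements plus an `assigned` column in
#'   "A"/"B"/"unassigned"), `counts` (per-cell A/B/unassigned tallies).
#' @export
partition_reads <- function(placements, blocks) {
  placements <- as.data.table(placements)
  stopifnot(all(c("read_id", "cell", "chrom", "start", "end") %in%
                  names(placements)))
  unknown <- setdiff(unique(placements$cell), unique(blocks$cell))
  if (length(unknown) && nrow(blocks)) {
    stop("placements reference cell(s) without blocks: ",
         paste(unknown, collapse = ", "))
  }
  bl <- as.data.table(blocks)
  assigned <- rep("unassigned", nrow(placements))
  if (nrow(bl)) {
    grp_p <- split(seq_len(nrow(placements)),
                   paste(placements$cell, placements$chrom))
    for (gkey in names(grp_p)) {
      pi <- grp_p[[gkey]]
      cl <- placements$cell[pi[1L]]
      ch <- placements$chrom[pi[1L]]
      b <- bl[cell == cl & chrom == ch]
      if (!nrow(b)) next
      setorder(b, start)
      # blocks tile the chromosome: the candidate block is the one whose
      # start is the last <= read start; containment then just checks end
      hit <- findInterval(placements$start[pi], b$start)
      ok <- hit >= 1L & placements$end[pi] <= b$end[pmax(hit, 1L)]
      assigned[pi[ok]] <- b$origin[hit[ok]]
    }
  }
  if ("mate_id" %in% names(placements) && any(!is.na(placements$mate_id))) {
    dt <- data.table(idx = seq_len(nrow(placements)),
                     pair = placements$mate_id, a = assigned)
    dt[!is.na(pair), a := {
      u <- setdiff(unique(a), "unassigned")
      if (length(u) == 1L) rep(u, .N)
      else if (length(u) > 1L) rep("unassigned", .N)
      else a
    }, by = pair]
    assigned <- dt[order(idx), a]
  }
  out <- copy(placements)
  out[, assigned := assigned]
  counts <- out[, .(n = .N), by = .(cell, assigned)]
  list(assignments = out[], counts = counts[])
}

#' Split an assignment table into per-pool read tables
#'
#' @param assignments the `assignments` table from [partition_reads()] (must
#'   carry a `seq` column to be written as FASTQ).
#' @return named list of data.tables: pool_A, pool_B, unassigned.
#' @export
split_pools <- function(assignments) {
  list(
    pool_A = assignments[assigned == "A"],
    pool_B = assignments[assigned == "B"],
    unassigned = assignments[assigned == "unassigned"]
  )
}
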