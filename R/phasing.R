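# Majority-vote consensus phasing.
#
# Finding the orientation assignment that satisfies the most linkage edges is
# NP-hard in general (it is an Ising ground state / MAX-CUT-type problem once
# edges may span arbitrary distances), so the chromosome-scale path is greedy
# chaining plus a local cleaning pass; phase sets small enough to solve
# exactly are then re-optimized by branch and bound, where greedy is both
# most fallible (sparse evidence) and exact search is affordable.
#
# Every gamete cell is haploid, so a pair of non-missing calls at two loci in
# one cell is direct phase evidence: equal genotype codes say the two alleles
# sit on the same parental haplotype (cis), unequal say trans. Aggregating
# these two-locus observations over cells and chaining them left-to-right
# gives the two parental haplotypes; evidence is broken only by meiotic
# crossovers (a minority at any junction when cells are independent) and by
# genotype errors.

#' Collect per-cell linkage edges and per-junction vote counts
#'
#' For each cell and chromosome, every pair of *consecutive non-missing* loci
#' yields one edge with orientation cis (equal genotypes) or trans. Edges
#' whose loci are adjacent in the panel (span 1) form the per-junction vote
#' table; longer-span edges (the cell is missing the loci in between) still
#' vote during phasing but are flagged by their span.
#'
#' @param gm a QC-filtered `genotype_matrix`.
#' @return list with `edges` (data.table: chrom, i, j — global panel column
#'   indices, cell, cis, span) and `junctions` (data.table: chrom, i, j,
#'   pos_i, pos_j, cis_votes, trans_votes, n_informative for every adjacent
#'   locus pair).
#' @export
collect_link_votes <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  panel <- gm$panel
  chrom_cols <- split(seq_len(nrow(panel)), panel$chrom)
  edge_list <- list()
  for (chrom in names(chrom_cols)) {
    cols <- chrom_cols[[chrom]]
    sub <- gm$geno[, cols, drop = FALSE]
    for (r in seq_along(gm$cells)) {
      nm <- which(!is.na(sub[r, ]))
      if (length(nm) < 2L) next
      a <- nm[-length(nm)]
      b <- nm[-1L]
      edge_list[[length(edge_list) + 1L]] <- data.table(
        chrom = chrom, i = cols[a], j = cols[b], cell = gm$cells[r],
        cis = sub[r, a] == sub[r, b], span = b - a
      )
    }
  }
  edges <- if (length(edge_list)) rbindlist(edge_list) else
    data.table(chrom = character(), i = integer(), j = integer(),
               cell = character(), cis = logical(), span = integer())
  adj <- rbindlist(c(
    list(data.table(chrom = character(), i = integer(), j = integer())),
    lapply(names(chrom_cols), function(ch) {
      cols <- chrom_cols[[ch]]
      if (length(cols) < 2L) return(NULL)
      data.table(chrom = ch, i = cols[-length(cols)], j = cols[-1L])
    })
  ))
  direct <- edges[span == 1L, .(cis_votes = sum(cis),
                                trans_votes = sum(!cis)), by = .(chrom, i, j)]
  junctions <- merge(adj, direct, by = c("chrom", "i", "j"), all.x = TRUE)
  junctions[is.na(cis_votes), `:=`(cis_votes = 0L, trans_votes = 0L)]
  junctions[, n_informative := cis_votes + trans_votes]
  junctions[, `:=`(pos_i = gm$panel$pos[i], pos_j = gm$panel$pos[j])]
  setorder(junctions, chrom, i)
  list(edges = edges, junctions = junctions[])
}

#' Reconstruct consensus parental haplotypes by majority vote
#'
#' Per chromosome. First, greedy left-to-right chaining: each locus receives
#' one vote per linkage edge arriving from an already-phased locus (the
#' edge's cis/trans composed with the source assignment) and the majority
#' wins. Second, a cleaning pass over the whole chromosome: any junction
#' whose net crossing-edge vote (satisfied minus violated edges spanning it)
#' is negative has its right-hand suffix flipped, and any single locus with
#' negative net agreement is flipped, until no such move remains — isolated
#' wrong majority calls from weak left-side evidence are corrected by the
#' evidence to their right; each flip strictly increases the number of
#' satisfied votes, so the pass terminates. Chromosomes with at most
#' `exact_limit` loci are additionally re-optimized to a certified
#' maximum-agreement assignment by depth-first branch and bound (initialized
#' at the cleaned greedy solution, which is kept when it already ties the
#' optimum).
#'
#' Phase sets are then derived from the converged solution: a break is
#' placed at every junction whose net crossing-edge vote is zero — no
#' informative cell, or votes exactly tied. A tie is never guessed, because
#' a wrong guess would silently propagate switch errors over the rest of the
#' chromosome. The first locus of each phase set is anchored with haplotype
#' A carrying its REF allele (a pure labeling convention).
#'
#' @param gm a QC-filtered `genotype_matrix`.
#' @param max_span optional cap on edge span (Inf: all edges vote).
#' @param exact_limit chromosomes with at most this many loci are solved to
#'   optimality (complexity is exponential in size; 16 keeps the worst case
#'   well under a second).
#' @return a `consensus_haplotypes` data.table: chrom, pos, ref, alt, hapA,
#'   hapB (allele characters, complementary), hapA_is_ref, phase_set (global
#'   id, non-decreasing within a chromosome), margin (converged net
#'   crossing-edge vote at the junction entering the locus; 0 at phase-set
#'   starts).
#' @export
majority_vote_phase <- function(gm, max_span = Inf, exact_limit = 16L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  lv <- collect_link_votes(gm)
  edges <- lv$edges
  if (is.finite(max_span)) edges <- edges[span <= max_span]
  panel <- gm$panel
  n <- nrow(panel)
  orientation <- integer(n)     # 0: hapA = REF at locus, 1: hapA = ALT
  phase_set <- integer(n)
  margin <- integer(n)
  ps <- 0L
  by_j <- split(seq_len(nrow(edges)), edges$j)
  chrom_cols <- split(seq_len(n), panel$chrom)
  for (chrom in names(chrom_cols)) {
    cols <- chrom_cols[[chrom]]
    L <- length(cols)
    if (L < 2L) {
      warning(sprintf("chromosome %s has %d locus/loci; single-locus phase set",
                      chrom, L))
      ps <- ps + 1L
      phase_set[cols] <- ps
      next
    }
    # greedy pass: majority over edges arriving from already-phased loci
    for (jj in cols[-1L]) {
      e <- by_j[[as.character(jj)]]
      votes1 <- votes0 <- 0L
      if (!is.null(e)) {
        src <- edges$i[e]
        implied <- xor(orientation[src] == 1L, !edges$cis[e])
        votes1 <- sum(implied)    # implied TRUE: hapA = ALT at jj
        votes0 <- sum(!implied)
      }
      orientation[jj] <- if (votes1 == votes0) orientation[jj - 1L] else
        as.integer(votes1 > votes0)
    }
    # cleaning pass over the whole chromosome (all edges)
    sel <- which(edges$j %in% cols)
    ei <- match(edges$i[sel], cols)
    ej <- match(edges$j[sel], cols)
    cis <- edges$cis[sel]
    s_j <- integer(L - 1L)
    if (length(sel)) {
      if (L <= exact_limit) {
        orientation[cols] <- max_agreement_exact(orientation[cols],
                                                 ei, ej, cis)
      }
      repeat {
        o <- orientation[cols]
        sat <- ifelse((o[ei] == o[ej]) == cis, 1L, -1L)
        s_j <- integer(L - 1L)
        s_l <- integer(L)
        for (r in seq_along(sat)) {
          rng <- ei[r]:(ej[r] - 1L)
          s_j[rng] <- s_j[rng] + sat[r]
          s_l[ei[r]] <- s_l[ei[r]] + sat[r]
          s_l[ej[r]] <- s_l[ej[r]] + sat[r]
        }
        worst_j <- which.min(s_j)
        worst_l <- which.min(s_l[-1L]) + 1L  # the anchor locus never flips
        if (s_j[worst_j] >= 0L && s_l[worst_l] >= 0L) break
        flip <- if (s_j[worst_j] <= s_l[worst_l]) {
          cols[(worst_j + 1L):L]     # suffix right of the worst junction
        } else {
          cols[worst_l]              # single worst locus
        }
        orientation[flip] <- 1L - orientation[flip]
      }
    }
    # phase sets: break exactly where the net crossing evidence is zero
    # (no informative cell, or votes exactly tied)
    brk <- s_j == 0L
    ids <- cumsum(c(TRUE, brk))
    phase_set[cols] <- ps + ids
    margin[cols] <- c(0L, ifelse(brk, 0L, s_j))
    ps <- ps + ids[length(ids)]
    # re-anchor every phase set: hapA = REF at its first locus
    for (p in unique(ids)) {
      first <- cols[which(ids == p)[1L]]
      if (orientation[first] == 1L) {
        grp <- cols[ids == p]
        orientation[grp] <- 1L - orientation[grp]
      }
    }
  }
  out <- data.table(
    chrom = panel$chrom, pos = panel$pos, ref = panel$ref, alt = panel$alt,
    hapA = ifelse(orientation == 0L, panel$ref, panel$alt),
    hapB = ifelse(orientation == 0L, panel$alt, panel$ref),
    hapA_is_ref = orientation == 0L,
    phase_set = phase_set, margin = margin
  )
  class(out) <- c("consensus_haplotypes", class(out))
  out
}

# Certified maximum-agreement orientations for one small phase set by
# depth-first branch and bound over o[2..L] (o[1] anchored at 0), pruning on
# the violation count of the incumbent. The incumbent starts at the cleaned
# greedy solution and is only replaced by strictly better assignments, so
# ties keep the greedy answer and determinism is preserved.
max_agreement_exact <- function(o_init, ei, ej, cis) {
  L <- length(o_init)
  viol_of <- function(o) sum((o[ei] == o[ej]) != cis)
  if (o_init[1L] == 1L) o_init <- 1L - o_init   # normalize anchor
  best_o <- o_init
  best_v <- viol_of(o_init)
  if (best_v == 0L || L < 2L) return(best_o)
  ends_at <- split(seq_along(ej), ej)
  o <- integer(L)
  dfs <- function(l, v) {
    if (v >= best_v) return()
    if (l > L) {
      best_v <<- v
      best_o <<- o[seq_len(L)]
      return()
    }
    dec <- ends_at[[as.character(l)]]
    for (bit in 0:1) {
      o[l] <<- bit
      dv <- if (is.null(dec)) 0L else
        sum((o[ei[dec]] == bit) != cis[dec])
      dfs(l + 1L, v + dv)
    }
  }
  dfs(2L, 0L)
  best_o
}

#' Exhaustive maximum-agreement phasing oracle (tests only)
#'
#' Enumerates every orientation assignment of a small single-chromosome
#' genotype matrix and returns the assignment(s) maximizing the number of
#' satisfied linkage edges. Complexity 2^(L-1); refuses more than `max_loci`
#' loci.
#'
#' @param gm a single-chromosome `genotype_matrix` with at most `max_loci`
#'   loci.
#' @param max_loci combinatorial guard (default 12).
#' @return list with `best` (orientation vector of the first optimum, 0 =
#'   hapA is REF), `optima` (matrix, one row per optimal assignment),
#'   `score` (satisfied edge count).
#' @export
exhaustive_phase_oracle <- function(gm, max_loci = 12L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(unique(gm$panel$chrom)) != 1L) {
    stop("oracle handles a single chromosome")
  }
  L <- ncol(gm$geno)
  if (L > max_loci) stop("refusing to enumerate more than ", max_loci, " loci")
  edges <- collect_link_votes(gm)$edges
  if (L == 1L) {
    return(list(best = 0L, optima = matrix(0L, 1L, 1L), score = 0))
  }
  n_assign <- 2^(L - 1L)
  assign <- matrix(0L, nrow = n_assign, ncol = L)
  for (l in 2:L) {
    assign[, l] <- bitwAnd(seq_len(n_assign) - 1L, bitwShiftL(1L, l - 2L)) > 0L
  }
  score <- numeric(n_assign)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      same <- assign[, edges$i[e]] == assign[, edges$j[e]]
      score <- score + (same == edges$cis[e])
    }
  }
  top <- which(score == max(score))
  list(best = assign[top[1L], ], optima = assign[top, , drop = FALSE],
       score = max(score))
}
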