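# Fixture builders shared across tests. Everything is generated in code; no
# binary fixtures.

# genotype_matrix straight from an integer matrix (rows = cells); codes
# 0 = REF, 1 = ALT, NA = missing
make_gm <- function(geno, pos = NULL, chrom = "chr1",
                    n_het_raw = NULL, n_called = NULL) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L)
  n_cells <- nrow(geno)
  n_loci <- ncol(geno)
  cells <- sprintf("cell%02d", seq_len(n_cells))
  dimnames(geno) <- list(cells, NULL)
  storage.mode(geno) <- "integer"
  if (is.null(pos)) pos <- seq_len(n_loci) * 1000L
  panel <- data.table::data.table(
    chrom = rep(chrom, length.out = n_loci), pos = as.integer(pos),
    ref = "A", alt = "C"
  )
  data.table::setorder(panel, chrom, pos)
  if (is.null(n_called)) n_called <- rowSums(!is.na(geno))
  if (is.null(n_het_raw)) n_het_raw <- integer(n_cells)
  structure(
    list(geno = geno, panel = panel, cells = cells,
         n_called = stats::setNames(as.integer(n_called), cells),
         n_het_raw = stats::setNames(as.integer(n_het_raw), cells),
         n_low_depth = stats::setNames(integer(n_cells), cells)),
    class = "genotype_matrix"
  )
}

# random small phasing instance: cells follow recombinant paths over an
# all-REF haplotype A, with genotype error and missingness
random_instance <- function(n_loci, n_cells, error = 0.05, missing = 0.3,
                            switch_prob = 0.2) {
  geno <- matrix(NA_integer_, n_cells, n_loci)
  for (r in seq_len(n_cells)) {
    state <- sample(0:1, 1L)
    g <- integer(n_loci)
    for (l in seq_len(n_loci)) {
      if (l > 1L && runif(1) < switch_prob) state <- 1L - state
      g[l] <- state
    }
    flip <- runif(n_loci) < error
    g[flip] <- 1L - g[flip]
    g[runif(n_loci) < missing] <- NA_integer_
    geno[r, ] <- g
  }
  make_gm(geno)
}

# the stated world for read-level tests: per-base SNP density and crossover
# density of the genotype-scale default (2 crossovers and 2000 SNPs per Mb),
# shrunk to 100 kb chromosomes so read volumes stay within desk-scale budgets
read_world_cfg <- function(seed = 11L, ...) {
  args <- list(
    n_chromosomes = 2L, chrom_length = 1e5, snp_rate = 0.002,
    n_cells = 20L, crossover_lambda = 0.2, genotype_error = 0.01,
    missing_rate_target = 0.40, het_call_rate = 0.01,
    read_length = 100L, mean_depth = 6, seed = seed
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# brute-force most-probable HMM path by full enumeration (independent oracle)
brute_force_best_path <- function(match_codes, pos, epsilon, rate) {
  n <- length(match_codes)
  n_paths <- 2^n
  best_lp <- -Inf
  best_path <- NULL
  states <- matrix(1L, n_paths, n)
  for (l in seq_len(n)) {
    states[, l] <- bitwAnd(seq_len(n_paths) - 1L, bitwShiftL(1L, l - 1L)) > 0L
  }
  states <- states + 1L
  lp <- numeric(n_paths)
  le <- log(epsilon); lm <- log1p(-epsilon)
  for (l in seq_len(n)) {
    lp <- lp + ifelse(states[, l] == match_codes[l], lm, le)
  }
  lp <- lp + log(0.5)
  if (n > 1L) {
    tau <- pmin(pmax(1 - exp(-rate * diff(pos)), 1e-12), 1 - 1e-12)
    for (l in 2:n) {
      sw <- states[, l] != states[, l - 1L]
      lp <- lp + ifelse(sw, log(tau[l - 1L]), log1p(-tau[l - 1L]))
    }
  }
  list(states = states[which.max(lp), ], logp = max(lp))
}

# fraction of assigned reads whose label matches truth origin, after mapping
# the per-(chrom, phase set) consensus labels to truth by majority (labels are
# conventions; a globally swapped phase set is not an assignment error)
assigned_purity <- function(assigned, blocks) {
  a <- data.table::as.data.table(assigned)
  bl <- data.table::as.data.table(blocks)
  grp <- split(seq_len(nrow(a)), paste(a$cell, a$chrom))
  ps <- integer(nrow(a))
  for (g in grp) {
    b <- bl[bl$cell == a$cell[g[1]] & bl$chrom == a$chrom[g[1]]]
    data.table::setorder(b, start)
    ps[g] <- b$phase_set[findInterval(a$start[g], b$start)]
  }
  a[, ps_ := ps]
  per <- a[, .(n_match = max(sum(assigned == truth_origin),
                             sum(assigned != truth_origin)), n = .N),
           by = .(chrom, ps_)]
  sum(per$n_match) / sum(per$n)
}

# random DNA string
rand_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
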