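#' Simulate a diploid genome with heterozygous biallelic SNPs
#'
#' Draws one random nucleotide sequence per chromosome (haplotype A), then
#' plants heterozygous biallelic SNPs at a per-base rate; haplotype B is
#' identical except for the alternate allele at each SNP locus. By simulation
#' bookkeeping convention the reference allele is the haplotype-A allele.
#'
#' @param cfg a [sim_config()].
#' @return list with `hapA`, `hapB` (named character vectors, one sequence per
#'   chromosome), `chrom_lengths` (named integer vector) and `snp_truth`
#'   (data.table: chrom, pos (1-based), ref, alt).
#' @export
simulate_diploid_genome <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, 1L))
  bases <- c("A", "C", "G", "T")
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  hapA <- hapB <- setNames(character(cfg$n_chromosomes), chroms)
  snp_list <- vector("list", cfg$n_chromosomes)
  for (ci in seq_along(chroms)) {
    L <- cfg$chrom_length
    seqA <- sample(bases, L, replace = TRUE)
    pos <- which(runif(L) < cfg$snp_rate)
    seqB <- seqA
    if (length(pos)) {
      # alternate allele: a uniformly random base different from ref
      shift_by <- sample(1:3, length(pos), replace = TRUE)
      refs <- seqA[pos]
      alts <- bases[(match(refs, bases) - 1L + shift_by) %% 4L + 1L]
      seqB[pos] <- alts
      snp_list[[ci]] <- data.table(
        chrom = chroms[ci], pos = pos, ref = refs, alt = alts
      )
    } else {
      snp_list[[ci]] <- data.table(
        chrom = character(), pos = integer(),
        ref = character(), alt = character()
      )
    }
    hapA[ci] <- paste0(seqA, collapse = "")
    hapB[ci] <- paste0(seqB, collapse = "")
  }
  snp_truth <- rbindlist(snp_list)
  setkey(snp_truth, chrom, pos)
  list(
    hapA = hapA, hapB = hapB,
    chrom_lengths = setNames(rep(cfg$chrom_length, cfg$n_chromosomes), chroms),
    snp_truth = snp_truth
  )
}

#' Simulate meiotic crossovers for each gamete cell
#'
#' Per cell and chromosome the crossover count is Poisson(`crossover_lambda`)
#' with breakpoints uniform along the chromosome (no interference, no obligate
#' crossover). Segments alternate parental origin starting from a fair coin.
#'
#' @param genome output of [simulate_diploid_genome()].
#' @param cfg a [sim_config()].
#' @return list with `cell_paths` (data.table: cell, chrom, start, end
#'   (0-based half-open), origin "A"/"B") and `crossovers` (data.table: cell,
#'   chrom, pos — the 0-based breakpoint between adjacent segments).
#' @export
simulate_meiosis <- function(genome, cfg) {
  set.seed(substream_seed(cfg$seed, 2L))
  cells <- sprintf("cell%02d", seq_len(cfg$n_cells))
  paths <- vector("list", cfg$n_cells * length(genome$chrom_lengths))
  cos <- vector("list", length(paths))
  k <- 0L
  for (cell in cells) {
    for (chrom in names(genome$chrom_lengths)) {
      k <- k + 1L
      L <- genome$chrom_lengths[[chrom]]
      n_co <- rpois(1L, cfg$crossover_lambda)
      bp <- sort(unique(ceiling(runif(n_co) * (L - 1L))))  # in [1, L-1]
      bounds <- c(0L, bp, L)
      n_seg <- length(bounds) - 1L
      first <- sample(c("A", "B"), 1L)
      orig <- rep(c(first, setdiff(c("A", "B"), first)),
                  length.out = n_seg)
      paths[[k]] <- data.table(
        cell = cell, chrom = chrom,
        start = bounds[-length(bounds)], end = bounds[-1L], origin = orig
      )
      cos[[k]] <- if (length(bp)) {
        data.table(cell = cell, chrom = chrom, pos = bp)
      } else {
        data.table(cell = character(), chrom = character(), pos = integer())
      }
    }
  }
  list(cell_paths = rbindlist(paths), crossovers = rbindlist(cos))
}

# Per-(cell, chromosome, window) MDA amplification factors,
# Gamma(shape, rate = shape) so the mean is 1. One shared stream: the same
# factors drive genotype dropout and read depth, as MDA chemistry would.
mda_window_factors <- function(cfg, chrom_lengths, cells) {
  set.seed(substream_seed(cfg$seed, 3L))
  grid <- rbindlist(lapply(names(chrom_lengths), function(chrom) {
    n_win <- ceiling(chrom_lengths[[chrom]] / cfg$mda_window)
    data.table(chrom = chrom, window = seq_len(n_win) - 1L)
  }))
  out <- rbindlist(lapply(cells, function(cl) {
    g <- data.table(cell = cl, grid)
    g[, factor_ := rgamma(.N, shape = cfg$mda_gamma_shape,
                          rate = cfg$mda_gamma_shape)]
    g
  }))
  setkey(out, cell, chrom, window)
  out
}

# parental origin of each (cell, locus): project cell_paths onto SNP positions
origin_at_loci <- function(cell_paths, snp_truth) {
  stopifnot(nrow(snp_truth) > 0L)
  paths <- split(cell_paths, by = "cell")
  cells <- names(paths)
  org <- matrix(NA_character_, nrow = length(cells), ncol = nrow(snp_truth),
                dimnames = list(cells, NULL))
  by_chrom <- split(seq_len(nrow(snp_truth)), snp_truth$chrom)
  for (cl in cells) {
    p <- paths[[cl]]
    for (ch in names(by_chrom)) {
      idx <- by_chrom[[ch]]
      seg <- p[p[["chrom"]] == ch]
      # pos is 1-based; segment [start, end) 0-based contains pos iff
      # start < pos <= end
      seg_idx <- findInterval(snp_truth$pos[idx] - 1L, seg$start)
      org[cl, idx] <- seg$origin[seg_idx]
    }
  }
  org
}

#' Simulate per-cell genotype observations
#'
#' Projects each cell's recombinant path onto the SNP loci (origin A gives the
#' reference allele, origin B the alternate), then distorts the truth the way
#' MDA-amplified single-cell calls are distorted: genotypes flip with
#' probability `genotype_error`, a fraction `het_call_rate` of calls is
#' reported heterozygous-in-haploid, and whole amplification windows drop out
#' (missing calls) wherever the cell's MDA factor falls below the quantile
#' matching `missing_rate_target`.
#'
#' @param truth list with `genome` ([simulate_diploid_genome()] output) and
#'   `cell_paths` ([simulate_meiosis()] output).
#' @param cfg a [sim_config()].
#' @return a `raw_observations` object: list with `geno` (cells x loci integer
#'   matrix; 0 = REF, 1 = ALT, 2 = heterozygous raw call, NA = missing),
#'   `panel` (the SNP loci) and `cells`.
#' @export
simulate_cell_observations <- function(truth, cfg) {
  snp <- truth$genome$snp_truth
  cells <- unique(truth$cell_paths$cell)
  org <- origin_at_loci(truth$cell_paths, snp)
  geno <- matrix(ifelse(org == "A", 0L, 1L), nrow = length(cells),
                 dimnames = list(cells, NULL))

  set.seed(substream_seed(cfg$seed, 4L))
  n <- length(geno)
  if (cfg$genotype_error > 0) {
    flip <- matrix(runif(n) < cfg$genotype_error, nrow = nrow(geno))
    geno[flip] <- 1L - geno[flip]
  }
  if (cfg$het_call_rate > 0) {
    het <- matrix(runif(n) < cfg$het_call_rate, nrow = nrow(geno))
    geno[het] <- 2L
  }
  if (cfg$missing_rate_target > 0) {
    fac <- mda_window_factors(cfg, truth$genome$chrom_lengths, cells)
    locus_win <- (snp$pos - 1L) %/% cfg$mda_window
    for (cl in cells) {
      f <- fac[cell == cl]
      thr <- quantile(f$factor_, cfg$missing_rate_target, type = 1)
      dropped <- f[factor_ <= thr]
      drop_loci <- which(paste(snp$chrom, locus_win) %in%
                           paste(dropped$chrom, dropped$window))
      geno[cl, drop_loci] <- NA_integer_
    }
  }
  structure(
    list(geno = geno, panel = copy(snp), cells = cells),
    class = "raw_observations"
  )
}

#' Simulate gamete-cell short reads with MDA coverage bias
#'
#' Samples error-free fixed-length reads from each cell's recombinant gamete
#' sequence. Per amplification window the expected read count is scaled by the
#' cell's MDA factor (shared with [simulate_cell_observations()]), reproducing
#' the extremely uneven single-cell coverage that motivates k-mer-depth
#' normalization downstream.
#'
#' @param truth list with `genome` and `cell_paths` components.
#' @param cfg a [sim_config()].
#' @return data.table with columns read_id, cell, chrom, start, end (0-based
#'   half-open placement on the reference), truth_origin (origin of the
#'   segment containing the read midpoint) and seq.
#' @export
simulate_cell_reads <- function(truth, cfg) {
  if (cfg$read_length > min(truth$genome$chrom_lengths)) {
    stop("read_length exceeds chromosome length")
  }
  cells <- unique(truth$cell_paths$cell)
  fac <- mda_window_factors(cfg, truth$genome$chrom_lengths, cells)
  set.seed(substream_seed(cfg$seed, 5L))
  out <- vector("list", length(cells) * length(truth$genome$chrom_lengths))
  k <- 0L
  for (cl in cells) {
    for (ch in names(truth$genome$chrom_lengths)) {
      k <- k + 1L
      L <- truth$genome$chrom_lengths[[ch]]
      f <- fac[list(cl, ch)]
      win_start <- f$window * cfg$mda_window
      win_len <- pmin(cfg$mda_window, L - win_start)
      lambda <- cfg$mean_depth * win_len / cfg$read_length * f$factor_
      n_reads <- rpois(length(lambda), lambda)
      if (sum(n_reads) == 0L) next
      starts <- unlist(mapply(function(ws, wl, n) {
        if (n == 0L) return(integer())
        floor(ws + runif(n) * wl)
      }, win_start, win_len, n_reads, SIMPLIFY = FALSE), use.names = FALSE)
      starts <- pmin(as.integer(starts), L - cfg$read_length)
      seg <- truth$cell_paths[list(cl, ch), on = c("cell", "chrom")]
      mid <- starts + cfg$read_length %/% 2L
      origin <- seg$origin[findInterval(mid, seg$start)]
      gam <- splice_gamete_sequence(truth$genome, seg, ch)
      seqs <- substring(gam, starts + 1L, starts + cfg$read_length)
      out[[k]] <- data.table(
        cell = cl, chrom = ch, start = starts,
        end = starts + cfg$read_length, truth_origin = origin, seq = seqs
      )
    }
  }
  reads <- rbindlist(out)
  setorder(reads, cell, chrom, start)
  reads[, read_id := sprintf("%s_r%06d", cell, seq_len(.N)), by = cell]
  setcolorder(reads, c("read_id", "cell", "chrom", "start", "end",
                       "truth_origin", "seq"))
  reads[]
}

# recombinant gamete sequence of one cell on one chromosome: splice hapA/hapB
# segments (haplotypes are colinear, so coordinates carry over)
splice_gamete_sequence <- function(genome, seg, chrom) {
  pieces <- mapply(function(s, e, o) {
    substring(if (o == "A") genome$hapA[[chrom]] else genome$hapB[[chrom]],
              s + 1L, e)
  }, seg$start, seg$end, seg$origin)
  paste0(pieces, collapse = "")
}

#' Run the full gamete-cell simulator
#'
#' Chains [simulate_diploid_genome()], [simulate_meiosis()],
#' [simulate_cell_observations()] and (optionally) [simulate_cell_reads()]
#' into one truth-complete synthetic data set.
#'
#' @param cfg a [sim_config()].
#' @param reads if FALSE, skip read simulation (genotype-level studies).
#' @return list with `config`, `genome`, `cell_paths`, `crossovers`,
#'   `observations` (raw per-cell genotype codes) and `reads` (or NULL).
#' @export
#' @examples
#' sim <- simulate_gametes(sim_config(n_chromosomes = 1, chrom_length = 5e4,
#'                                    n_cells = 8, seed = 42), reads = FALSE)
#' dim(sim$observations$geno)
simulate_gametes <- function(cfg, reads = TRUE) {
  genome <- simulate_diploid_genome(cfg)
  mei <- simulate_meiosis(genome, cfg)
  truth <- list(genome = genome, cell_paths = mei$cell_paths)
  obs <- simulate_cell_observations(truth, cfg)
  rd <- if (reads) simulate_cell_reads(truth, cfg) else NULL
  list(
    config = cfg, genome = genome,
    cell_paths = mei$cell_paths, crossovers = mei$crossovers,
    observations = obs, reads = rd
  )
}
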