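# End-to-end pipeline driver and tabular adapters.

#' Write / read the genotype matrix as TSV
#'
#' Layout: one row per locus (chrom, pos, ref, alt) followed by one column per
#' cell holding 0 (REF), 1 (ALT) or NA (missing).
#'
#' @param gm a `genotype_matrix`.
#' @param path output TSV.
#' @export
write_genotype_matrix_tsv <- function(gm, path) {
  dt <- copy(gm$panel[, .(chrom, pos, ref, alt)])
  for (cl in gm$cells) dt[, (cl) := gm$geno[cl, ]]
  fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix_tsv
#' @param counters optional per-cell counter table (cell, n_called,
#'   n_het_raw, n_low_depth) to restore QC counters on read.
#' @export
read_genotype_matrix_tsv <- function(path, counters = NULL) {
  dt <- fread(path, sep = "\t")
  cells <- setdiff(names(dt), c("chrom", "pos", "ref", "alt"))
  geno <- t(as.matrix(dt[, cells, with = FALSE]))
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(cells, NULL)
  nc <- rowSums(!is.na(geno))
  nh <- setNames(integer(length(cells)), cells)
  nl <- setNames(integer(length(cells)), cells)
  if (!is.null(counters)) {
    counters <- as.data.table(counters)
    m <- match(cells, counters$cell)
    nc <- counters$n_called[m]
    nh <- counters$n_het_raw[m]
    nl <- counters$n_low_depth[m]
  }
  structure(
    list(geno = geno, panel = dt[, .(chrom, pos, ref, alt)], cells = cells,
         n_called = setNames(as.integer(nc), cells),
         n_het_raw = setNames(as.integer(nh), cells),
         n_low_depth = setNames(as.integer(nl), cells)),
    class = "genotype_matrix"
  )
}

#' Write simulator outputs to disk
#'
#' Emits per-cell FASTQ, the SNP panel as a minimal VCF, per-cell VCFs of raw
#' genotype calls, a 6-column placement table (read_id, cell, chrom, start,
#' end, truth_origin; 0-based half-open) and truth TSVs (haplotype FASTA,
#' cell paths, crossovers).
#'
#' @param sim a [simulate_gametes()] result.
#' @param outdir output directory (created).
#' @return invisibly, the named list of paths written.
#' @export
write_sim <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  paths$panel_vcf <- file.path(outdir, "snp_panel.vcf")
  write_panel_vcf(sim$genome$snp_truth, paths$panel_vcf)
  paths$cell_vcfs <- write_cell_vcfs(sim, file.path(outdir, "cell_vcfs"))
  paths$cell_paths <- file.path(outdir, "truth_cell_paths.tsv")
  fwrite(sim$cell_paths, paths$cell_paths, sep = "\t")
  paths$crossovers <- file.path(outdir, "truth_crossovers.tsv")
  fwrite(sim$crossovers, paths$crossovers, sep = "\t")
  paths$snp_truth <- file.path(outdir, "truth_snps.tsv")
  fwrite(sim$genome$snp_truth, paths$snp_truth, sep = "\t")
  for (h in c("hapA", "hapB")) {
    p <- file.path(outdir, paste0("truth_", h, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$genome[[h]]), p)
    paths[[paste0(h, "_fasta")]] <- p
  }
  if (!is.null(sim$reads)) {
    fq_dir <- file.path(outdir, "fastq")
    dir.create(fq_dir, showWarnings = FALSE)
    for (cl in unique(sim$reads$cell)) {
      write_fastq(sim$reads[cell == cl],
                  file.path(fq_dir, paste0(cl, ".fastq.gz")))
    }
    paths$fastq_dir <- fq_dir
    paths$placements <- file.path(outdir, "placements.tsv")
    fwrite(sim$reads[, .(read_id, cell, chrom, start, end, truth_origin)],
           paths$placements, sep = "\t")
  }
  invisible(paths)
}

#' Pipeline configuration
#'
#' All stage parameters of [run_pipeline()] with their defaults; unknown keys
#' are rejected so typos cannot silently fall back to defaults. Every value
#' is echoed into the run report.
#'
#' @param ... overrides of the defaults listed below.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    min_qual = 20, af_lo = 0.3, af_hi = 0.7, indel_dist = 5L,
    min_depth = 5L, het_max = 0.05, miss_lo = 0.30, miss_hi = 0.70,
    epsilon = 0.02, crossover_rate_per_bp = 1e-8, min_block_snps = 5L,
    k_norm = 31L, target_depth = NULL, k_hapmer = 21L,
    normalize = TRUE, evaluate = TRUE, seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown)) {
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, ov)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline on simulated data
#'
#' Chains simulation, SNP filtering, genotype-matrix construction, cell QC,
#' majority-vote phasing, HMM block/crossover calling, block-based read
#' partitioning, k-mer-depth normalization and truth-based evaluation;
#' writes every stage output plus a JSON run report into `outdir`.
#'
#' @param sim_cfg a [sim_config()] describing the synthetic data set.
#' @param params a [pipeline_config()]; `target_depth = NULL` defaults to the
#'   simulator's `mean_depth` (echoed in the report).
#' @param outdir output directory; NULL skips all file output.
#' @param reads simulate and process reads (set FALSE for genotype-only runs).
#' @return a run report list (also serialized to `run_report.json`), with the
#'   in-memory stage results attached under `$stages`.
#' @export
run_pipeline <- function(sim_cfg = sim_config(), params = pipeline_config(),
                         outdir = NULL, reads = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(nm) {
    t <- proc.time()[["elapsed"]]
    timings[[nm]] <<- round(t - t0, 3)
    t0 <<- t
  }
  sim <- simulate_gametes(sim_cfg, reads = reads)
  tick("simulate")

  # SNP filtering operates on the simulator's panel records (QUAL fixed by the
  # cell-VCF writer; pooled allele fraction from the raw observation codes)
  obs <- sim$observations
  af <- colMeans(obs$geno == 1L, na.rm = TRUE)
  af[is.nan(af)] <- NA_real_
  hets <- colMeans(obs$geno == 2L, na.rm = TRUE)
  variants <- data.table(obs$panel[, .(chrom, pos, ref, alt)],
                         qual = 60, alt_fraction = af + 0.5 * hets)
  panel <- filter_snps(variants, indels = NULL, min_qual = params$min_qual,
                       af_range = c(params$af_lo, params$af_hi),
                       indel_dist = params$indel_dist)
  keep_loci <- which(paste(obs$panel$chrom, obs$panel$pos) %in%
                       paste(panel$chrom, panel$pos))
  obs_f <- structure(
    list(geno = obs$geno[, keep_loci, drop = FALSE],
         panel = obs$panel[keep_loci], cells = obs$cells),
    class = "raw_observations"
  )
  gm <- as_genotype_matrix(obs_f)
  tick("filter_and_matrix")

  qc <- qc_cells(gm, het_max = params$het_max, miss_lo = params$miss_lo,
                 miss_hi = params$miss_hi)
  tick("qc")

  consensus <- majority_vote_phase(qc$matrix)
  votes <- collect_link_votes(qc$matrix)
  tick("phase")

  bl <- viterbi_blocks(qc$matrix, consensus, sim$genome$chrom_lengths,
                       epsilon = params$epsilon,
                       crossover_rate_per_bp = params$crossover_rate_per_bp,
                       min_block_snps = params$min_block_snps)
  tick("blocks")

  part <- norm_pools <- eval_out <- NULL
  if (reads) {
    placements <- sim$reads[cell %in% qc$matrix$cells]
    part <- partition_reads(placements, bl$blocks)
    tick("partition")
    if (params$normalize) {
      target <- if (is.null(params$target_depth)) sim_cfg$mean_depth else
        params$target_depth
      pools <- split_pools(part$assignments)
      norm_pools <- list(
        pool_A = normalize_by_kmer_depth(pools$pool_A, k = params$k_norm,
                                         target_depth = target,
                                         seed = substream_seed(params$seed, 7L)),
        pool_B = normalize_by_kmer_depth(pools$pool_B, k = params$k_norm,
                                         target_depth = target,
                                         seed = substream_seed(params$seed, 8L)),
        target_depth = target
      )
      tick("normalize")
    }
  }
  if (params$evaluate) {
    sw <- switch_error(consensus, gm$panel)
    co <- crossover_recovery(bl$crossovers,
                             sim$crossovers[cell %in% qc$matrix$cells],
                             tolerance = sim_cfg$chrom_length)
    eval_out <- list(switch = sw, crossovers = co)
    if (reads && !is.null(part)) {
      hm <- compute_hapmers(sim$genome$hapA, sim$genome$hapB,
                            k = params$k_hapmer)
      pools <- split_pools(part$assignments)
      # per (pool x chromosome) units: phase-set labels are per-chromosome
      # conventions, so cross-chromosome marker sums would cancel
      units <- list()
      for (p in c("pool_A", "pool_B")) {
        for (ch in unique(pools[[p]]$chrom)) {
          units[[paste(p, ch, sep = ".")]] <- pools[[p]][chrom == ch, seq]
        }
      }
      eval_out$ppv <- score_pool(units, hm)
    }
    tick("evaluate")
  }

  report <- list(
    seed = sim_cfg$seed,
    parameters = list(sim = unclass(sim_cfg), pipeline = unclass(params)),
    counts = list(
      loci_in = ncol(obs$geno), loci_kept = nrow(panel),
      cells_in = length(obs$cells), cells_passed = length(qc$matrix$cells),
      phase_sets = length(unique(consensus$phase_set)),
      blocks = nrow(bl$blocks), crossovers_detected = nrow(bl$crossovers),
      reads_simulated = if (reads) nrow(sim$reads) else 0L,
      reads_in = if (!is.null(part)) nrow(part$assignments) else 0L,
      reads_pool_A = if (!is.null(part)) sum(part$assignments$assigned == "A") else NA,
      reads_pool_B = if (!is.null(part)) sum(part$assignments$assigned == "B") else NA,
      reads_unassigned = if (!is.null(part))
        sum(part$assignments$assigned == "unassigned") else NA,
      reads_after_normalization = if (!is.null(norm_pools))
        nrow(norm_pools$pool_A) + nrow(norm_pools$pool_B) else NA
    ),
    evaluation = if (!is.null(eval_out)) list(
      switch_error_rate = eval_out$switch$switch_error_rate,
      hamming_accuracy = eval_out$switch$hamming_accuracy,
      crossover_precision = eval_out$crossovers$precision,
      crossover_recall = eval_out$crossovers$recall,
      aggregate_ppv = if (!is.null(eval_out$ppv))
        eval_out$ppv[pool == "ALL", ppv] else NA
    ) else NULL,
    wall_times_s = as.list(timings)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_sim(sim, file.path(outdir, "sim"))
    write_panel_vcf(panel, file.path(outdir, "panel.filtered.vcf"))
    write_genotype_matrix_tsv(gm, file.path(outdir, "genotype_matrix.tsv"))
    fwrite(qc$report, file.path(outdir, "qc_report.tsv"), sep = "\t")
    jsonlite::write_json(qc$report, file.path(outdir, "qc_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    write_phased_vcf(consensus, file.path(outdir, "haplotypes.phased.vcf"))
    fwrite(as.data.table(consensus), file.path(outdir, "haplotypes.tsv"),
           sep = "\t")
    fwrite(votes$junctions, file.path(outdir, "junction_votes.tsv"),
           sep = "\t")
    fwrite(bl$blocks, file.path(outdir, "blocks.tsv"), sep = "\t")
    fwrite(bl$crossovers, file.path(outdir, "crossovers.tsv"), sep = "\t")
    if (!is.null(part)) {
      fwrite(part$assignments[, .(read_id, cell, chrom, start, end, assigned)],
             file.path(outdir, "read_assignments.tsv"), sep = "\t")
      pools <- split_pools(part$assignments)
      write_fastq(pools$unassigned, file.path(outdir, "unassigned.fastq.gz"))
      if (is.null(norm_pools)) {
        write_fastq(pools$pool_A, file.path(outdir, "pool_A.fastq.gz"))
        write_fastq(pools$pool_B, file.path(outdir, "pool_B.fastq.gz"))
      } else {
        write_fastq(norm_pools$pool_A, file.path(outdir, "pool_A.fastq.gz"))
        write_fastq(norm_pools$pool_B, file.path(outdir, "pool_B.fastq.gz"))
      }
    }
    jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  report$stages <- list(sim = sim, panel = panel, matrix = gm, qc = qc,
                        consensus = consensus, votes = votes, blocks = bl,
                        partition = part, normalized = norm_pools,
                        evaluation = eval_out)
  invisible(report)
}
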