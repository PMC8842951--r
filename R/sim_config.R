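#' Simulation configuration
#'
#' Bundles every knob of the gamete-cell simulator. The defaults describe a
#' desk-scale caricature of a highly heterozygous F1 plant: ~0.2% heterozygous
#' SNP density, a few tens of gamete cells amplified by MDA (hence strongly
#' uneven coverage and ~40% missing genotype calls per cell), and on average
#' two crossovers per chromosome per gamete.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bases (all chromosomes equal).
#' @param snp_rate per-base probability that a position is a heterozygous SNP
#'   (0.002 emulates ~2% SNP heterozygosity genomes at the SNP level).
#' @param n_cells number of gamete cells.
#' @param crossover_lambda expected crossovers per chromosome per gamete
#'   (Poisson; no interference, no obligate crossover).
#' @param genotype_error probability that a non-missing observed genotype is
#'   flipped.
#' @param missing_rate_target expected fraction of loci missing per cell;
#'   realized by dropping the amplification windows whose MDA factor falls
#'   below this quantile.
#' @param het_call_rate fraction of raw calls reported heterozygous despite
#'   the cell being haploid (contamination/ambient artifact; exercises QC).
#' @param mda_window bases per amplification window.
#' @param mda_gamma_shape shape of the per-window Gamma amplification factor
#'   (mean fixed at 1; smaller shape = more uneven coverage).
#' @param read_length read length in bases (reads are error-free).
#' @param mean_depth mean fold-coverage per cell before MDA distortion.
#' @param seed integer seed; fully determines all simulator outputs.
#'
#' @return a `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, chrom_length = 5e4, seed = 1)
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 1e6,
                       snp_rate = 0.002,
                       n_cells = 30L,
                       crossover_lambda = 2,
                       genotype_error = 0.01,
                       missing_rate_target = 0.40,
                       het_call_rate = 0.01,
                       mda_window = 10000L,
                       mda_gamma_shape = 0.8,
                       read_length = 150L,
                       mean_depth = 20,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    snp_rate = snp_rate,
    n_cells = as.integer(n_cells),
    crossover_lambda = crossover_lambda,
    genotype_error = genotype_error,
    missing_rate_target = missing_rate_target,
    het_call_rate = het_call_rate,
    mda_window = as.integer(mda_window),
    mda_gamma_shape = mda_gamma_shape,
    read_length = as.integer(read_length),
    mean_depth = mean_depth,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1L, cfg$chrom_length >= 1L, cfg$n_cells >= 1L,
    cfg$mda_window >= 1L, cfg$read_length >= 1L,
    cfg$mda_gamma_shape > 0, cfg$mean_depth >= 0, cfg$crossover_lambda >= 0
  )
  for (p in c("snp_rate", "genotype_error", "missing_rate_target",
              "het_call_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(sprintf("sim_config: '%s' must be in [0, 1], got %g", p, cfg[[p]]))
    }
  }
  if (cfg$snp_rate > 0 && cfg$snp_rate * cfg$chrom_length < 2) {
    stop("sim_config: expected fewer than 2 SNPs per chromosome ",
         "(snp_rate * chrom_length < 2); increase chrom_length or snp_rate")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chromosomes, "chromosome(s) x",
      x$chrom_length, "bp,", x$n_cells, "cells\n")
  cat("  snp_rate =", x$snp_rate, " crossover_lambda =", x$crossover_lambda,
      "\n  genotype_error =", x$genotype_error,
      " missing_rate_target =", x$missing_rate_target,
      " het_call_rate =", x$het_call_rate,
      "\n  mda_window =", x$mda_window,
      " mda_gamma_shape =", x$mda_gamma_shape,
      "\n  read_length =", x$read_length, " mean_depth =", x$mean_depth,
      " seed =", x$seed, "\n")
  invisible(x)
}

# Independent deterministic RNG substreams per simulator stage, all derived
# from cfg$seed (kept < 2^31 - 1). Stages stay individually reproducible and
# share the MDA factor stream.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 16807) %% 2147483629)
}
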