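# Simulator: genome, meiosis, observations, reads.

test_that("simulate_diploid_genome plants biallelic SNPs where it says", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 1e5, snp_rate = 0.002,
                    seed = 1L)
  g <- simulate_diploid_genome(cfg)
  snp <- g$snp_truth
  # count within the central 99% binomial interval (oracle: qbinom)
  expect_gte(nrow(snp), qbinom(0.005, 1e5, 0.002))
  expect_lte(nrow(snp), qbinom(0.995, 1e5, 0.002))
  expect_false(is.unsorted(snp$pos, strictly = TRUE))
  expect_true(all(snp$ref != snp$alt))
  # haplotypes differ exactly at the SNP loci
  a <- strsplit(g$hapA[[1]], "")[[1]]
  b <- strsplit(g$hapB[[1]], "")[[1]]
  expect_identical(which(a != b), snp$pos)
  expect_identical(a[snp$pos], snp$ref)
  expect_identical(b[snp$pos], snp$alt)
})

test_that("snp_rate = 0 gives identical haplotypes and an empty panel", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 1e4, snp_rate = 0,
                    seed = 3L)
  g <- simulate_diploid_genome(cfg)
  expect_identical(g$hapA, g$hapB)
  expect_equal(nrow(g$snp_truth), 0L)
})

test_that("degenerate configs are rejected", {
  expect_error(sim_config(chrom_length = 500, snp_rate = 0.002),
               "fewer than 2 SNPs")
  expect_error(sim_config(genotype_error = 1.5), "must be in")
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 2e3, snp_rate = 0.01,
                    read_length = 5000L, seed = 1L)
  g <- simulate_diploid_genome(cfg)
  mei <- simulate_meiosis(g, cfg)
  expect_error(
    simulate_cell_reads(list(genome = g, cell_paths = mei$cell_paths), cfg),
    "read_length"
  )
})

test_that("the simulator is byte-identical under a fixed seed", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 2e4, n_cells = 5L,
                    read_length = 80L, mean_depth = 3, seed = 7L)
  s1 <- simulate_gametes(cfg)
  s2 <- simulate_gametes(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$cell_paths, s2$cell_paths)
  expect_identical(s1$observations$geno, s2$observations$geno)
  expect_identical(s1$reads, s2$reads)
})

test_that("meiosis: Poisson crossover counts, tiling, alternation", {
  cfg <- sim_config(n_chromosomes = 10L, chrom_length = 1e4, snp_rate = 0.01,
                    n_cells = 100L, crossover_lambda = 2, seed = 5L)
  g <- simulate_diploid_genome(cfg)
  mei <- simulate_meiosis(g, cfg)
  paths <- mei$cell_paths
  # segments tile each chromosome without gaps or overlap, origins alternate
  paths[, {
    expect_equal(start[1], 0L)
    expect_equal(end[.N], 1e4L)
    if (.N > 1) {
      expect_identical(start[-1], end[-.N])
      expect_true(all(origin[-1] != origin[-.N]))
    }
    NULL
  }, by = .(cell, chrom)]
  # crossovers per cell-chromosome = segments - 1
  nseg <- paths[, .N, by = .(cell, chrom)]
  nco <- mei$crossovers[, .N, by = .(cell, chrom)]
  merged <- merge(nseg, nco, by = c("cell", "chrom"), all.x = TRUE)
  merged[is.na(N.y), N.y := 0L]
  expect_identical(merged$N.x - 1L, merged$N.y)
  # empirical mean within 3 Poisson standard errors (1000 cell-chromosomes)
  n_cc <- nrow(nseg)
  expect_equal(n_cc, 1000L)
  se <- sqrt(2 / n_cc)
  expect_lt(abs(mean(merged$N.y) - 2), 3 * se)
})

test_that("crossover_lambda = 0 gives single full-length segments", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 1e4, snp_rate = 0.01,
                    n_cells = 12L, crossover_lambda = 0, seed = 2L)
  g <- simulate_diploid_genome(cfg)
  mei <- simulate_meiosis(g, cfg)
  expect_equal(nrow(mei$cell_paths), 12L)
  expect_true(all(mei$cell_paths$start == 0L))
  expect_true(all(mei$cell_paths$end == 1e4L))
  expect_equal(nrow(mei$crossovers), 0L)
})

test_that("error-free, dropout-free observations are the projection of cell paths", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 2e4, snp_rate = 0.005,
                    n_cells = 8L, genotype_error = 0, missing_rate_target = 0,
                    het_call_rate = 0, seed = 9L)
  sim <- simulate_gametes(cfg, reads = FALSE)
  geno <- sim$observations$geno
  expect_false(anyNA(geno))
  snp <- sim$genome$snp_truth
  for (cl in rownames(geno)) {
    seg <- sim$cell_paths[cell == cl]
    expected <- vapply(seq_len(nrow(snp)), function(k) {
      s <- seg[chrom == snp$chrom[k] & start < snp$pos[k] & end >= snp$pos[k]]
      if (s$origin == "A") 0L else 1L
    }, integer(1))
    expect_identical(unname(geno[cl, ]), expected)
  }
})

test_that("missing rate lands near its target for most cells", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 2e5, snp_rate = 0.002,
                    n_cells = 30L, missing_rate_target = 0.4, seed = 13L)
  sim <- simulate_gametes(cfg, reads = FALSE)
  miss <- rowMeans(is.na(sim$observations$geno))
  expect_gte(mean(miss >= 0.30 & miss <= 0.50), 0.9)
})

test_that("reads: placement bounds, origin truth, expected volume", {
  cfg <- read_world_cfg(seed = 21L)
  sim <- simulate_gametes(cfg)
  rd <- sim$reads
  expect_true(all(rd$start >= 0L))
  expect_true(all(rd$end <= cfg$chrom_length))
  expect_true(all(nchar(rd$seq) == cfg$read_length))
  # total bases within 10% of n_cells * n_chrom * L * depth
  expected <- cfg$n_cells * cfg$n_chromosomes * cfg$chrom_length * cfg$mean_depth
  expect_lt(abs(sum(nchar(rd$seq)) - expected) / expected, 0.10)
  # reads fully inside a truth segment carry that segment's origin, and their
  # sequence equals the corresponding haplotype substring (error-free reads)
  seg <- sim$cell_paths
  sub <- rd[sample(.N, 200)]
  for (k in seq_len(nrow(sub))) {
    s <- seg[cell == sub$cell[k] & chrom == sub$chrom[k] &
               start <= sub$start[k] & end >= sub$end[k]]
    if (nrow(s) == 1L) {
      expect_identical(sub$truth_origin[k], s$origin)
      hap <- if (s$origin == "A") sim$genome$hapA else sim$genome$hapB
      expect_identical(
        sub$seq[k],
        substring(hap[[sub$chrom[k]]], sub$start[k] + 1L, sub$end[k])
      )
    }
  }
})

test_that("weak MDA bias yields more even window depth than strong bias", {
  base <- read_world_cfg(seed = 31L)
  strong <- simulate_gametes(base)
  weak_cfg <- read_world_cfg(seed = 31L, mda_gamma_shape = 100)
  weak <- simulate_gametes(weak_cfg)
  win_cv <- function(rd, w = 1e4) {
    d <- rd[, .N, by = .(chrom, win = start %/% w)]
    sd(d$N) / mean(d$N)
  }
  expect_lt(win_cv(weak$reads), win_cv(strong$reads))
})
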