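# Hapmers, PPV, switch error, crossover recovery.

test_that("compute_hapmers: identical haplotypes, single SNP, spaced SNPs", {
  expect_error(compute_hapmers("ACGT", "ACGT", k = 4L), "odd")
  set.seed(97)
  s <- rand_dna(100)
  hm0 <- compute_hapmers(s, s, k = 5L)
  expect_length(hm0$hap1_only, 0L)
  expect_length(hm0$hap2_only, 0L)

  # one SNP: each hapmer set has at most k members (k-mers crossing the SNP),
  # verified against direct enumeration
  set.seed(101)
  k <- 7L
  a <- rand_dna(60)
  b <- a
  substring(b, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                  substring(a, 30, 30))[1]
  hm <- compute_hapmers(a, b, k)
  expect_lte(length(hm$hap1_only), k)
  enum_only <- function(x, y) {
    kx <- unique(vapply(1:(nchar(x) - k + 1), function(i) {
      km <- substring(x, i, i + k - 1); min(km, revcomp(km))
    }, character(1)))
    ky <- unique(vapply(1:(nchar(y) - k + 1), function(i) {
      km <- substring(y, i, i + k - 1); min(km, revcomp(km))
    }, character(1)))
    setdiff(kx, ky)
  }
  expect_setequal(hm$hap1_only, enum_only(a, b))
  expect_setequal(hm$hap2_only, enum_only(b, a))

  # symmetry under exchanging inputs
  hm_sw <- compute_hapmers(b, a, k)
  expect_setequal(hm_sw$hap1_only, hm$hap2_only)
  expect_setequal(hm_sw$hap2_only, hm$hap1_only)
})

test_that("simulator truth with well-separated SNPs gives s*k hapmers per set", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 1e5, snp_rate = 2e-4,
                    seed = 103L)
  g <- simulate_diploid_genome(cfg)
  k <- 21L
  gaps <- diff(c(0L, g$snp_truth$pos, cfg$chrom_length))
  expect_gt(min(gaps), k)  # precondition of the combinatorial count
  hm <- compute_hapmers(g$hapA, g$hapB, k)
  s <- nrow(g$snp_truth)
  expect_equal(length(hm$hap1_only), s * k)
  expect_equal(length(hm$hap2_only), s * k)
})

test_that("score_pool: purity, chimera, label-swap invariance, aggregation", {
  set.seed(107)
  a <- rand_dna(400)
  b <- a
  for (p in seq(20, 380, by = 40)) {
    substring(b, p, p) <- setdiff(c("A", "C", "G", "T"), substring(a, p, p))[1]
  }
  hm <- compute_hapmers(a, b, k = 11L)
  pure <- score_pool(list(pA = a), hm)
  expect_equal(pure[pool == "pA", ppv], 1.0)
  # half-A half-B chimera scores about 0.5 and is flagged
  chim <- paste0(substring(a, 1, 200), substring(b, 201, 400))
  sc <- score_pool(list(ch = chim), hm)
  expect_lt(abs(sc[pool == "ch", ppv] - 0.5), 0.1)
  expect_true(sc[pool == "ch", chimeric])
  # swapping hapmer labels leaves ppv unchanged
  hm_sw <- structure(list(k = hm$k, hap1_only = hm$hap2_only,
                          hap2_only = hm$hap1_only), class = "hapmer_sets")
  expect_equal(score_pool(list(ch = chim), hm_sw)$ppv, sc$ppv)
  # aggregate equals marker-count-weighted combination
  two <- score_pool(list(x = a, y = b), hm)
  agg <- two[pool == "ALL"]
  expect_equal(agg$n_hap1_markers, sum(two[pool != "ALL", n_hap1_markers]))
  expect_equal(agg$n_hap2_markers, sum(two[pool != "ALL", n_hap2_markers]))
  # no markers -> NA ppv
  none <- score_pool(list(z = rand_dna(9)), compute_hapmers(a, a, 11L))
  expect_true(all(is.na(none$ppv)))
})

test_that("switch_error: exact, flipped-segment, locus mismatch", {
  # a non-recombinant error-free cell: consensus equals the truth haplotypes
  gm <- make_gm(rep(0L, 6L))
  cons <- majority_vote_phase(gm)
  truth <- gm$panel
  sw0 <- switch_error(cons, truth)
  expect_equal(sw0$switch_error_rate, 0)
  expect_equal(sw0$hamming_accuracy, 1)

  # flip an internal segment of the consensus: exactly 2 switches (entry/exit)
  flipped <- data.table::copy(as.data.table(cons))
  seg <- 3:4
  tmp <- flipped$hapA[seg]
  flipped$hapA[seg] <- flipped$hapB[seg]
  flipped$hapB[seg] <- tmp
  flipped$hapA_is_ref[seg] <- !flipped$hapA_is_ref[seg]
  class(flipped) <- class(cons)
  sw2 <- switch_error(flipped, truth)
  expect_equal(sw2$n_switches, 2L)
  expect_equal(sw2$switch_error_rate, 2 / 5)

  bad <- data.table::copy(truth)[, pos := pos + 1L]
  expect_error(switch_error(cons, bad), "differ")
})

test_that("crossover_recovery: perfect, empty, and tolerance matching", {
  det <- data.table::data.table(cell = "c1", chrom = "chr1",
                                left_snp_pos = c(900L, 4900L),
                                right_snp_pos = c(1100L, 5100L),
                                midpoint = c(1000, 5000))
  tru <- data.table::data.table(cell = "c1", chrom = "chr1",
                                pos = c(1000L, 5000L))
  r <- crossover_recovery(det, tru, tolerance = 100)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$frac_in_interval, 1)

  r0 <- crossover_recovery(det[0], tru, tolerance = 100)
  expect_equal(r0$recall, 0)
  expect_true(is.na(r0$precision))

  # one detection cannot match two truth events (one-to-one matching)
  r1 <- crossover_recovery(det[1], tru, tolerance = 1e6)
  expect_equal(r1$n_matched, 1L)
  expect_equal(r1$recall, 0.5)
  # a detection in the wrong cell never matches
  det_wrong <- data.table::copy(det)[, cell := "c2"]
  r2 <- crossover_recovery(det_wrong, tru, tolerance = 1e6)
  expect_equal(r2$n_matched, 0L)
})
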