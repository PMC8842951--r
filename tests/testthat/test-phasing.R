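# Majority-vote consensus phasing and its exhaustive oracle.

test_that("collect_link_votes emits consecutive non-missing edges", {
  gm <- make_gm(matrix(c(1L, 1L, NA, 0L), nrow = 1L))
  lv <- collect_link_votes(gm)
  # [ALT, ALT] adjacent -> cis edge; [ALT, MISSING, REF] -> span-2 trans edge
  expect_equal(nrow(lv$edges), 2L)
  e12 <- lv$edges[i == 1L & j == 2L]
  expect_true(e12$cis)
  expect_equal(e12$span, 1L)
  e24 <- lv$edges[i == 2L & j == 4L]
  expect_false(e24$cis)
  expect_equal(e24$span, 2L)
  # junctions (2,3) and (3,4) have no direct vote
  expect_identical(lv$junctions$n_informative, c(1L, 0L, 0L))
})

test_that("error-free cells all vote the same way at crossover-free junctions", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 2e4, snp_rate = 0.01,
                    n_cells = 5L, genotype_error = 0, het_call_rate = 0,
                    missing_rate_target = 0, seed = 29L)
  sim <- simulate_gametes(cfg, reads = FALSE)
  gm <- as_genotype_matrix(sim$observations)
  lv <- collect_link_votes(gm)
  pos <- gm$panel$pos
  co <- sim$crossovers$pos
  no_co_between <- vapply(seq_len(nrow(lv$junctions)), function(r) {
    !any(co > lv$junctions$pos_i[r] & co <= lv$junctions$pos_j[r])
  }, logical(1))
  j <- lv$junctions[no_co_between]
  expect_true(all(j$cis_votes == 0L | j$trans_votes == 0L))
})

test_that("a single complete cell defines the whole haplotype, one phase set", {
  g <- c(0L, 1L, 1L, 0L, 1L)
  gm <- make_gm(g)
  cons <- majority_vote_phase(gm)
  expect_equal(length(unique(cons$phase_set)), 1L)
  # anchoring: hapA at the phase-set start is the REF allele; the rest follows
  # the cell's genotype vector relative to its first locus
  expected_hapA_is_ref <- g == g[1L]
  expect_identical(cons$hapA_is_ref, expected_hapA_is_ref)
  expect_true(all(cons$hapA != cons$hapB))
})

test_that("ties and uncovered junctions open new phase sets", {
  # two cells disagree on the (1,2) junction orientation: tie
  gm <- make_gm(rbind(c(0L, 0L), c(0L, 1L)))
  cons <- majority_vote_phase(gm)
  expect_equal(cons$phase_set, c(1L, 2L))
  expect_equal(cons$margin, c(0L, 0L))

  # junction with zero informative cells splits the phase set
  gm2 <- make_gm(rbind(c(0L, 0L, NA, NA), c(NA, NA, 1L, 1L)))
  cons2 <- majority_vote_phase(gm2)
  expect_equal(cons2$phase_set, c(1L, 1L, 2L, 2L))
})

test_that("label-swap symmetry: flipping all genotypes swaps the consensus", {
  set.seed(41)
  gm <- random_instance(10L, 6L, error = 0.05, missing = 0.3)
  flipped <- gm
  flipped$geno <- 1L - gm$geno
  c1 <- majority_vote_phase(gm)
  c2 <- majority_vote_phase(flipped)
  expect_identical(c1$phase_set, c2$phase_set)
  expect_identical(c1$margin, c2$margin)
  # within each phase set, orientations are complementary except at the
  # anchor convention: hapA(anchor)=REF in both, so hapA vectors relate by
  # locus-wise equality of relative orientation
  rel1 <- c1$hapA_is_ref == c1$hapA_is_ref[match(c1$phase_set, c1$phase_set)]
  rel2 <- c2$hapA_is_ref == c2$hapA_is_ref[match(c2$phase_set, c2$phase_set)]
  expect_identical(rel1, rel2)
})

test_that("3 cells x 4 loci with one crossover matches the exhaustive oracle", {
  # cell 3 recombines between loci 2 and 3; no errors
  geno <- rbind(c(0L, 1L, 0L, 1L),
                c(0L, 1L, 0L, 1L),
                c(0L, 1L, 1L, 0L))
  gm <- make_gm(geno)
  cons <- majority_vote_phase(gm)
  oracle <- exhaustive_phase_oracle(gm)
  got <- as.integer(!cons$hapA_is_ref)
  expect_true(any(apply(oracle$optima, 1L, function(o) {
    all(o == got) || all(o == 1L - got)
  })))
  expect_equal(length(unique(cons$phase_set)), 1L)
})

test_that("exact recovery on clean simulated data", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 1e5, snp_rate = 0.002,
                    n_cells = 10L, genotype_error = 0, het_call_rate = 0,
                    missing_rate_target = 0, seed = 43L)
  sim <- simulate_gametes(cfg, reads = FALSE)
  gm <- as_genotype_matrix(sim$observations)
  cons <- majority_vote_phase(gm)
  sw <- switch_error(cons, gm$panel)
  expect_equal(sw$switch_error_rate, 0)
  expect_equal(sw$hamming_accuracy, 1)
})

test_that("oracle guards its combinatorial limit and trivial cases", {
  gm <- make_gm(matrix(0L, 2L, 13L))
  expect_error(exhaustive_phase_oracle(gm), "12 loci")
  gm1 <- make_gm(matrix(c(0L, 1L), 2L, 1L))
  expect_equal(exhaustive_phase_oracle(gm1)$best, 0L)
})

test_that("switch-error rate degrades gracefully with genotype error", {
  rates <- c(0, 0.05, 0.15)
  mean_sw <- vapply(rates, function(e) {
    sw <- vapply(1:5, function(s) {
      cfg <- sim_config(n_chromosomes = 1L, chrom_length = 5e4,
                        snp_rate = 0.004, n_cells = 8L, genotype_error = e,
                        het_call_rate = 0, missing_rate_target = 0.2,
                        seed = 100L + s)
      sim <- simulate_gametes(cfg, reads = FALSE)
      gm <- as_genotype_matrix(sim$observations)
      switch_error(majority_vote_phase(gm), gm$panel)$switch_error_rate
    }, numeric(1))
    mean(sw)
  }, numeric(1))
  expect_true(all(diff(mean_sw) >= -1e-9))
})
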