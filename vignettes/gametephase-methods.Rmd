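---
title: "Phasing diploid genomes with single gamete cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing diploid genomes with single gamete cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gametephase)
library(data.table)
```

## The problem

A diploid individual carries two haplotypes per chromosome. Short- and
long-read assemblers can phase the two locally, but long homozygous stretches
break the phase and produce haplotype switches; chromosome-scale phasing needs
long-range evidence. Gamete cells supply it for free: each gamete is haploid,
so every cell is one *recombinant* haplotype of the individual, observed end
to end. With a few tens of gamete cells, every pair of adjacent heterozygous
SNPs is covered by many cells, most of which carry a parental (non-recombinant)
allele combination — so a simple majority vote per junction recovers the two
parental haplotypes, a crossover being a minority event at any given junction.

`gametephase` implements the computational chain from per-cell SNP calls to
haplotype-partitioned, coverage-normalized read pools ready for a
trio-binning-style assembler, plus a simulator and scoring functions so the
whole chain is verifiable at desk scale.

## Data model and conventions

* **Genotype codes**: per cell and SNP locus, `0` (REF allele), `1` (ALT),
  `NA` (missing). Raw observations may additionally be heterozygous —
  impossible in a haploid cell, hence treated as an artifact (demoted to
  missing, counted for QC).
* **Coordinates**: SNP positions are 1-based (VCF convention); all intervals
  (haplotype blocks, read placements, truth segments) are 0-based half-open.
* **Phase sets**: a maximal run of loci whose relative phase is jointly
  determined. Labels A/B are conventions *per phase set* (anchored so
  haplotype A carries the REF allele at the first locus); every evaluation is
  therefore swap-aware.

## Stage 1 — SNP and cell QC

Variant records are reduced to a high-confidence biallelic panel: quality
$\ge 20$, pooled alternate-allele fraction in $[0.3, 0.7]$ (a true
heterozygous site sampled across haploid cells should be near 0.5), and at
least 5 bp from the nearest InDel boundary (strictly closer records are
removed; a SNP exactly 5 bp away is kept — comparators follow the printed
thresholds, inclusive at `>=`/`between`, strict at `<`/`>`). Per cell, calls
with supporting depth below 5 become missing. Cells are excluded when their
raw heterozygous-call rate exceeds 5% (contamination signature) or their
missing rate falls outside [30%, 70%] — a single MDA-amplified haploid cell
with too few missing calls is suspect (doublet/contamination), one with too
many is uninformative.

The pooled allele fraction uses allelic depths summed across cells when
available, else the mean of genotype calls; whether the source data computes
it per cell or pooled is not observable from the inputs, so pooled is the
default and both thresholds stay configurable.

## Stage 2 — consensus phasing by majority vote

Every pair of *consecutive non-missing* loci in one cell is a linkage edge:
cis (equal codes) or trans. Edges between panel-adjacent loci form the
per-junction support counts; longer-span edges (the cell is missing the loci
between) still vote but never fabricate evidence at the junctions they skip.

Finding the orientation assignment that satisfies the most edges is an Ising
ground-state / MAX-CUT-type problem and NP-hard once edges span arbitrary
distances, so the solver is layered:

1. **Greedy chaining** left to right; each locus takes the majority vote of
   edges arriving from already-phased loci.
2. **Cleaning** over the whole chromosome: while any junction has a negative
   net crossing vote (satisfied minus violated edges spanning it), flip the
   suffix to its right; likewise flip any single locus with negative net
   agreement. Each flip strictly increases the satisfied-vote count, so the
   pass terminates. This repairs greedy mistakes made on weak left-side
   evidence using the evidence to the right.
3. **Exact refinement** by depth-first branch and bound for chromosomes of at
   most `exact_limit = 16` loci (where greedy is most fallible and
   exhaustive search is affordable). The incumbent starts at the cleaned
   greedy solution and is replaced only by strictly better assignments, so
   ties never change the answer.

Phase-set breaks are then *derived* from the converged solution: a break at
every junction whose net crossing vote is zero — either no informative cell
or an exact tie. A tie is never guessed; a wrong guess would propagate switch
errors over the rest of the chromosome. The reported `margin` per junction is
that converged net crossing vote.

This layering is this package's own design. A purely greedy chain (with or
without local search) provably disagrees with the global maximum-agreement
assignment at a small fraction (~0.5% in our adversarial benchmarks) of
junctions with nonzero margin; deriving breaks after cleaning, rather than
freezing them during the greedy pass, is also what makes the implementation
meet its oracle-equivalence test, because assignment-time breaks discard
cross-break evidence that a global optimizer uses.

## Stage 3 — per-cell blocks and crossovers (HMM)

Each QC-passing cell is compared with the consensus: at every non-missing
locus it matches haplotype A or B (mutually exclusive by complementarity). A
two-state HMM over these match calls is decoded by Viterbi:

* **Emission**: match with probability $1-\varepsilon$, mismatch
  $\varepsilon$; default $\varepsilon = 0.02$, deliberately above the
  simulator's 1% genotype error so isolated miscalls are absorbed rather than
  called as crossover pairs.
* **Transition**: switch probability between loci at distance $d$ bp is
  $\tau(d) = 1 - e^{-rd}$ with $r = 10^{-8}$ per bp ($\approx$ 1 cM/Mb), so
  SNP deserts do not inflate per-junction crossover probability.
* **Short-run absorption**: state runs shorter than `min_block_snps = 5` are
  dropped and the remaining loci re-decoded until stable, suppressing
  MDA-artifact micro-blocks. Segments with fewer than 5 informative loci in
  total keep a single majority-state block.

Block boundaries sit at the midpoint between the flanking informative loci of
adjacent blocks — the true breakpoint is unidentifiable inside that interval,
and the crossover record keeps the full flanking interval. Chromosome ends
extend to the sequence ends, so one cell's blocks always tile the chromosome.
Phase-set boundaries force block breaks without emitting a crossover, because
haplotype labels are not comparable across phase sets.

## Stage 4 — read partitioning and k-mer-depth normalization

A read is assigned to a parental pool only when its mapped interval is fully
contained in one haplotype block *of its own cell*; boundary-straddling and
gap reads go to `unassigned`, and discordant mate pairs are unassigned while
a half-assigned pair inherits the assigned mate's origin. Containment rather
than majority-overlap is deliberate: boundary reads are exactly the ones
whose wrong-haplotype k-mers would poison downstream trio-binning, and the
pipeline can afford to discard them. Block-level (not SNP-level) assignment
is the core robustness idea: single false SNP calls cannot flip a read's
pool.

Pools are merged across cells and then normalized by k-mer depth, two-pass:
pass 1 counts canonical k-mers (odd $k = 31$; canonical = lexicographic
minimum of a k-mer and its reverse complement) exactly and in memory; pass 2
retains each read with probability $\min(1, t/m)$ where $m$ is the read's
*median* k-mer count (median resists repeat-induced outliers) and $t$ the
target depth. Reads at or below target are always kept, so normalization only
removes reads from over-amplified regions and its output is always a subset
of its input. Retention draws are seeded, so the retained set is
reproducible. The target depth has no silent default in file-driven runs; the
simulated demo uses the simulator's `mean_depth`, echoed in the run report.

## Evaluation

* **Hapmers**: canonical k-mers ($k = 21$, the usual genome-survey size)
  occurring in exactly one truth haplotype.
* **PPV** per pool/contig: dominant-haplotype marker count over total, in
  $[0.5, 1]$, label-swap invariant. The aggregate is the marker-count-weighted
  mean of per-pool PPVs — per-contig-style aggregation; a global marker sum
  would cancel across chromosomes whose phase-set labels are independent
  conventions.
* **Switch error / Hamming accuracy**: per phase set under the better global
  label; switch errors count adjacent phased pairs whose relative orientation
  disagrees with truth.
* **Crossover recovery**: greedy one-to-one matching of detected events to
  truth breakpoints per cell and chromosome, with localization quantiles and
  the fraction of matches whose truth breakpoint lies inside the detected
  flanking interval.

## The simulator: what it emulates, and what it does not

The stated world (defaults of `sim_config()`): 2 chromosomes of 1 Mb, 0.2%
per-base heterozygous SNP density (the SNP-level face of a ~2% heterozygosity
F1 hybrid), 30 gamete cells, Poisson(2) crossovers per chromosome with
uniform positions, 1% genotype error, 1% heterozygous-in-haploid calls, 40%
target missingness, and MDA coverage bias as a per-(cell, window) Gamma
multiplicative factor (10 kb windows, shape 0.8, mean 1). Missingness is
realized by dropping each cell's windows below the Gamma factor quantile
matching the target, so dropout and read depth are driven by the same factors
— the mechanism MDA chemistry implies. Reads are error-free at fixed length;
genotype error is injected at the genotype level instead, because the
pipeline consumes genotypes, not base calls.

Deliberate simplifications: no crossover interference and no obligate
crossover (real tetrads show interference); no tetrad structure (cells are
independent gametes); no sequencing base errors; no chimeric or doublet
cells beyond the injected heterozygous-call rate. A green test on this world
therefore establishes algorithmic correctness under the stated noise model,
not robustness to every artifact of real MDA libraries.

Read-level tests run on a proportionally scaled world (100 kb chromosomes
with per-base SNP and crossover densities matching the default world, 20
cells at 6-fold depth): read volume scales with genome size while the tested
properties (conservation, purity, PPV, coverage evenness) are densities, so
shrinking length — not density — keeps them meaningful within a single-CPU
test budget.

## Numerical and degenerate-input choices

* Identical seeds give byte-identical outputs everywhere; all randomness
  derives from explicit integer seeds (per-stage substreams below $2^{31}$).
* Viterbi runs in log space; decode ties are broken toward staying in the
  current state, and equivalence with brute force is asserted on path
  probability (ties may have several best paths).
* $\tau(d)$ is clamped to $[10^{-12}, 1 - 10^{-12}]$; $\varepsilon \ge 0.5$
  is rejected.
* Even k is rejected for all k-mer operations (canonicalization would be
  ambiguous for palindromes).
* A chromosome with a single locus phases as a single-locus phase set with a
  warning; an all-cells-fail QC outcome is an error that names the thresholds.
* Multi-allelic records are silently excluded (caller behavior), while
  unsorted variant input is an error (it indicates a broken upstream sort).

## Known limitations

* Gene conversions are invisible: they flip isolated loci and are absorbed by
  design (`min_block_snps`).
* Two true crossovers closer than the informative-locus spacing times
  `min_block_snps` cancel and are undetectable; at the default densities this
  is rare, but it bounds recall below 1 in principle.
* The consensus is exact only for tiny chromosomes; at scale it is a local
  optimum with non-negative junction margins, which the oracle-equivalence
  tests show is indistinguishable from the optimum at decisively supported
  junctions.
* Exact in-memory k-mer sets are desk-scale tools; real genomes need
  disk-backed counters (meryl, KMC) behind the same interfaces.
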