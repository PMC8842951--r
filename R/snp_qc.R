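# SNP-level filtering and cell-level QC.
#
# Haploid gamete cells should yield (almost) only homozygous SNP calls; an
# elevated heterozygous-call rate flags contamination, and extreme missing
# rates flag failed amplification or cross-cell contamination. Thresholds
# default to: quality >= 20, pooled alternate-allele fraction in [0.3, 0.7],
# no InDel within 5 bp, per-cell depth >= 5, het rate <= 5%, missing rate in
# [30%, 70%].

#' Filter SNPs to a high-confidence biallelic panel
#'
#' Keeps biallelic SNPs with quality at or above `min_qual`, pooled
#' alternate-allele fraction inside `af_range` (inclusive), and distance of at
#' least `indel_dist` bases from the nearest InDel boundary (strictly closer
#' records are removed). Multi-allelic or non-SNP records are silently
#' excluded, mirroring variant-caller practice.
#'
#' @param variants data.table with chrom, pos, ref, alt, qual and
#'   alt_fraction columns, sorted by (chrom, pos). Records with multi-base or
#'   comma-separated alleles are treated as non-SNPs and dropped.
#' @param indels optional data.table of InDel records (chrom, pos, ref, alt);
#'   proximity is measured to the closest start or end of any InDel.
#' @param min_qual phred-scaled quality threshold (inclusive).
#' @param af_range inclusive pooled alternate-allele fraction window.
#' @param indel_dist SNPs strictly closer than this many bases to an InDel
#'   boundary are excluded (a SNP exactly `indel_dist` away is kept).
#' @return the filtered SNP panel, sorted by (chrom, pos).
#' @export
filter_snps <- function(variants, indels = NULL, min_qual = 20,
                        af_range = c(0.3, 0.7), indel_dist = 5L) {
  variants <- as.data.table(variants)
  req <- c("chrom", "pos", "ref", "alt", "qual", "alt_fraction")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants lack column(s): ", paste(miss, collapse = ", "))
  if (is.unsorted(order(variants$chrom, variants$pos))) {
    stop("variant records must be sorted by (chrom, pos)")
  }
  is_snp <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    !grepl(",", variants$alt, fixed = TRUE) & variants$ref != variants$alt
  keep <- is_snp &
    !is.na(variants$qual) & variants$qual >= min_qual &
    !is.na(variants$alt_fraction) &
    variants$alt_fraction >= af_range[1L] &
    variants$alt_fraction <= af_range[2L]
  panel <- variants[keep]
  if (!is.null(indels) && nrow(as.data.table(indels))) {
    indels <- as.data.table(indels)
    # InDel footprint boundaries on the reference: [pos, pos + nchar(ref) - 1]
    bnd <- indels[, .(b = c(pos, pos + nchar(ref) - 1L)), by = chrom]
    panel <- panel[, {
      ib <- sort(bnd[chrom == .BY$chrom, b])
      if (!length(ib)) .SD else {
        lo <- findInterval(pos, ib)
        d_left <- ifelse(lo >= 1L, pos - ib[pmax(lo, 1L)], Inf)
        d_right <- ifelse(lo < length(ib), ib[pmin(lo + 1L, length(ib))] - pos,
                          Inf)
        .SD[pmin(d_left, d_right) >= indel_dist]
      }
    }, by = chrom][, c("chrom", setdiff(names(panel), "chrom")), with = FALSE]
  }
  setorder(panel, chrom, pos)
  panel[]
}

#' Split raw VCF records into SNP and InDel tables with pooled allele fraction
#'
#' @param cell_records named list of per-cell record tables from
#'   [read_vcf_records()] (or one pooled table).
#' @return list with `snvs` (chrom, pos, ref, alt, qual, alt_fraction; qual is
#'   the maximum across cells, alt_fraction is pooled over allelic depths, or
#'   over genotype calls when AD is absent) and `indels`.
#' @export
pool_variants <- function(cell_records) {
  if (is.data.frame(cell_records)) cell_records <- list(cell_records)
  all <- rbindlist(cell_records, idcol = "cell")
  is_indel <- nchar(all$ref) > 1L | (nchar(all$alt) > 1L &
                                       !grepl(",", all$alt, fixed = TRUE))
  indels <- unique(all[is_indel, .(chrom, pos, ref, alt)])
  snv <- all[!is_indel]
  pooled <- snv[, {
    ad_ok <- !is.na(ad_ref) & !is.na(ad_alt)
    af <- if (any(ad_ok)) {
      sum(ad_alt[ad_ok]) / sum(ad_ref[ad_ok] + ad_alt[ad_ok])
    } else {
      # haploid cells: each call contributes its allele; hets count half
      mean(fifelse(gt_code == 2L, 0.5, as.numeric(gt_code)), na.rm = TRUE)
    }
    .(qual = suppressWarnings(max(qual, na.rm = TRUE)), alt_fraction = af)
  }, by = .(chrom, pos, ref, alt)]
  setorder(pooled, chrom, pos)
  list(snvs = pooled[], indels = indels[])
}

#' Build the cells x loci genotype matrix
#'
#' Looks up each cell's call at every panel locus. A locus is MISSING (NA) for
#' a cell when the cell has no record there, the supporting depth is below
#' `min_depth`, or the raw call is heterozygous — a haploid cell cannot be
#' heterozygous, so such calls are demoted to missing but counted in
#' `n_het_raw` for QC.
#'
#' @param cell_calls named list of per-cell call tables (columns chrom, pos,
#'   gt_code, dp as from [read_vcf_records()]), or a named character vector of
#'   per-cell VCF paths.
#' @param panel SNP panel from [filter_snps()].
#' @param min_depth calls below this depth are treated as missing.
#' @return a `genotype_matrix`: list with `geno` (cells x loci integer matrix,
#'   0 = REF, 1 = ALT, NA = missing), `panel`, `cells`, and per-cell counters
#'   `n_called` (depth-passing raw calls), `n_het_raw`, `n_low_depth`.
#' @export
build_genotype_matrix <- function(cell_calls, panel, min_depth = 5L) {
  if (!nrow(panel)) stop("empty SNP panel")
  if (is.character(cell_calls)) {
    paths <- cell_calls
    nm <- if (is.null(names(paths)) || any(names(paths) == "")) {
      sub("\\.vcf(\\.gz)?$", "", basename(paths))
    } else names(paths)
    cell_calls <- setNames(lapply(paths, read_vcf_records), nm)
  }
  cells <- names(cell_calls)
  if (is.null(cells) || any(cells == "")) stop("cell_calls must be named")
  key <- paste(panel$chrom, panel$pos)
  geno <- matrix(NA_integer_, nrow = length(cells), ncol = nrow(panel),
                 dimnames = list(cells, NULL))
  n_called <- n_het <- n_lowdp <- setNames(integer(length(cells)), cells)
  for (cl in cells) {
    calls <- as.data.table(cell_calls[[cl]])
    bad <- setdiff(unique(calls$chrom), unique(panel$chrom))
    if (length(bad)) {
      stop(sprintf("cell '%s' has calls on contig(s) absent from the panel: %s",
                   cl, paste(bad, collapse = ", ")))
    }
    hit <- match(paste(calls$chrom, calls$pos), key)
    ok <- !is.na(hit) & !is.na(calls$gt_code)
    dp <- calls$dp
    deep <- is.na(dp) | dp >= min_depth  # records without DP pass through
    n_lowdp[cl] <- sum(ok & !deep)
    use <- ok & deep
    n_called[cl] <- sum(use)
    n_het[cl] <- sum(use & calls$gt_code == 2L)
    hom <- use & calls$gt_code != 2L
    geno[cl, hit[hom]] <- calls$gt_code[hom]
  }
  structure(
    list(geno = geno, panel = as.data.table(panel), cells = cells,
         n_called = n_called, n_het_raw = n_het, n_low_depth = n_lowdp),
    class = "genotype_matrix"
  )
}

#' Convert raw simulator observations into a genotype matrix
#'
#' Applies the same heterozygous-call demotion as [build_genotype_matrix()]
#' to the simulator's in-memory raw observation codes.
#'
#' @param obs a `raw_observations` object from [simulate_cell_observations()].
#' @return a `genotype_matrix`.
#' @export
as_genotype_matrix <- function(obs) {
  stopifnot(inherits(obs, "raw_observations"))
  geno <- obs$geno
  n_called <- rowSums(!is.na(geno))
  n_het <- rowSums(geno == 2L, na.rm = TRUE)
  geno[geno == 2L] <- NA_integer_
  structure(
    list(geno = geno, panel = copy(obs$panel), cells = obs$cells,
         n_called = n_called, n_het_raw = n_het,
         n_low_depth = setNames(integer(length(obs$cells)), obs$cells)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$cells), "cells x", ncol(x$geno),
      "loci on", length(unique(x$panel$chrom)), "chromosome(s)\n")
  cat(sprintf("  missing: %.1f%%  raw het calls: %d\n",
              100 * mean(is.na(x$geno)), sum(x$n_het_raw)))
  invisible(x)
}

#' Cell-level QC on the genotype matrix
#'
#' A haploid cell fails QC when its raw heterozygous-call rate exceeds
#' `het_max` (contamination signature) or its missing rate falls outside
#' `[miss_lo, miss_hi]` (too complete to be a single MDA-amplified cell, or
#' too sparse to be informative). Comparisons are strict, matching the
#' printed thresholds (> 5%, < 30%, > 70%).
#'
#' @param gm a `genotype_matrix`.
#' @param het_max maximum tolerated het rate (n_het_raw / n_called).
#' @param miss_lo,miss_hi allowed missing-rate window.
#' @return list with `report` (data.table: cell, n_called, n_het_raw,
#'   het_rate, missing_rate, passed, reason) and `matrix` (the genotype
#'   matrix restricted to passing cells).
#' @export
qc_cells <- function(gm, het_max = 0.05, miss_lo = 0.30, miss_hi = 0.70) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_loci <- ncol(gm$geno)
  missing_rate <- rowSums(is.na(gm$geno)) / n_loci
  het_rate <- ifelse(gm$n_called > 0, gm$n_het_raw / gm$n_called, NA_real_)
  reason <- character(length(gm$cells))
  fail_het <- is.na(het_rate) | het_rate > het_max
  fail_lo <- missing_rate < miss_lo
  fail_hi <- missing_rate > miss_hi
  reason[fail_hi] <- sprintf("missing rate > %d%%", round(100 * miss_hi))
  reason[fail_lo] <- sprintf("missing rate < %d%%", round(100 * miss_lo))
  reason[fail_het] <- sprintf("heterozygous rate > %d%%", round(100 * het_max))
  reason[is.na(het_rate)] <- "no depth-passing calls"
  passed <- !(fail_het | fail_lo | fail_hi)
  report <- data.table(
    cell = gm$cells, n_called = as.integer(gm$n_called),
    n_het_raw = as.integer(gm$n_het_raw),
    het_rate = as.numeric(het_rate), missing_rate = missing_rate,
    passed = passed, reason = reason
  )
  if (!any(passed)) {
    stop("all cells fail QC; review het_max/miss_lo/miss_hi thresholds ",
         "(downstream phasing is impossible with zero cells)")
  }
  keep <- which(passed)
  filtered <- structure(
    list(geno = gm$geno[keep, , drop = FALSE], panel = gm$panel,
         cells = gm$cells[keep], n_called = gm$n_called[keep],
         n_het_raw = gm$n_het_raw[keep], n_low_depth = gm$n_low_depth[keep]),
    class = "genotype_matrix"
  )
  list(report = report, matrix = filtered)
}
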