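# Minimal VCF reading/writing for the restricted dialect this pipeline
# consumes: CHROM/POS/REF/ALT/QUAL plus per-sample DP (depth), optionally
# AD (allelic depths) and GT. Positions are 1-based per VCF convention.

#' Read variant records from a (possibly gzipped) VCF file
#'
#' Parses one single-sample VCF into a flat table. Only the fields the
#' pipeline needs are extracted; genotype is inferred from allelic depths when
#' GT is absent (alt fraction >= 0.9 -> hom-alt, <= 0.1 -> hom-ref, else het).
#'
#' @param path VCF file, plain or gzip.
#' @return data.table with columns chrom, pos, ref, alt, qual, dp, ad_ref,
#'   ad_alt, gt_code (0 hom-ref, 1 hom-alt, 2 het, NA no-call).
#' @export
read_vcf_records <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  body_at <- which(!startsWith(lines, "#"))
  if (!length(body_at)) {
    return(data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(), dp = integer(),
                      ad_ref = integer(), ad_alt = integer(),
                      gt_code = integer()))
  }
  parts <- strsplit(lines[body_at], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 8L)) {
    bad <- body_at[which(nf < 8L)[1L]]
    stop(sprintf("malformed VCF record at line %d of %s (< 8 fields)",
                 bad, path))
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:10)), ncol = 10L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(pos)) {
    bad <- body_at[which(is.na(pos))[1L]]
    stop(sprintf("malformed POS at line %d of %s", bad, path))
  }
  qual <- suppressWarnings(as.numeric(m[, 6L]))
  qual[m[, 6L] == "."] <- NA_real_

  fmt <- m[, 9L]
  smp <- m[, 10L]
  get_field <- function(name) {
    keys <- strsplit(fmt, ":", fixed = TRUE)
    vals <- strsplit(smp, ":", fixed = TRUE)
    vapply(seq_along(keys), function(r) {
      hit <- match(name, keys[[r]])
      if (is.na(hit) || hit > length(vals[[r]])) NA_character_
      else vals[[r]][hit]
    }, character(1L))
  }
  dp <- suppressWarnings(as.integer(get_field("DP")))
  ad <- get_field("AD")
  ad_split <- strsplit(ad, ",", fixed = TRUE)
  ad_ref <- suppressWarnings(as.integer(vapply(ad_split, function(x)
    if (length(x) >= 1L) x[1L] else NA_character_, character(1L))))
  ad_alt <- suppressWarnings(as.integer(vapply(ad_split, function(x)
    if (length(x) >= 2L) x[2L] else NA_character_, character(1L))))
  gt <- get_field("GT")
  gt_code <- rep(NA_integer_, length(gt))
  gt_norm <- gsub("|", "/", gt, fixed = TRUE)
  gt_code[gt_norm %in% c("0/0", "0")] <- 0L
  gt_code[gt_norm %in% c("1/1", "1")] <- 1L
  gt_code[gt_norm %in% c("0/1", "1/0")] <- 2L
  no_gt <- is.na(gt)
  if (any(no_gt)) {
    af <- ad_alt / (ad_ref + ad_alt)
    gt_code[no_gt & !is.na(af) & af >= 0.9] <- 1L
    gt_code[no_gt & !is.na(af) & af <= 0.1] <- 0L
    gt_code[no_gt & !is.na(af) & af > 0.1 & af < 0.9] <- 2L
  }
  dt <- data.table(
    chrom = m[, 1L], pos = pos, ref = m[, 4L], alt = m[, 5L],
    qual = qual, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt, gt_code = gt_code
  )
  if (is.unsorted(order(dt$chrom, dt$pos))) setorder(dt, chrom, pos)
  dt
}

#' Write a SNP panel as a minimal VCF
#'
#' @param panel data.table with chrom, pos, ref, alt and optionally qual.
#' @param path output path (".gz" suffix triggers gzip).
#' @export
write_panel_vcf <- function(panel, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gametephase",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  qual <- if ("qual" %in% names(panel)) format(panel$qual) else "."
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t.",
                  panel$chrom, panel$pos, panel$ref, panel$alt, qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Write one single-sample VCF per simulated cell
#'
#' Emits the simulator's raw genotype observations in the dialect
#' [build_genotype_matrix()] consumes: non-missing calls only, GT plus a
#' simulated DP always at or above the depth filter (missingness is simulated
#' at the window level, so round-tripping through VCF reproduces the raw
#' observation matrix exactly).
#'
#' @param sim output of [simulate_gametes()].
#' @param dir output directory.
#' @return named character vector of VCF paths, one per cell.
#' @export
write_cell_vcfs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obs <- sim$observations
  panel <- obs$panel
  set.seed(substream_seed(sim$config$seed, 6L))
  paths <- setNames(file.path(dir, paste0(obs$cells, ".vcf")), obs$cells)
  for (cl in obs$cells) {
    g <- obs$geno[cl, ]
    keep <- which(!is.na(g))
    dp <- 5L + rpois(length(keep), max(sim$config$mean_depth, 1))
    gt <- c("0/0", "1/1", "0/1")[g[keep] + 1L]
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##source=gametephase-simulator",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", cl)
    )
    body <- sprintf("%s\t%d\t.\t%s\t%s\t60\tPASS\t.\tGT:DP\t%s:%d",
                    panel$chrom[keep], panel$pos[keep], panel$ref[keep],
                    panel$alt[keep], gt, dp)
    writeLines(c(hdr, body), paths[[cl]])
  }
  paths
}

#' Write consensus haplotypes as a two-sample phased VCF
#'
#' Samples hapA/hapB carry `0|1` / `1|0` genotypes with a PS (phase set) tag;
#' phase is only meaningful within a phase set.
#'
#' @param consensus a [majority_vote_phase()] result.
#' @param path output path.
#' @export
write_phased_vcf <- function(consensus, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gametephase",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\thapA\thapB"
  )
  gtA <- ifelse(consensus$hapA_is_ref, "0|0", "1|1")
  gtB <- ifelse(consensus$hapA_is_ref, "1|1", "0|0")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:PS\t%s:%d\t%s:%d",
                  consensus$chrom, consensus$pos, consensus$ref, consensus$alt,
                  gtA, consensus$phase_set, gtB, consensus$phase_set)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' @param reads data.table with read_id and seq columns.
#' @param path output FASTQ path (".gz" for gzip).
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads)) {
    recs <- sprintf("@%s\n%s\n+\n%s", reads$read_id, reads$seq,
                    strrep("I", nchar(reads$seq)))
    writeLines(recs, con)
  }
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (plain or gzip).
#' @return data.table with read_id and seq.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table(read_id = names(x), seq = as.character(x))
}
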