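## CpG-, SNP- and pair-level quality filters producing the analysis-ready
## SNP--CpG pair table.

#' Filter CpG sites
#'
#' Applies, in order, the three CpG-level exclusion rules:
#' (i) measured (total reads >= 1) in less than \code{presence_min} of
#' samples; (ii) constitutively hypo-/hypermethylated, i.e. methylation
#' below \code{constitutive_bounds[1]} or above \code{constitutive_bounds[2]}
#' in at least \code{constitutive_fraction} of measured samples; (iii) mean
#' read depth over measured samples below \code{depth_min}. Each excluded
#' CpG is tagged with its first failing rule.
#'
#' @param mc \code{\link{methylation_counts}} (rows = CpGs).
#' @param cfg \code{\link{run_config}}.
#' @return list with \code{retained} (character vector of CpG ids),
#'   \code{ledger} (data.frame cpg_id, rule in
#'   \{"presence","constitutive","depth"\}).
#' @export
filter_cpg_sites <- function(mc, cfg = run_config()) {
  stopifnot(inherits(mc, "methylation_counts"))
  n_samp <- ncol(mc$total)
  if (n_samp == 0) stop("zero samples")
  measured <- !is.na(mc$total) & mc$total >= 1
  n_meas <- rowSums(measured)
  frac_meas <- n_meas / n_samp

  ratio <- mc$meth / mc$total
  ratio[!measured] <- NA
  lo <- cfg$constitutive_bounds[1]; hi <- cfg$constitutive_bounds[2]
  extreme <- (ratio < lo) | (ratio > hi)
  frac_extreme <- rowSums(extreme, na.rm = TRUE) / pmax(1, n_meas)

  depth <- mc$total
  depth[!measured] <- NA
  mean_depth <- rowMeans(depth, na.rm = TRUE)

  rule <- rep(NA_character_, nrow(mc$total))
  rule[frac_meas < cfg$presence_min] <- "presence"
  rule[is.na(rule) & frac_extreme >= cfg$constitutive_fraction] <- "constitutive"
  rule[is.na(rule) & (n_meas == 0 | mean_depth < cfg$depth_min)] <- "depth"

  ids <- rownames(mc$total)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mc$total)))
  list(retained = ids[is.na(rule)],
       ledger = data.frame(cpg_id = ids[!is.na(rule)],
                           rule = rule[!is.na(rule)],
                           stringsAsFactors = FALSE))
}

#' Build the analysis-ready SNP--CpG pair table
#'
#' Pairs each retained CpG with every called SNP within \code{asm_window}
#' bp on the same (autosomal) chromosome whose MAF, computed across the
#' samples with methylation data at that CpG, is at least \code{maf_min}.
#' One row per SNP--CpG combination; a CpG may pair with several SNPs.
#'
#' @param mc \code{\link{methylation_counts}} for the retained CpGs (rows
#'   named by CpG id).
#' @param cpg_pos data.frame cpg_id, chrom, pos.
#' @param geno \code{genotype_table} (dosages x samples; sites with chrom,
#'   pos, ref, alt).
#' @param asm optional ASM records
#'   (\code{\link{extract_allele_specific_counts}} output plus snp_id) to
#'   attach per-allele counts.
#' @param cfg \code{\link{run_config}}.
#' @return \code{\link{pair_table}} restricted to samples shared between
#'   \code{mc} and \code{geno}.
#' @export
build_pairs <- function(mc, cpg_pos, geno, asm = NULL, cfg = run_config()) {
  stopifnot(inherits(mc, "methylation_counts"))
  samples <- intersect(colnames(mc$total), geno$samples)
  if (!length(samples)) stop("no shared samples between methylation and genotypes")
  auto <- !grepl("^(chr)?[XYM]", geno$sites$chrom)
  snp_idx <- which(auto)
  cpgs <- cpg_pos[cpg_pos$cpg_id %in% rownames(mc$total), , drop = FALSE]

  rows <- list(); k <- 0L
  dos <- geno$dosage[, samples, drop = FALSE]
  meth <- mc$meth[, samples, drop = FALSE]
  tot <- mc$total[, samples, drop = FALSE]
  for (ci in seq_len(nrow(cpgs))) {
    on_chr <- snp_idx[geno$sites$chrom[snp_idx] == cpgs$chrom[ci]]
    if (!length(on_chr)) next
    near <- on_chr[abs(geno$sites$pos[on_chr] - cpgs$pos[ci]) <= cfg$asm_window]
    if (!length(near)) next
    has_meth <- !is.na(tot[cpgs$cpg_id[ci], ]) & tot[cpgs$cpg_id[ci], ] >= 1
    for (si in near) {
      d <- dos[si, ]
      dm <- d[has_meth & !is.na(d)]
      if (!length(dm)) next
      af <- mean(dm) / 2
      maf <- min(af, 1 - af)
      if (maf < cfg$maf_min) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        snp_row = si, cpg_id = cpgs$cpg_id[ci], chrom = cpgs$chrom[ci],
        snp_pos = geno$sites$pos[si], cpg_pos = cpgs$pos[ci], maf = maf,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!k) stop("no SNP-CpG pairs pass the filters")
  pr <- do.call(rbind, rows)
  snp_id <- if (!is.null(rownames(geno$dosage))) {
    rownames(geno$dosage)[pr$snp_row]
  } else {
    paste0(geno$sites$chrom[pr$snp_row], ":", geno$sites$pos[pr$snp_row])
  }
  pairs <- data.frame(
    pair_id = sprintf("pair%05d", seq_len(k)), snp_id = snp_id,
    cpg_id = pr$cpg_id, chrom = pr$chrom, snp_pos = pr$snp_pos,
    cpg_pos = pr$cpg_pos, maf = pr$maf, stringsAsFactors = FALSE
  )
  n <- nrow(pairs); m <- length(samples)
  shape <- function(src) {
    out <- src[pr$snp_row, , drop = FALSE]
    dimnames(out) <- list(pairs$pair_id, samples)
    out
  }
  y <- meth[pairs$cpg_id, , drop = FALSE]
  r <- tot[pairs$cpg_id, , drop = FALSE]
  dimnames(y) <- dimnames(r) <- list(pairs$pair_id, samples)
  y[is.na(r) | r < 1] <- NA; r[is.na(r) | r < 1] <- NA

  ayr <- arr <- aya <- ara <- matrix(NA_real_, n, m,
                                     dimnames = list(pairs$pair_id, samples))
  if (!is.null(asm) && nrow(asm)) {
    for (i in seq_len(n)) {
      sub <- asm[asm$snp_id == pairs$snp_id[i] &
                   asm$sample_id %in% samples, , drop = FALSE]
      if (!nrow(sub)) next
      j <- match(sub$sample_id, samples)
      ## allele totals must not exceed the CpG totals (invariant)
      scale_ok <- !is.na(r[i, j]) & (sub$total_ref + sub$total_alt) <= r[i, j]
      j <- j[scale_ok]; sub <- sub[scale_ok, , drop = FALSE]
      if (!length(j)) next
      ara[i, j] <- sub$total_ref; aya[i, j] <- sub$meth_ref
      arr[i, j] <- sub$total_alt; ayr[i, j] <- sub$meth_alt
    }
  }
  pair_table(pairs, samples, shape(dos), y, r,
             asm_y_ref = aya, asm_r_ref = ara,
             asm_y_alt = ayr, asm_r_alt = arr)
}
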