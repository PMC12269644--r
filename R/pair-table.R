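## The SNP--CpG pair table: unit of analysis for meQTL mapping.

#' Construct a SNP--CpG pair table
#'
#' Holds, for each pair (rows) and sample (columns), the SNP dosage, total
#' methylated/total read counts and, for heterozygotes with
#' allele-assignable reads, per-allele methylated/total counts.
#'
#' @param pairs data.frame with at least pair_id, snp_id, cpg_id, chrom,
#'   snp_pos, cpg_pos; one row per pair.
#' @param samples character vector of sample ids (column order).
#' @param dosage pairs x samples dosage of the non-reference allele.
#' @param y,r pairs x samples methylated / total counts (NA = unmeasured).
#' @param asm_y_ref,asm_r_ref,asm_y_alt,asm_r_alt per-allele counts for
#'   heterozygotes (NA where no allele-assignable reads).
#' @return list of class \code{pair_table}.
#' @export
pair_table <- function(pairs, samples, dosage, y, r,
                       asm_y_ref = NULL, asm_r_ref = NULL,
                       asm_y_alt = NULL, asm_r_alt = NULL) {
  n <- nrow(pairs); m <- length(samples)
  blank <- function(x) if (is.null(x)) matrix(NA_real_, n, m) else x
  asm_y_ref <- blank(asm_y_ref); asm_r_ref <- blank(asm_r_ref)
  asm_y_alt <- blank(asm_y_alt); asm_r_alt <- blank(asm_r_alt)
  for (mm in list(dosage, y, r, asm_y_ref, asm_r_ref, asm_y_alt, asm_r_alt)) {
    stopifnot(nrow(mm) == n, ncol(mm) == m)
  }
  if (any(y > r, na.rm = TRUE)) stop("methylated counts exceed totals")
  if (any(asm_y_ref > asm_r_ref, na.rm = TRUE) ||
      any(asm_y_alt > asm_r_alt, na.rm = TRUE)) {
    stop("allele-level methylated counts exceed allele totals")
  }
  tot_asm <- ifelse(is.na(asm_r_ref), 0, asm_r_ref) +
    ifelse(is.na(asm_r_alt), 0, asm_r_alt)
  if (any(tot_asm > ifelse(is.na(r), 0, r) + 1e-9, na.rm = TRUE)) {
    stop("allele totals exceed the sample's total reads")
  }
  out <- list(pairs = pairs, samples = samples, dosage = dosage, y = y, r = r,
              asm_y_ref = asm_y_ref, asm_r_ref = asm_r_ref,
              asm_y_alt = asm_y_alt, asm_r_alt = asm_r_alt)
  class(out) <- "pair_table"
  out
}

#' @export
print.pair_table <- function(x, ...) {
  n_asm <- sum(!is.na(x$asm_r_ref) | !is.na(x$asm_r_alt))
  cat(sprintf("pair_table: %d SNP-CpG pairs x %d samples (%d het sample-pairs with ASM)\n",
              nrow(x$pairs), length(x$samples), n_asm))
  invisible(x)
}

#' Subset a pair table by pair index
#' @param pt pair_table.
#' @param i integer or logical index over pairs.
#' @return pair_table restricted to the selected pairs.
#' @export
subset_pairs <- function(pt, i) {
  pt$pairs <- pt$pairs[i, , drop = FALSE]
  for (nm in c("dosage", "y", "r", "asm_y_ref", "asm_r_ref",
               "asm_y_alt", "asm_r_alt")) {
    pt[[nm]] <- pt[[nm]][i, , drop = FALSE]
  }
  if (!is.null(pt$truth_g)) pt$truth_g <- pt$truth_g[i, , drop = FALSE]
  rownames(pt$pairs) <- NULL
  pt
}

#' Permute genotype data across samples under the no-effect null
#'
#' Applies one sample permutation to the dosage vectors of the selected
#' pairs (methylation counts, covariates and relatedness untouched) and
#' rebuilds the ASM allele assignment for samples that are heterozygous
#' after permutation: each such sample's own reads are first thinned to the
#' pair's observed allele-assignable fraction (so the null fits carry the
#' same read information as the observed fit), then re-tagged by an
#' exchangeable split (allele totals Binomial(1/2), methylated reads
#' hypergeometric given the sample's own methylated total) -- the
#' read-level null of no allele effect. Uses the current RNG stream.
#'
#' @param pt pair_table.
#' @param perm integer permutation of \code{seq_along(pt$samples)}.
#' @param i pairs to permute (default all).
#' @return pair_table with permuted genotypes and null ASM assignments.
#' @export
permute_pair_genotypes <- function(pt, perm, i = seq_len(nrow(pt$pairs))) {
  stopifnot(length(perm) == length(pt$samples),
            all(sort(perm) == seq_along(pt$samples)))
  ## observed assessable fraction per pair (reads entering allele rows /
  ## total reads of het samples with ASM); 0 when the pair has no ASM
  asm_tot <- ifelse(is.na(pt$asm_r_ref), 0, pt$asm_r_ref) +
    ifelse(is.na(pt$asm_r_alt), 0, pt$asm_r_alt)
  has_asm <- asm_tot > 0 & !is.na(pt$r) & pt$r > 0
  num <- rowSums(asm_tot * has_asm)
  den <- rowSums(pt$r * has_asm, na.rm = TRUE)
  frac <- ifelse(den > 0, num / den, 0)

  pt$dosage[i, ] <- pt$dosage[i, perm, drop = FALSE]
  d <- pt$dosage[i, , drop = FALSE]
  y <- pt$y[i, , drop = FALSE]; r <- pt$r[i, , drop = FALSE]
  fr <- frac[i]
  ayR <- arR <- ayA <- arA <- matrix(NA_real_, nrow(d), ncol(d))
  het <- which(d == 1L & !is.na(r) & r > 0)
  if (length(het)) {
    pr <- fr[((het - 1L) %% nrow(d)) + 1L]
    r_asm <- stats::rbinom(length(het), r[het], pr)
    y_asm <- .rhyper_safe(y[het], r[het] - y[het], r_asm)
    rr <- stats::rbinom(length(het), r_asm, 0.5)
    yr <- .rhyper_safe(y_asm, r_asm - y_asm, rr)
    keep <- r_asm > 0
    hk <- het[keep]
    arR[hk] <- rr[keep]; ayR[hk] <- yr[keep]
    arA[hk] <- r_asm[keep] - rr[keep]; ayA[hk] <- y_asm[keep] - yr[keep]
  }
  pt$asm_r_ref[i, ] <- arR; pt$asm_y_ref[i, ] <- ayR
  pt$asm_r_alt[i, ] <- arA; pt$asm_y_alt[i, ] <- ayA
  pt
}

.rhyper_safe <- function(m, n, k) {
  out <- numeric(length(m))
  ok <- k > 0 & (m + n) > 0
  out[ok] <- stats::rhyper(sum(ok), m[ok], n[ok], k[ok])
  out
}
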