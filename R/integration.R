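## meQTL-eQTL integration: overlap, effect-direction concordance,
## methylation-expression correlation, and mapping summary statistics.

#' Intersect meQTL and eQTL call sets into SNP--CpG--gene trios
#'
#' Joins the two significant sets on exact SNP genomic position: an meQTL
#' SNP overlaps an eQTL SNP only when they share the same (chrom, pos).
#'
#' @param meqtl association table with chrom, snp_pos, cpg_id, beta,
#'   significant (or a q column with \code{meqtl_fdr}).
#' @param eqtl eQTL table with snp_id, gene_id, beta, significant and SNP
#'   coordinates via \code{snp_coords} when not embedded.
#' @param snp_coords data.frame snp_id, chrom, pos for the eQTL SNPs.
#' @return data.frame of trios: chrom, snp_pos, cpg_id, gene_id, beta_meth,
#'   beta_expr, concordant.
#' @export
intersect_meqtl_eqtl <- function(meqtl, eqtl, snp_coords) {
  ms <- meqtl[!is.na(meqtl$significant) & meqtl$significant, , drop = FALSE]
  es <- eqtl[!is.na(eqtl$significant) & eqtl$significant, , drop = FALSE]
  ec <- snp_coords[match(es$snp_id, snp_coords$snp_id), , drop = FALSE]
  key_m <- paste(ms$chrom, ms$snp_pos)
  key_e <- paste(ec$chrom, ec$pos)
  hit <- which(key_m %in% key_e)
  out <- list(); k <- 0L
  for (i in hit) {
    j <- which(key_e == key_m[i])
    for (jj in j) {
      k <- k + 1L
      out[[k]] <- data.frame(
        chrom = ms$chrom[i], snp_pos = ms$snp_pos[i],
        cpg_id = ms$cpg_id[i], gene_id = es$gene_id[jj],
        beta_meth = ms$beta[i], beta_expr = es$beta[jj],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!k) {
    return(data.frame(chrom = character(0), snp_pos = integer(0),
                      cpg_id = character(0), gene_id = character(0),
                      beta_meth = numeric(0), beta_expr = numeric(0),
                      concordant = logical(0)))
  }
  trios <- unique(do.call(rbind, out))
  trios$concordant <- sign(trios$beta_meth) == sign(trios$beta_expr)
  rownames(trios) <- NULL
  trios
}

#' Effect-direction concordance of meQTL--eQTL trios
#'
#' Fraction of trios in which the genotype effect on methylation and on
#' expression share a sign, with a two-sided exact binomial test against
#' 0.5. The denominator is unique trios by default; \code{unit =
#' "snp_gene"} collapses to unique SNP--gene pairs first.
#'
#' @param trios \code{\link{intersect_meqtl_eqtl}} output.
#' @param unit "trio" (default) or "snp_gene".
#' @return list with fraction, n, n_concordant, p_value.
#' @export
direction_concordance <- function(trios, unit = c("trio", "snp_gene")) {
  unit <- match.arg(unit)
  if (unit == "snp_gene") {
    trios <- trios[!duplicated(trios[, c("chrom", "snp_pos", "gene_id")]), ,
                   drop = FALSE]
  }
  n <- nrow(trios)
  if (!n) return(list(fraction = NA_real_, n = 0L, n_concordant = 0L,
                      p_value = NA_real_))
  k <- sum(trios$concordant)
  bt <- stats::binom.test(k, n, p = 0.5, alternative = "two.sided")
  list(fraction = k / n, n = n, n_concordant = k, p_value = bt$p.value)
}

#' Methylation--expression correlation over trio CpG--gene pairs
#'
#' Spearman's rank correlation (midranks for ties) between the CpG
#' methylation ratio and the gene's expression across matched samples, for
#' every unique CpG--gene pair in the trio set, with Storey/BH q-values at
#' \code{fdr_level}. Sample matching is strict one-to-one by id; a sample
#' present in only one assay is an error.
#'
#' @param meth_ratio CpGs x samples methylation-ratio matrix.
#' @param expr genes x samples expression matrix.
#' @param trios \code{\link{intersect_meqtl_eqtl}} output.
#' @param fdr_level FDR level (default 0.20).
#' @return data.frame cpg_id, gene_id, rho, n, p, q, significant.
#' @export
methylation_expression_correlation <- function(meth_ratio, expr, trios,
                                               fdr_level = 0.20) {
  if (!setequal(colnames(meth_ratio), colnames(expr))) {
    only <- c(setdiff(colnames(meth_ratio), colnames(expr)),
              setdiff(colnames(expr), colnames(meth_ratio)))
    stop("samples not matched between assays: ", paste(only, collapse = ", "))
  }
  expr <- expr[, colnames(meth_ratio), drop = FALSE]
  pairs <- unique(trios[, c("cpg_id", "gene_id")])
  res <- list(); k <- 0L
  for (i in seq_len(nrow(pairs))) {
    cg <- pairs$cpg_id[i]; gn <- pairs$gene_id[i]
    if (!cg %in% rownames(meth_ratio) || !gn %in% rownames(expr)) next
    x <- meth_ratio[cg, ]; y <- expr[gn, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4) next
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    k <- k + 1L
    res[[k]] <- data.frame(cpg_id = cg, gene_id = gn,
                           rho = unname(ct$estimate), n = sum(ok),
                           p = ct$p.value, stringsAsFactors = FALSE)
  }
  if (!k) return(data.frame(cpg_id = character(0), gene_id = character(0),
                            rho = numeric(0), n = integer(0), p = numeric(0),
                            q = numeric(0), significant = logical(0)))
  out <- do.call(rbind, res)
  out$q <- bh_qvalues(out$p)
  out$significant <- !is.na(out$q) & out$q <= fdr_level
  rownames(out) <- NULL
  out
}

#' Summary statistics of a mapping run
#'
#' Headline counts and fractions of an meQTL association table: number and
#' percentage of significant pairs, unique significant SNPs and CpGs,
#' percentage of CpGs with at least one meQTL, mean SNPs per CpG,
#' percentage of significant SNPs associated with more than one CpG, the
#' sign-concordance of multi-CpG SNPs, and PVE summaries when a
#' \code{pve} column is present.
#'
#' @param assoc association table with cpg_id, snp-identifying columns,
#'   beta, significant (and optionally pve).
#' @return named list of summary values (percentages in 0--100).
#' @export
summarize_mapping_results <- function(assoc) {
  snp_key <- if ("snp_id" %in% names(assoc)) assoc$snp_id else
    paste(assoc$chrom, assoc$snp_pos)
  sig <- !is.na(assoc$significant) & assoc$significant
  n_pairs <- nrow(assoc)
  n_sig <- sum(sig)
  u_cpg <- unique(assoc$cpg_id)
  u_sig_cpg <- unique(assoc$cpg_id[sig])
  u_sig_snp <- unique(snp_key[sig])
  ## multi-CpG significant SNPs and their sign concordance
  sig_tab <- assoc[sig, , drop = FALSE]
  sig_snp_key <- snp_key[sig]
  cpg_per_snp <- tapply(sig_tab$cpg_id, sig_snp_key,
                        function(x) length(unique(x)))
  multi <- names(cpg_per_snp)[cpg_per_snp > 1]
  concordant_multi <- if (length(multi)) {
    same_sign <- vapply(multi, function(s) {
      b <- sig_tab$beta[sig_snp_key == s]
      all(b > 0) || all(b < 0)
    }, TRUE)
    100 * mean(same_sign)
  } else NA_real_
  out <- list(
    n_pairs = n_pairs,
    n_significant = n_sig,
    pct_pairs_significant = 100 * n_sig / max(1, n_pairs),
    n_unique_cpgs = length(u_cpg),
    n_unique_significant_cpgs = length(u_sig_cpg),
    pct_cpgs_with_meqtl = 100 * length(u_sig_cpg) / max(1, length(u_cpg)),
    n_unique_significant_snps = length(u_sig_snp),
    mean_snps_per_cpg = n_pairs / max(1, length(u_cpg)),
    pct_multi_cpg_snps = if (length(cpg_per_snp)) {
      100 * mean(cpg_per_snp > 1)
    } else NA_real_,
    pct_multi_cpg_snps_concordant = concordant_multi
  )
  if ("pve" %in% names(assoc)) {
    pv <- assoc$pve[sig]
    out$pve_mean_pct <- 100 * mean(pv, na.rm = TRUE)
    out$pve_median_pct <- 100 * stats::median(pv, na.rm = TRUE)
  }
  out
}
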