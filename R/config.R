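#' Run configuration for the meQTL/eQTL pipeline
#'
#' Collects every tunable threshold of the analysis in one validated list.
#' Defaults are the values used throughout the mapping pipeline: depth and
#' presence filters for CpGs, MAF/HWE/missingness filters for SNPs, the
#' same-read cis window for SNP--CpG pairs (100 bp) and the 200 kb cis window
#' for SNP--gene pairs, FDR levels (5% meQTL, 20% eQTL and
#' methylation--expression correlation), permutation counts, and the
#' CpG-island shore/shelf and promoter geometry used for annotation.
#'
#' @param seed integer seed fixed for a run.
#' @param depth_min minimum read depth (genotype calls and CpG mean depth).
#' @param maf_min minimum minor allele frequency.
#' @param presence_min minimum fraction of samples in which a CpG is measured.
#' @param constitutive_bounds methylation bounds (low, high) outside of which
#'   a sample counts as constitutively hypo-/hypermethylated.
#' @param constitutive_fraction fraction of measured samples beyond the bounds
#'   at which the CpG is dropped.
#' @param meqtl_fdr,eqtl_fdr,corr_fdr FDR levels for the three call sets.
#' @param cis_window maximum SNP-to-gene distance (bp) for eQTL pairing.
#' @param asm_window maximum SNP-to-CpG distance (bp) for same-read pairs.
#' @param n_perm_per_chrom permutations per chromosome for the empirical FDR.
#' @param n_gene_perm label permutations for the gene-level test.
#' @param min_cpgs_per_gene minimum tested CpGs for a gene to enter the
#'   gene-level permutation test.
#' @param gene_flank flank (bp) around a gene body defining "near the gene"
#'   for the gene-level test.
#' @param promoter_len promoter length upstream of the TSS (bp).
#' @param shore_len,shelf_len CpG shore and shelf widths (bp).
#' @param n_latent_factors latent factors removed from expression.
#' @param hwe_p_min minimum exact Hardy-Weinberg p-value.
#' @param max_missing maximum genotype missingness per site.
#' @param paths optional named list of file paths.
#' @param logging level string, one of "quiet", "info", "debug".
#' @return An object of class \code{asmqtl_config} (a named list).
#' @export
run_config <- function(seed = 1L,
                       depth_min = 5,
                       maf_min = 0.05,
                       presence_min = 0.10,
                       constitutive_bounds = c(0.10, 0.90),
                       constitutive_fraction = 0.90,
                       meqtl_fdr = 0.05,
                       eqtl_fdr = 0.20,
                       corr_fdr = 0.20,
                       cis_window = 200000,
                       asm_window = 100,
                       n_perm_per_chrom = 10,
                       n_gene_perm = 100,
                       min_cpgs_per_gene = 10,
                       gene_flank = 50000,
                       promoter_len = 2000,
                       shore_len = 2000,
                       shelf_len = 2000,
                       n_latent_factors = 5,
                       hwe_p_min = 1e-8,
                       max_missing = 0.05,
                       paths = list(),
                       logging = "info") {
  stopifnot(
    is.numeric(seed), length(seed) == 1L, is.finite(seed),
    depth_min >= 0, maf_min >= 0, maf_min <= 0.5,
    presence_min >= 0, presence_min <= 1,
    length(constitutive_bounds) == 2L,
    constitutive_bounds[1] >= 0, constitutive_bounds[2] <= 1,
    constitutive_bounds[1] < constitutive_bounds[2],
    constitutive_fraction >= 0, constitutive_fraction <= 1,
    meqtl_fdr > 0, meqtl_fdr < 1, eqtl_fdr > 0, eqtl_fdr < 1,
    corr_fdr > 0, corr_fdr < 1,
    cis_window >= 0, asm_window >= 0,
    n_perm_per_chrom >= 1, n_gene_perm >= 1,
    min_cpgs_per_gene >= 1, gene_flank >= 0,
    promoter_len >= 0, shore_len >= 0, shelf_len >= 0,
    n_latent_factors >= 0,
    hwe_p_min >= 0, hwe_p_min <= 1,
    max_missing >= 0, max_missing <= 1
  )
  logging <- match.arg(logging, c("quiet", "info", "debug"))
  cfg <- list(
    seed = as.integer(seed), depth_min = depth_min, maf_min = maf_min,
    presence_min = presence_min, constitutive_bounds = constitutive_bounds,
    constitutive_fraction = constitutive_fraction, meqtl_fdr = meqtl_fdr,
    eqtl_fdr = eqtl_fdr, corr_fdr = corr_fdr, cis_window = cis_window,
    asm_window = asm_window, n_perm_per_chrom = n_perm_per_chrom,
    n_gene_perm = n_gene_perm, min_cpgs_per_gene = min_cpgs_per_gene,
    gene_flank = gene_flank, promoter_len = promoter_len,
    shore_len = shore_len, shelf_len = shelf_len,
    n_latent_factors = n_latent_factors, hwe_p_min = hwe_p_min,
    max_missing = max_missing, paths = paths, logging = logging
  )
  class(cfg) <- "asmqtl_config"
  cfg
}

#' @export
print.asmqtl_config <- function(x, ...) {
  cat("asmqtl run configuration\n")
  flat <- x[!names(x) %in% c("paths", "logging")]
  for (nm in names(flat)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(flat[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

## internal logging helper; level-gated messages to stderr
asmqtl_log <- function(cfg, level = c("info", "debug"), ...) {
  level <- match.arg(level)
  if (is.null(cfg) || identical(cfg$logging, "quiet")) return(invisible(NULL))
  if (level == "debug" && !identical(cfg$logging, "debug")) return(invisible(NULL))
  message(sprintf(...))
  invisible(NULL)
}
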