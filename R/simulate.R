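## Synthetic-data generator with known truth.
##
## Emulates the statistical structure the mapping pipeline assumes:
## pedigree-structured genotypes, bisulfite read counts with logit-scale
## genotype effects and kinship-correlated + independent overdispersion,
## allele-assignable reads for heterozygotes (with bisulfite C/T and G/A
## ambiguity), covariate effects, pileups at SNP positions, and expression
## with shared cis effects plus injected latent factors.

#' Simulation parameters
#'
#' Defaults mirror the study design the pipeline targets where a value is
#' stated (mean read depth 18 per SNP--CpG pair, bisulfite conversion 0.99,
#' sequencing error 0.01, ~12% of individuals resampled, MAF >= 0.05,
#' variance components sigma_g^2 = 0.5 and sigma_e^2 = 0.3 with mean
#' genotype effect 0.8 on the logit scale); sizes not stated by the design
#' are set to desk scale (see the methods vignette).
#'
#' @param n_individuals pedigree size.
#' @param repeat_fraction fraction of individuals sampled twice.
#' @param n_cpgs number of CpG sites.
#' @param pairs_per_cpg mean SNPs paired with each CpG (>= 1; the excess
#'   over 1 is Poisson).
#' @param maf_range founder minor-allele-frequency range.
#' @param depth_mean,depth_size negative-binomial read-depth parameters.
#' @param conversion bisulfite conversion rate for unmethylated cytosines.
#' @param error_rate per-base sequencing error.
#' @param frac_nonnull fraction of SNP--CpG pairs with a true effect.
#' @param effect_mean,effect_sd magnitude distribution of non-null logit
#'   effects.
#' @param effect_sign "random" (default) or "positive".
#' @param sigma_g2,sigma_e2 kinship-correlated and independent random-effect
#'   variances on the logit scale.
#' @param mu_sd SD of per-CpG baseline logit methylation (mean 0).
#' @param covariate_fraction fraction of CpGs carrying age/sex/batch effects.
#' @param age_effect,sex_effect,batch_effect covariate effect sizes (logit
#'   units; age per year).
#' @param miss_rate probability a (sample, CpG) is unmeasured.
#' @param ct_snp_fraction fraction of SNPs that are C/T (bisulfite
#'   ambiguous); the rest are A/G.
#' @param n_chrom number of autosomes in the synthetic genome.
#' @param n_genes number of expressed genes.
#' @param expr_frac_nonnull fraction of genes with a true cis expression
#'   effect.
#' @param frac_shared_eqtl fraction of effect genes whose causal SNP is an
#'   meQTL SNP with a non-null methylation effect.
#' @param expr_effect_mean,expr_effect_sd expression effect magnitudes.
#' @param expr_sigma_u2,expr_sigma_e2 expression variance components.
#' @param n_latent,latent_sd injected latent factors (count, loading SD).
#' @param founder_fraction fraction of pedigree members that are founders.
#' @param seed integer seed; all generator output is a deterministic
#'   function of the parameter list.
#' @return list of class \code{sim_params}.
#' @export
sim_params <- function(n_individuals = 500, repeat_fraction = 0.12,
                       n_cpgs = 200, pairs_per_cpg = 1.4,
                       maf_range = c(0.1, 0.5),
                       depth_mean = 18, depth_size = 2,
                       conversion = 0.99, error_rate = 0.01,
                       frac_nonnull = 0.2,
                       effect_mean = 0.8, effect_sd = 0.2,
                       effect_sign = c("random", "positive"),
                       sigma_g2 = 0.5, sigma_e2 = 0.3,
                       mu_sd = 1,
                       covariate_fraction = 0.2,
                       age_effect = 0.02, sex_effect = 0.3, batch_effect = 0.3,
                       miss_rate = 0.05, ct_snp_fraction = 0.25,
                       n_chrom = 4, n_genes = 30, expr_frac_nonnull = 0.5,
                       frac_shared_eqtl = 0.5,
                       expr_effect_mean = 0.6, expr_effect_sd = 0.2,
                       expr_sigma_u2 = 0.3, expr_sigma_e2 = 0.7,
                       n_latent = 3, latent_sd = 1,
                       founder_fraction = 0.4,
                       seed = 1L) {
  effect_sign <- match.arg(effect_sign)
  p <- as.list(environment())
  stopifnot(
    p$n_individuals >= 2,
    p$repeat_fraction >= 0, p$repeat_fraction <= 1,
    p$pairs_per_cpg >= 1,
    p$maf_range[1] > 0, p$maf_range[2] <= 0.5,
    p$depth_mean > 0, p$depth_size > 0,
    p$conversion >= 0, p$conversion <= 1,
    p$error_rate >= 0, p$error_rate < 0.5,
    p$frac_nonnull >= 0, p$frac_nonnull <= 1,
    p$sigma_g2 >= 0, p$sigma_e2 >= 0,
    p$miss_rate >= 0, p$miss_rate < 1,
    p$ct_snp_fraction >= 0, p$ct_snp_fraction <= 1,
    p$n_chrom >= 1
  )
  p$seed <- as.integer(p$seed)
  class(p) <- "sim_params"
  p
}

#' Simulate pedigree, genotypes and relatedness
#'
#' Founder alleles are drawn at a per-SNP target MAF uniform in
#' \code{maf_range} and gene-dropped through the pedigree (independent
#' transmission per SNP). Repeated samples duplicate an individual's
#' genotypes. Also lays out the synthetic genome: CpGs spaced along
#' \code{n_chrom} chromosomes, each paired with one or more SNPs within
#' 100 bp (a small fraction of offsets land on the CpG itself, giving
#' CpG-disrupting SNPs).
#'
#' @param params \code{\link{sim_params}}.
#' @return list with pedigree, sample_map (sample_id, individual_id, sex,
#'   age, batch), K (sample relatedness), genotypes (genotype_table over
#'   samples), layout (data.frame pair_id, snp_id, cpg_id, chrom, snp_pos,
#'   cpg_pos, ref, alt, target_maf).
#' @export
simulate_pedigree_genotypes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  ped <- simulate_pedigree(params$n_individuals, params$founder_fraction)

  n <- params$n_individuals
  n_rep <- round(params$repeat_fraction * n)
  rep_ids <- if (n_rep > 0) sort(sample.int(n, n_rep)) else integer(0)
  sample_map <- data.frame(
    sample_id = c(sprintf("I%04d_S1", seq_len(n)), sprintf("I%04d_S2", rep_ids)),
    individual_id = c(seq_len(n), rep_ids),
    stringsAsFactors = FALSE
  )
  sample_map <- sample_map[order(sample_map$individual_id, sample_map$sample_id), ]
  rownames(sample_map) <- NULL
  sample_map$sex <- ped$sex[sample_map$individual_id]
  sample_map$age <- round(stats::runif(nrow(sample_map), 0.11, 28.8), 2)
  sample_map$batch <- sample(c(1L, 2L), nrow(sample_map), replace = TRUE)

  K <- build_relatedness_matrix(ped, sample_map)

  ## genome layout: CpGs round-robin over chromosomes, 1 kb apart
  n_cpg <- params$n_cpgs
  extra <- stats::rpois(n_cpg, params$pairs_per_cpg - 1)
  n_snp_per_cpg <- 1L + extra
  cpg_chrom_i <- ((seq_len(n_cpg) - 1L) %% params$n_chrom) + 1L
  within <- stats::ave(seq_len(n_cpg), cpg_chrom_i, FUN = seq_along)
  cpg_pos <- 10000L + (within - 1L) * 1000L
  cpg_id <- rep(seq_len(n_cpg), n_snp_per_cpg)
  offs <- sample(-100:100, length(cpg_id), replace = TRUE)
  layout <- data.frame(
    pair_id = sprintf("pair%05d", seq_along(cpg_id)),
    snp_id = sprintf("snp%05d", seq_along(cpg_id)),
    cpg_id = sprintf("cpg%05d", cpg_id),
    chrom = paste0("chr", cpg_chrom_i[cpg_id]),
    snp_pos = cpg_pos[cpg_id] + offs,
    cpg_pos = cpg_pos[cpg_id],
    stringsAsFactors = FALSE
  )
  is_ct <- stats::runif(nrow(layout)) < params$ct_snp_fraction
  layout$ref <- ifelse(is_ct, "C", "A")
  layout$alt <- ifelse(is_ct, "T", "G")
  layout$target_maf <- stats::runif(nrow(layout), params$maf_range[1],
                                    params$maf_range[2])

  ## founder haplotypes + gene dropping (alt-allele indicators)
  n_snp <- nrow(layout)
  H1 <- H2 <- matrix(0L, n, n_snp)
  founders <- which(is.na(ped$sire) & is.na(ped$dam))
  H1[founders, ] <- matrix(stats::rbinom(length(founders) * n_snp, 1L,
                                         rep(layout$target_maf, each = length(founders))),
                           length(founders), n_snp)
  H2[founders, ] <- matrix(stats::rbinom(length(founders) * n_snp, 1L,
                                         rep(layout$target_maf, each = length(founders))),
                           length(founders), n_snp)
  for (i in setdiff(seq_len(n), founders)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    pick_s <- stats::runif(n_snp) < 0.5
    pick_d <- stats::runif(n_snp) < 0.5
    H1[i, ] <- ifelse(pick_s, H1[s, ], H2[s, ])
    H2[i, ] <- ifelse(pick_d, H1[d, ], H2[d, ])
  }
  dos_ind <- H1 + H2                       # individuals x SNPs
  dosage <- t(dos_ind[sample_map$individual_id, , drop = FALSE])
  dimnames(dosage) <- list(layout$snp_id, sample_map$sample_id)

  af <- rowMeans(dosage) / 2
  sites <- data.frame(chrom = layout$chrom, pos = layout$snp_pos,
                      ref = layout$ref, alt = layout$alt,
                      maf = pmin(af, 1 - af), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  genotypes <- structure(list(dosage = dosage, sites = sites,
                              samples = sample_map$sample_id,
                              excluded = data.frame()),
                         class = "genotype_table")
  list(pedigree = ped, sample_map = sample_map, K = K,
       genotypes = genotypes, layout = layout)
}

#' Truth table for a simulated study
#'
#' Draws the true per-pair methylation effects (logit units), the per-CpG
#' baselines and covariate effects, and the per-gene expression effects,
#' recording which pairs are null.
#'
#' @param geno output of \code{\link{simulate_pedigree_genotypes}}.
#' @param params \code{\link{sim_params}}.
#' @return list with \code{pairs} (pair_id, beta, is_null, sigma_g2,
#'   sigma_e2), \code{cpgs} (cpg_id, mu, has_covariates), \code{genes}
#'   (gene_id, chrom, start, end, strand, tss, causal_snp, beta_expr,
#'   shared_with_meqtl) and \code{samples} (covariates).
#' @export
simulate_truth <- function(geno, params) {
  set.seed(params$seed + 2L)
  layout <- geno$layout
  n_pair <- nrow(layout)
  nonnull <- stats::runif(n_pair) < params$frac_nonnull
  sgn <- if (identical(params$effect_sign, "positive")) {
    rep(1, n_pair)
  } else {
    sample(c(-1, 1), n_pair, replace = TRUE)
  }
  beta <- ifelse(nonnull,
                 sgn * abs(stats::rnorm(n_pair, params$effect_mean,
                                        params$effect_sd)),
                 0)
  pairs <- data.frame(pair_id = layout$pair_id, beta = beta,
                      is_null = !nonnull,
                      sigma_g2 = params$sigma_g2, sigma_e2 = params$sigma_e2,
                      stringsAsFactors = FALSE)
  cpg_ids <- unique(layout$cpg_id)
  cpgs <- data.frame(
    cpg_id = cpg_ids,
    mu = stats::rnorm(length(cpg_ids), 0, params$mu_sd),
    has_covariates = stats::runif(length(cpg_ids)) < params$covariate_fraction,
    stringsAsFactors = FALSE
  )

  ## genes: bodies along each chromosome, strand alternating
  n_g <- params$n_genes
  g_chrom_i <- ((seq_len(n_g) - 1L) %% params$n_chrom) + 1L
  within <- stats::ave(seq_len(n_g), g_chrom_i, FUN = seq_along)
  start <- 5000L + (within - 1L) * 40000L
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_g)),
    chrom = paste0("chr", g_chrom_i),
    start = start, end = start + 4999L,
    strand = rep(c("+", "-"), length.out = n_g),
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)

  ## causal SNP: nearest layout SNP on the chromosome within 200 kb of body
  genes$causal_snp <- NA_character_
  genes$beta_expr <- 0
  genes$shared_with_meqtl <- FALSE
  has_effect <- stats::runif(n_g) < params$expr_frac_nonnull
  want_shared <- stats::runif(n_g) < params$frac_shared_eqtl
  for (j in seq_len(n_g)) {
    if (!has_effect[j]) next
    on_chr <- layout[layout$chrom == genes$chrom[j], , drop = FALSE]
    if (!nrow(on_chr)) next
    dist <- pmax(0, pmax(genes$start[j] - on_chr$snp_pos,
                         on_chr$snp_pos - genes$end[j]))
    cand <- on_chr[dist <= 200000, , drop = FALSE]
    if (!nrow(cand)) next
    cand_nonnull <- cand[!pairs$is_null[match(cand$pair_id, pairs$pair_id)], ,
                         drop = FALSE]
    pick <- if (want_shared[j] && nrow(cand_nonnull)) {
      cand_nonnull[sample.int(nrow(cand_nonnull), 1L), ]
    } else {
      cand[sample.int(nrow(cand), 1L), ]
    }
    genes$causal_snp[j] <- pick$snp_id
    genes$beta_expr[j] <- sample(c(-1, 1), 1L) *
      abs(stats::rnorm(1L, params$expr_effect_mean, params$expr_effect_sd))
    genes$shared_with_meqtl[j] <-
      !pairs$is_null[match(pick$pair_id, pairs$pair_id)]
  }
  list(pairs = pairs, cpgs = cpgs, genes = genes,
       samples = geno$sample_map)
}

## observed-base probabilities for one read group after bisulfite chemistry
## and sequencing error; bases ordered A,C,G,T; context "C" = OT strand
## (C->T when unmethylated), "G" = OB strand (G->A when unmethylated).
.obs_base_probs <- function(base, context, methylated, conversion, error_rate) {
  p <- c(A = 0, C = 0, G = 0, T = 0)
  if (base == "C" && context == "C" && !methylated) {
    p["T"] <- conversion; p["C"] <- 1 - conversion
  } else if (base == "G" && context == "G" && !methylated) {
    p["A"] <- conversion; p["G"] <- 1 - conversion
  } else {
    p[base] <- 1
  }
  p * (1 - error_rate) + (1 - p) * (error_rate / 3)
}

#' Simulate bisulfite read counts with allele-specific methylation
#'
#' For each (sample, allele copy) the methylation probability is
#' inverse-logit(mu + beta * a + covariates + g + e) with
#' g ~ MVN(0, sigma_g^2 K) and e ~ N(0, sigma_e^2 I); reads are binomial at
#' that probability, heterozygote reads carry allele tags, and allele
#' assessability follows bisulfite chemistry (on the converted strand an
#' unmethylated C reads as T, so reads showing the convertible base's
#' converted form are not allele-assignable at C/T or A/G SNPs).
#'
#' @param geno output of \code{\link{simulate_pedigree_genotypes}}.
#' @param truth output of \code{\link{simulate_truth}}.
#' @param params \code{\link{sim_params}}.
#' @param emit_reads also generate read-level tallies and per-SNP pileups
#'   (with conversion failures and sequencing errors) for the genotype
#'   caller; slower, off by default.
#' @return \code{pair_table} (see \code{\link{pair_table}}); when
#'   \code{emit_reads} the list members \code{reads} (allele-tagged read
#'   tallies for heterozygotes) and \code{pileups} (per sample/SNP/strand
#'   base counts) are attached as attributes-free list entries.
#' @export
simulate_methylation_reads <- function(geno, truth, params, emit_reads = FALSE) {
  set.seed(params$seed + 3L)
  K <- geno$K
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-6 * max(1, abs(ev))) stop("relatedness matrix is not positive semi-definite")
  L <- chol(K + diag(1e-6, nrow(K)))
  m <- nrow(K)
  layout <- geno$layout
  n_pair <- nrow(layout)
  sm <- geno$sample_map
  cov_eff <- sm$age * params$age_effect +
    (sm$sex == "M") * params$sex_effect +
    (sm$batch == 2L) * params$batch_effect

  y <- r <- matrix(NA_real_, n_pair, m,
                   dimnames = list(layout$pair_id, sm$sample_id))
  asm_y_ref <- asm_r_ref <- asm_y_alt <- asm_r_alt <-
    matrix(NA_real_, n_pair, m, dimnames = dimnames(y))
  g_mat <- matrix(NA_real_, n_pair, m)

  reads_list <- if (emit_reads) vector("list", n_pair) else NULL

  mu_cpg <- truth$cpgs$mu[match(layout$cpg_id, truth$cpgs$cpg_id)]
  hascov <- truth$cpgs$has_covariates[match(layout$cpg_id, truth$cpgs$cpg_id)]
  beta <- truth$pairs$beta[match(layout$pair_id, truth$pairs$pair_id)]

  for (p in seq_len(n_pair)) {
    g <- sqrt(params$sigma_g2) * drop(crossprod(L, stats::rnorm(m)))
    e <- stats::rnorm(m, 0, sqrt(params$sigma_e2))
    eta0 <- mu_cpg[p] + (if (hascov[p]) cov_eff else 0) + g + e
    pA <- stats::plogis(eta0)              # reference allele copy (a = 0)
    pB <- stats::plogis(eta0 + beta[p])    # alternate allele copy (a = 1)
    g_mat[p, ] <- g

    rr <- stats::rnbinom(m, size = params$depth_size, mu = params$depth_mean)
    rr[stats::runif(m) < params$miss_rate] <- 0L
    dos <- geno$genotypes$dosage[layout$snp_id[p], ]
    rA <- ifelse(dos == 0L, rr, ifelse(dos == 2L, 0L, stats::rbinom(m, rr, 0.5)))
    rB <- rr - rA
    ## context split (OT/OB strands), then methylation per group
    rA_g <- stats::rbinom(m, rA, 0.5); rA_c <- rA - rA_g
    rB_g <- stats::rbinom(m, rB, 0.5); rB_c <- rB - rB_g
    yA_c <- stats::rbinom(m, rA_c, pA); yA_g <- stats::rbinom(m, rA_g, pA)
    yB_c <- stats::rbinom(m, rB_c, pB); yB_g <- stats::rbinom(m, rB_g, pB)
    y[p, ] <- yA_c + yA_g + yB_c + yB_g
    r[p, ] <- rr
    y[p, rr == 0L] <- NA; r[p, rr == 0L] <- NA

    ## allele-assignable (assessable) counts for heterozygotes, ignoring the
    ## error rate. A strand on which one of the SNP alleles is
    ## bisulfite-convertible is excluded outright: keeping its methylated
    ## (unconverted) reads would select on methylation state and bias the
    ## allele's methylation fraction. C/T SNPs are therefore assessed from
    ## OB ("G") strand reads only, A/G SNPs from OT ("C") strand reads only.
    het <- which(dos == 1L & rr > 0L)
    if (length(het)) {
      if (layout$ref[p] == "C") {          # C/T SNP: use OB strand only
        tot_ref <- rA_g[het]; met_ref <- yA_g[het]
        tot_alt <- rB_g[het]; met_alt <- yB_g[het]
      } else {                             # A/G SNP: use OT strand only
        tot_ref <- rA_c[het]; met_ref <- yA_c[het]
        tot_alt <- rB_c[het]; met_alt <- yB_c[het]
      }
      ok <- tot_ref + tot_alt > 0
      idx <- het[ok]
      asm_r_ref[p, idx] <- tot_ref[ok]; asm_y_ref[p, idx] <- met_ref[ok]
      asm_r_alt[p, idx] <- tot_alt[ok]; asm_y_alt[p, idx] <- met_alt[ok]
    }

    if (emit_reads) {
      reads_list[[p]] <- .tally_reads(
        p, layout, sm$sample_id, dos,
        rA_c, rA_g, rB_c, rB_g, yA_c, yA_g, yB_c, yB_g, params
      )
    }
  }

  pt <- pair_table(
    pairs = data.frame(layout,
                       maf = geno$genotypes$sites$maf[match(layout$snp_id,
                                                            rownames(geno$genotypes$dosage))],
                       stringsAsFactors = FALSE),
    samples = sm$sample_id,
    dosage = geno$genotypes$dosage[layout$snp_id, , drop = FALSE],
    y = y, r = r,
    asm_y_ref = asm_y_ref, asm_r_ref = asm_r_ref,
    asm_y_alt = asm_y_alt, asm_r_alt = asm_r_alt
  )
  pt$truth_g <- g_mat
  if (emit_reads) {
    reads <- do.call(rbind, reads_list)
    pt$reads <- reads
    pt$pileups <- .reads_to_pileups(reads, layout)
  }
  pt
}

## read groups -> observed-base tallies; one row per
## (sample, pair, context, true allele, methylation state, observed base)
.tally_reads <- function(p, layout, sample_ids, dos,
                         rA_c, rA_g, rB_c, rB_g,
                         yA_c, yA_g, yB_c, yB_g, params) {
  ref <- layout$ref[p]; alt <- layout$alt[p]
  groups <- list(
    list(allele = "ref", base = ref, context = "C", meth = TRUE,  n = yA_c),
    list(allele = "ref", base = ref, context = "C", meth = FALSE, n = rA_c - yA_c),
    list(allele = "ref", base = ref, context = "G", meth = TRUE,  n = yA_g),
    list(allele = "ref", base = ref, context = "G", meth = FALSE, n = rA_g - yA_g),
    list(allele = "alt", base = alt, context = "C", meth = TRUE,  n = yB_c),
    list(allele = "alt", base = alt, context = "C", meth = FALSE, n = rB_c - yB_c),
    list(allele = "alt", base = alt, context = "G", meth = TRUE,  n = yB_g),
    list(allele = "alt", base = alt, context = "G", meth = FALSE, n = rB_g - yB_g)
  )
  out <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    gk <- groups[[k]]
    pr <- .obs_base_probs(gk$base, gk$context, gk$meth,
                          params$conversion, params$error_rate)
    pos <- which(gk$n > 0)
    if (!length(pos)) next
    obs <- vapply(gk$n[pos], function(nn) {
      drop(stats::rmultinom(1L, nn, pr))
    }, numeric(4L))                        # 4 x length(pos)
    df <- data.frame(
      sample_id = rep(sample_ids[pos], each = 4L),
      pair_id = layout$pair_id[p], snp_id = layout$snp_id[p],
      context = gk$context, true_allele = gk$allele, methylated = gk$meth,
      obs_base = rep(c("A", "C", "G", "T"), length(pos)),
      n = as.vector(obs), stringsAsFactors = FALSE
    )
    out[[k]] <- df[df$n > 0, , drop = FALSE]
  }
  do.call(rbind, out)
}

## aggregate tagged reads into per (sample, SNP, context) base-count pileups
.reads_to_pileups <- function(reads, layout) {
  if (is.null(reads) || !nrow(reads)) return(NULL)
  key <- interaction(reads$sample_id, reads$snp_id, reads$context, drop = TRUE)
  agg <- lapply(split(reads, key), function(df) {
    counts <- vapply(c("A", "C", "G", "T"),
                     function(b) sum(df$n[df$obs_base == b]), 0)
    i <- match(df$snp_id[1], layout$snp_id)
    data.frame(sample_id = df$sample_id[1], chrom = layout$chrom[i],
               pos = layout$snp_pos[i], snp_id = df$snp_id[1],
               context = df$context[1],
               A = counts[1], C = counts[2], G = counts[3], T = counts[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$sample_id, out$snp_id, out$context), , drop = FALSE]
}

#' Simulate expression with shared cis effects and latent structure
#'
#' expression = mu + x beta_e + covariates + latent factors + u + eps with
#' u ~ MVN(0, sigma_u^2 K); latent factor scores are standard normal with
#' per-gene loadings, giving the latent-factor stage signal to remove.
#' RIN is generated as noise.
#'
#' @param geno,truth,params as elsewhere.
#' @return list with \code{expr} (genes x samples matrix), \code{covariates}
#'   (sample data.frame incl. RIN), \code{factors} (samples x n_latent
#'   scores), \code{loadings} (genes x n_latent).
#' @export
simulate_expression <- function(geno, truth, params) {
  set.seed(params$seed + 4L)
  K <- geno$K
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-6 * max(1, abs(ev))) stop("relatedness matrix is not positive semi-definite")
  m <- nrow(K)
  sm <- geno$sample_map
  genes <- truth$genes
  n_g <- nrow(genes)
  L <- chol(K + diag(1e-6, m))
  rin <- stats::rnorm(m, 7, 0.5)
  fac <- matrix(stats::rnorm(m * params$n_latent), m, params$n_latent)
  loadings <- matrix(stats::rnorm(n_g * params$n_latent, 0, params$latent_sd),
                     n_g, params$n_latent)
  covar <- sm$age * 0.01 + (sm$sex == "M") * 0.1 + (rin - 7) * 0.05
  expr <- matrix(NA_real_, n_g, m,
                 dimnames = list(genes$gene_id, sm$sample_id))
  for (j in seq_len(n_g)) {
    x <- if (is.na(genes$causal_snp[j])) rep(0, m) else
      geno$genotypes$dosage[genes$causal_snp[j], ]
    u <- sqrt(params$expr_sigma_u2) * drop(crossprod(L, stats::rnorm(m)))
    eps <- stats::rnorm(m, 0, sqrt(params$expr_sigma_e2))
    expr[j, ] <- stats::rnorm(1, 5, 1) + x * genes$beta_expr[j] + covar +
      drop(fac %*% loadings[j, ]) + u + eps
  }
  covariates <- data.frame(sample_id = sm$sample_id, age = sm$age,
                           sex = sm$sex, batch = sm$batch, rin = rin,
                           stringsAsFactors = FALSE)
  list(expr = expr, covariates = covariates, factors = fac,
       loadings = loadings)
}

#' Run the full generator
#'
#' Convenience wrapper calling \code{\link{simulate_pedigree_genotypes}},
#' \code{\link{simulate_truth}}, \code{\link{simulate_methylation_reads}}
#' and \code{\link{simulate_expression}} with one parameter list.
#'
#' @param params \code{\link{sim_params}}.
#' @param emit_reads forwarded to \code{\link{simulate_methylation_reads}}.
#' @param expression also simulate expression (default TRUE).
#' @return list with members geno, truth, pairs (pair_table), expression.
#' @export
simulate_study <- function(params, emit_reads = FALSE, expression = TRUE) {
  geno <- simulate_pedigree_genotypes(params)
  truth <- simulate_truth(geno, params)
  pairs <- simulate_methylation_reads(geno, truth, params, emit_reads)
  expr <- if (expression) simulate_expression(geno, truth, params) else NULL
  list(geno = geno, truth = truth, pairs = pairs, expression = expr)
}

#' Write generator output as standard files
#'
#' Emits VCF genotypes, methylated/total TSV count matrices, a pedigree TSV,
#' a truth TSV and a BED of CpG positions into \code{dir}.
#'
#' @param study output of \code{\link{simulate_study}}.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_study_files <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    meth = file.path(dir, "meth.tsv"), total = file.path(dir, "total.tsv"),
    pedigree = file.path(dir, "pedigree.tsv"),
    truth = file.path(dir, "truth_pairs.tsv"),
    cpgs = file.path(dir, "cpgs.bed")
  )
  write_vcf_genotypes(study$geno$genotypes, paths["vcf"])
  write_count_matrix(study$pairs$y, paths["meth"], "pair_id")
  write_count_matrix(study$pairs$r, paths["total"], "pair_id")
  write_pedigree(study$geno$pedigree, paths["pedigree"])
  utils::write.table(study$truth$pairs, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lay <- study$geno$layout
  cpg <- unique(lay[, c("chrom", "cpg_pos", "cpg_id")])
  write_bed_intervals(annotation_set(cpg$chrom, cpg$cpg_pos, cpg$cpg_pos + 1L,
                                     cpg$cpg_id), paths["cpgs"])
  invisible(paths)
}
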