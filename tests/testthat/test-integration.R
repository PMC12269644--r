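mk_meqtl <- function(chrom, pos, cpg, beta, sig) {
  data.frame(chrom = chrom, snp_pos = pos, cpg_id = cpg, beta = beta,
             significant = sig, stringsAsFactors = FALSE)
}
mk_eqtl <- function(snp, gene, beta, sig) {
  data.frame(snp_id = snp, gene_id = gene, beta = beta, significant = sig,
             stringsAsFactors = FALSE)
}

test_that("meQTL-eQTL overlap requires the exact genomic position", {
  meqtl <- mk_meqtl("chr1", c(100, 200, 300), c("c1", "c2", "c3"),
                    c(1, -2, 0.5), c(TRUE, TRUE, FALSE))
  eqtl <- mk_eqtl(c("sA", "sB"), c("g1", "g2"), c(0.7, -0.1), c(TRUE, TRUE))
  coords <- data.frame(snp_id = c("sA", "sB"), chrom = "chr1",
                       pos = c(100, 201))   # sB is 1 bp off
  trios <- intersect_meqtl_eqtl(meqtl, eqtl, coords)
  expect_equal(nrow(trios), 1)
  expect_equal(trios$gene_id, "g1")
  expect_true(trios$concordant)             # both effects positive
})

test_that("direction concordance: closed forms and enumeration oracle", {
  all_pos <- data.frame(chrom = "chr1", snp_pos = 1:12, cpg_id = "c",
                        gene_id = "g", beta_meth = 1, beta_expr = 1,
                        concordant = TRUE)
  dc <- direction_concordance(all_pos)
  expect_equal(dc$fraction, 1)
  expect_equal(dc$p_value, 2 * 0.5^12 * 1)  # both tails collapse to one point each...
  ## (two-sided exact test of 12/12 at p0 = 0.5)
  expect_equal(dc$p_value, binom.test(12, 12, 0.5)$p.value)

  half <- all_pos[1:10, ]
  half$concordant <- rep(c(TRUE, FALSE), 5)
  expect_equal(direction_concordance(half)$p_value, 1)

  six <- all_pos[1:10, ]
  six$concordant <- c(rep(TRUE, 6), rep(FALSE, 4))
  ## oracle: sum of point probabilities no larger than P(X = 6), X~Bin(10,.5)
  pk <- dbinom(0:10, 10, 0.5)
  p_oracle <- sum(pk[pk <= pk[7] + 1e-12])
  expect_equal(direction_concordance(six)$p_value, p_oracle, tolerance = 1e-12)
})

test_that("concordance is invariant to a joint sign flip", {
  set.seed(71)
  trios <- data.frame(chrom = "chr1", snp_pos = 1:30, cpg_id = "c",
                      gene_id = "g", beta_meth = rnorm(30),
                      beta_expr = rnorm(30))
  trios$concordant <- sign(trios$beta_meth) == sign(trios$beta_expr)
  flip <- trios
  flip$beta_meth <- -flip$beta_meth
  flip$beta_expr <- -flip$beta_expr
  flip$concordant <- sign(flip$beta_meth) == sign(flip$beta_expr)
  expect_equal(direction_concordance(trios)$fraction,
               direction_concordance(flip)$fraction)
})

test_that("Spearman correlation uses midranks and known values", {
  meth <- rbind(c1 = c(1, 2, 3, 4, 5) / 10)
  expr <- rbind(g1 = c(2, 1, 4, 3, 5))
  colnames(meth) <- colnames(expr) <- paste0("s", 1:5)
  trios <- data.frame(cpg_id = "c1", gene_id = "g1")
  res <- methylation_expression_correlation(meth, expr, trios)
  expect_equal(res$rho, 0.8)

  expr2 <- rbind(g1 = c(1, 2, 3, 4, 5)); colnames(expr2) <- colnames(meth)
  expect_equal(methylation_expression_correlation(meth, expr2, trios)$rho, 1)
  expr3 <- rbind(g1 = c(5, 4, 3, 2, 1)); colnames(expr3) <- colnames(meth)
  expect_equal(methylation_expression_correlation(meth, expr3, trios)$rho, -1)

  bad <- expr; colnames(bad)[1] <- "zz"
  expect_error(methylation_expression_correlation(meth, bad, trios),
               "not matched")
})

test_that("mapping summaries reproduce hand arithmetic on a fixture", {
  assoc <- data.frame(
    snp_id = c("s1", "s1", "s2", "s3", "s4"),
    cpg_id = c("c1", "c2", "c3", "c4", "c5"),
    beta = c(1, 2, -1, 3, 0.5),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  sm <- summarize_mapping_results(assoc)
  expect_equal(sm$n_pairs, 5)
  expect_equal(sm$pct_pairs_significant, 80)
  expect_equal(sm$n_unique_significant_snps, 3)
  expect_equal(sm$pct_cpgs_with_meqtl, 80)
  expect_equal(sm$mean_snps_per_cpg, 1)
  ## s1 is the only multi-CpG SNP and its betas share a sign
  expect_equal(sm$pct_multi_cpg_snps, 100 / 3)
  expect_equal(sm$pct_multi_cpg_snps_concordant, 100)
  assoc$beta[2] <- -2
  expect_equal(summarize_mapping_results(assoc)$pct_multi_cpg_snps_concordant, 0)
})

test_that("trio containment invariants hold on simulated integration", {
  set.seed(72)
  p <- sim_params(n_individuals = 70, n_cpgs = 60, n_genes = 20,
                  expr_frac_nonnull = 1, frac_shared_eqtl = 1, frac_nonnull = 0.6, seed = 72)
  st <- simulate_study(p, expression = TRUE)
  cov <- st$geno$sample_map[, c("sample_id", "age", "sex", "batch")]
  res <- map_meqtl(st$pairs, st$geno$K, covariates = cov)
  res$significant <- !is.na(res$p) & res$p < 0.01
  ex <- st$expression
  lf <- latent_factors_residualize(ex$expr,
                                   ex$covariates[, c("sample_id", "age", "sex")], 3)
  snps <- data.frame(snp_id = st$geno$layout$snp_id,
                     chrom = st$geno$layout$chrom,
                     pos = st$geno$layout$snp_pos)
  cp <- cis_pairing(snps, st$truth$genes, 200000)
  eq <- map_eqtl(lf$adjusted, st$geno$genotypes$dosage, cp,
                 genomic_relationship(st$geno$genotypes$dosage),
                 covariates = ex$covariates[, c("sample_id", "age", "sex", "rin")])
  trios <- intersect_meqtl_eqtl(res, eq, snps)
  if (nrow(trios)) {
    n_trio <- nrow(unique(trios[, c("chrom", "snp_pos", "cpg_id", "gene_id")]))
    n_sg <- nrow(unique(trios[, c("chrom", "snp_pos", "gene_id")]))
    n_gene <- length(unique(trios$gene_id))
    expect_gte(n_trio, n_sg)
    expect_gte(n_sg, n_gene)
    ## shared-effect SNPs are recovered in the trio set
    shared <- st$truth$genes$causal_snp[st$truth$genes$shared_with_meqtl]
    shared_pos <- st$geno$layout$snp_pos[match(shared, st$geno$layout$snp_id)]
    expect_gt(length(intersect(trios$snp_pos, shared_pos)), 0)
  } else {
    succeed("no trios at this size; containment vacuously true")
  }
})
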