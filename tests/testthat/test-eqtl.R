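test_that("latent-factor stage is the identity at zero factors and benign", {
  set.seed(61)
  m <- 60; g <- 300
  expr <- matrix(rnorm(g * m, 5), g, m,
                 dimnames = list(paste0("g", 1:g), paste0("s", 1:m)))
  covs <- data.frame(sample_id = paste0("s", 1:m), age = runif(m, 1, 20),
                     sex = sample(c("F", "M"), m, TRUE))
  id <- latent_factors_residualize(expr, covs, n_factors = 0)
  expect_identical(id$adjusted, expr)
  expect_error(latent_factors_residualize(expr, covs, n_factors = m),
               "smaller")
  ## no injected structure: adjustment leaves genes nearly unchanged
  ## (noise factors carry only ~1/m of any gene's variance)
  lf <- latent_factors_residualize(expr, covs, n_factors = 2)
  cors <- sapply(seq_len(g), function(i) cor(expr[i, ], lf$adjusted[i, ]))
  expect_gt(median(cors), 0.95)
  expect_gt(min(cors), 0.8)
})

test_that("a strong injected factor is removed", {
  set.seed(62)
  m <- 80; g <- 40
  fac <- rnorm(m)
  load <- rnorm(g, 0, 2)
  expr <- outer(load, fac) + matrix(rnorm(g * m, 0, 0.5), g, m)
  dimnames(expr) <- list(paste0("g", 1:g), paste0("s", 1:m))
  covs <- data.frame(sample_id = paste0("s", 1:m), age = runif(m, 1, 20),
                     sex = sample(c("F", "M"), m, TRUE))
  lf <- latent_factors_residualize(expr, covs, n_factors = 1)
  cors_before <- abs(sapply(seq_len(g), function(i) cor(expr[i, ], fac)))
  cors_after <- abs(sapply(seq_len(g), function(i) cor(lf$adjusted[i, ], fac)))
  expect_gt(median(cors_before), 0.7)
  expect_lt(max(cors_after), 0.1)
})

test_that("cis pairing respects the 200 kb boundary (body anchor)", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 500000L,
                      end = 510000L, strand = "+", tss = 500000L)
  snps <- data.frame(snp_id = c("in_body", "near", "far", "other_chrom"),
                     chrom = c("chr1", "chr1", "chr1", "chr2"),
                     pos = c(505000L, 510000L + 199999L, 510000L + 200001L,
                             505000L))
  cp <- cis_pairing(snps, genes, cis_window = 200000)
  expect_setequal(cp$snp_id, c("in_body", "near"))
  expect_equal(cp$distance[cp$snp_id == "in_body"], 0)
  ## TSS anchor measures from the transcription start instead
  cp_tss <- cis_pairing(snps, genes, cis_window = 200000, anchor = "tss")
  expect_false("near" %in% cp_tss$snp_id)   # 209999 bp from the TSS
})

test_that("the LMM collapses to OLS without genetic variance", {
  set.seed(63)
  m <- 50
  x <- rbinom(m, 2, 0.4)
  covs <- cbind(1, runif(m))
  y <- 0.6 * x + covs %*% c(1, 0.3) + rnorm(m, 0, 0.8)
  U <- diag(m); d <- rep(1, m)              # K = I
  fit <- asmqtl:::.lmm_reml_fit(drop(y), cbind(x, covs), d)
  ols <- lm(y ~ x + covs[, 2])
  expect_equal(fit$beta[1], unname(coef(ols)["x"]), tolerance = 1e-5)
  expect_equal(fit$se[1], unname(sqrt(vcov(ols)["x", "x"])), tolerance = 1e-4)
})

test_that("at a pinned variance ratio the LMM equals closed-form GLS", {
  set.seed(64)
  m <- 24
  A <- matrix(rnorm(m * m), m)
  K <- tcrossprod(A) / m
  e <- eigen(K, symmetric = TRUE)
  x <- rbinom(m, 2, 0.3)
  y <- 0.5 * x + drop(t(chol(K + diag(1e-8, m))) %*% rnorm(m)) + rnorm(m, 0, 0.5)
  X <- cbind(x, 1)
  delta <- 1.7
  Uy <- drop(crossprod(e$vectors, y))
  UX <- crossprod(e$vectors, X)
  pin <- log(delta)
  fit <- asmqtl:::.lmm_reml_fit(Uy, UX, e$values,
                                interval = c(pin, pin + 1e-9))
  V <- delta * K + diag(m)
  Vi <- solve(V)
  bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(fit$beta, drop(bhat), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("eQTL mapping finds planted effects and skips monomorphic SNPs", {
  set.seed(65)
  p <- sim_params(n_individuals = 90, n_cpgs = 40, n_genes = 16,
                  expr_frac_nonnull = 1, frac_shared_eqtl = 1, seed = 65)
  st <- simulate_study(p, expression = TRUE)
  ex <- st$expression
  lf <- latent_factors_residualize(ex$expr,
                                   ex$covariates[, c("sample_id", "age", "sex")],
                                   n_factors = 3)
  snps <- data.frame(snp_id = st$geno$layout$snp_id,
                     chrom = st$geno$layout$chrom,
                     pos = st$geno$layout$snp_pos)
  cp <- cis_pairing(snps, st$truth$genes, 200000)
  Kg <- genomic_relationship(st$geno$genotypes$dosage)
  ## plant a monomorphic SNP
  dos <- st$geno$genotypes$dosage
  dos[1, ] <- 0L
  eq <- map_eqtl(lf$adjusted, dos, cp, Kg,
                 covariates = ex$covariates[, c("sample_id", "age", "sex", "rin")])
  expect_false(st$geno$layout$snp_id[1] %in% eq$snp_id)
  causal <- st$truth$genes[!is.na(st$truth$genes$causal_snp) &
                             st$truth$genes$causal_snp != st$geno$layout$snp_id[1], ]
  hit <- eq[paste(eq$snp_id, eq$gene_id) %in%
              paste(causal$causal_snp, causal$gene_id), ]
  other <- eq[!paste(eq$snp_id, eq$gene_id) %in%
                paste(causal$causal_snp, causal$gene_id), ]
  expect_lt(median(hit$p), 0.05)
  expect_gt(median(other$p), 0.2)
  ## effect signs align with the planted effects
  expect_gt(cor(hit$beta,
                causal$beta_expr[match(paste(hit$snp_id, hit$gene_id),
                                       paste(causal$causal_snp,
                                             causal$gene_id))]), 0.7)
})

test_that("eQTL power is monotone in effect size and in MAF", {
  set.seed(66)
  m <- 100
  U <- diag(m)
  reject_rate <- function(beta, maf, n_rep = 60) {
    mean(replicate(n_rep, {
      x <- rbinom(m, 2, maf)
      if (length(unique(x)) < 2) return(NA)
      y <- beta * x + rnorm(m)
      fit <- asmqtl:::.lmm_reml_fit(y, cbind(x, 1), rep(1, m))
      2 * pnorm(-abs(fit$beta[1] / fit$se[1])) < 0.05
    }), na.rm = TRUE)
  }
  expect_lt(reject_rate(0.15, 0.3), reject_rate(0.6, 0.3))
  expect_lt(reject_rate(0.25, 0.05), reject_rate(0.25, 0.4))
})
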