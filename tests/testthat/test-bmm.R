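test_that("with variance components pinned at zero the fit is grouped logistic", {
  set.seed(41)
  for (rep in 1:5) {
    m <- 40 + rep * 5
    K <- identity_k(m)
    dos <- sample(0:2, m, replace = TRUE, prob = c(0.4, 0.45, 0.15))
    r <- rpois(m, 18) + 3
    y <- rbinom(m, r, plogis(-0.4 + 0.9 * dos / 2))
    fit <- meqtl_bmm(y, r, dos, K, mode = "genotype_only", sigma = c(0, 0))
    gl <- glm(cbind(y, r - y) ~ I(dos / 2), family = binomial)
    expect_equal(fit$beta, unname(coef(gl)[2]), tolerance = 1e-6)
    expect_equal(fit$mu, unname(coef(gl)[1]), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(vcov(gl)[2, 2])), tolerance = 1e-4)
  }
})

test_that("monomorphic pairs error; table mapping flags them instead", {
  m <- 20
  K <- identity_k(m)
  r <- rep(10, m); y <- rbinom(m, 10, 0.5)
  expect_error(meqtl_bmm(y, r, rep(1, m), K), "monomorphic")

  pt <- one_pair_table(y, r, rep(2, m))
  res <- map_meqtl(pt, K)
  expect_equal(res$status, "monomorphic")
  expect_true(is.na(res$beta))
})

test_that("ASM and genotype-only modes coincide on homozygote-only data", {
  set.seed(42)
  m <- 30
  K <- identity_k(m)
  dos <- rep(c(0, 2), each = 15)
  r <- rpois(m, 20) + 5
  y <- rbinom(m, r, plogis(0.2 + 0.7 * dos / 2))
  pt <- one_pair_table(y, r, dos)          # no heterozygotes, no ASM
  a <- map_meqtl(pt, K, mode = "asm")
  g <- map_meqtl(pt, K, mode = "genotype_only")
  expect_equal(a$beta, g$beta, tolerance = 1e-10)
  expect_equal(a$se, g$se, tolerance = 1e-10)
  expect_false(a$used_asm)
})

test_that("ASM rows enter the design and sharpen the genotype estimate", {
  set.seed(43)
  m <- 80
  K <- identity_k(m)
  dos <- sample(0:2, m, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  r <- rpois(m, 24) + 6
  beta <- 1
  pA <- plogis(-0.2); pB <- plogis(-0.2 + beta)
  rA <- ifelse(dos == 0, r, ifelse(dos == 2, 0, rbinom(m, r, 0.5)))
  rB <- r - rA
  yA <- rbinom(m, rA, pA); yB <- rbinom(m, rB, pB)
  asm <- list(y_ref = ifelse(dos == 1, yA, NA), r_ref = ifelse(dos == 1, rA, NA),
              y_alt = ifelse(dos == 1, yB, NA), r_alt = ifelse(dos == 1, rB, NA))
  fit_asm <- meqtl_bmm(yA + yB, r, dos, K, asm = asm, mode = "asm")
  fit_g <- meqtl_bmm(yA + yB, r, dos, K, mode = "genotype_only")
  expect_true(fit_asm$used_asm)
  expect_lt(fit_asm$se, fit_g$se)
  expect_equal(fit_asm$beta, beta, tolerance = 0.35)
})

test_that("the Wald test reports a two-sided normal p from beta/SE", {
  fit <- structure(list(beta = 0.5, se = 0.5 / 1.96, p = 2 * pnorm(-1.96),
                        converged = TRUE), class = "meqtl_bmm")
  tt <- test_snp_cpg(fit)
  expect_equal(tt$p, 0.05, tolerance = 1e-3)
  fit$converged <- FALSE
  expect_true(is.na(test_snp_cpg(fit)$p))
})

test_that("genotype PVE follows the residual-variance construction", {
  set.seed(44)
  m <- 60
  K <- identity_k(m)
  dos <- sample(0:2, m, replace = TRUE)
  r <- rep(50, m)
  y <- rbinom(m, r, 0.5)
  pt <- one_pair_table(y, r, dos)
  ## beta = 0 gives PVE 0
  fits0 <- data.frame(beta = 0)
  expect_equal(compute_pve_genotype(pt, fits0), 0)
  ## constructed data where genotype explains all residual variance:
  ## y chosen so the empirical logit is exactly beta * dosage/2
  b <- 1.2
  prob <- plogis(b * dos / 2)
  y2 <- round(prob * (r + 1) - 0.5)        # inverts the empirical logit
  pt2 <- one_pair_table(y2, r, dos)
  fits2 <- data.frame(beta = b)
  pve2 <- compute_pve_genotype(pt2, fits2)
  expect_gt(pve2, 0.95)
  ## adversarial large beta is clipped at 1
  fits3 <- data.frame(beta = 50)
  expect_lte(compute_pve_genotype(pt2, fits3), 1)
})

test_that("covariate PVE components are non-negative and sum to one", {
  set.seed(45)
  m <- 50
  K <- identity_k(m)
  covs <- data.frame(sample_id = paste0("s", 1:m),
                     age = runif(m, 1, 25),
                     sex = sample(c("F", "M"), m, TRUE),
                     batch = factor(sample(1:2, m, TRUE)))
  dos <- sample(0:2, m, replace = TRUE)
  r <- rpois(m, 25) + 5
  y <- rbinom(m, r, plogis(0.8 * dos / 2 + 0.02 * covs$age))
  pt <- one_pair_table(y, r, dos)
  fits <- map_meqtl(pt, K, covariates = covs, mode = "genotype_only")
  pv <- compute_pve_covariates(pt, fits, covs)
  comp <- unlist(pv[1, c("pve_genotype", "pve_age", "pve_sex", "pve_batch",
                         "pve_residual")])
  expect_true(all(comp >= 0))
  expect_equal(sum(comp), 1, tolerance = 1e-8)
  ## all-null covariates: their PVE is exactly zero
  fits0 <- fits
  fits0[grep("^alpha_", names(fits0))] <- 0
  pv0 <- compute_pve_covariates(pt, fits0, covs)
  expect_equal(pv0$pve_age + pv0$pve_sex + pv0$pve_batch, 0)
})

test_that("fitted values and residuals track the data", {
  set.seed(47)
  m <- 60
  K <- identity_k(m)
  dos <- sample(0:2, m, replace = TRUE)
  r <- rpois(m, 30) + 10
  y <- rbinom(m, r, plogis(-0.5 + 1.2 * dos / 2))
  fit <- meqtl_bmm(y, r, dos, K, mode = "genotype_only")
  pi_hat <- fitted(fit)
  expect_length(pi_hat, m)
  expect_true(all(pi_hat > 0 & pi_hat < 1))
  expect_gt(cor(pi_hat, y / r), 0.8)
  res <- residuals(fit, type = "pearson")
  expect_lt(abs(mean(res)), 0.2)
  expect_equal(residuals(fit, type = "response"), y / r - pi_hat,
               ignore_attr = TRUE)
  ## population prediction is monotone in dosage for a positive effect
  pr <- predict(fit, dosage = 0:2, type = "response")
  expect_true(all(diff(pr) > 0))
})

test_that("print/summary/coef methods expose the fit", {
  set.seed(46)
  m <- 30
  K <- identity_k(m)
  dos <- sample(0:2, m, replace = TRUE)
  r <- rpois(m, 20) + 5
  y <- rbinom(m, r, plogis(0.5 * dos / 2))
  fit <- meqtl_bmm(y, r, dos, K, mode = "genotype_only")
  expect_output(print(fit), "beta")
  expect_output(summary(fit), "variance components")
  expect_named(coef(fit)[1:2], c("(Intercept)", "genotype"))
  expect_equal(unname(vcov(fit)[1, 1]), fit$se^2)
})
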