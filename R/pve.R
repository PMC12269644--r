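## Variance decomposition: percent variance explained (PVE) by genotype and
## by demographic covariates.

#' PVE by genotype from residualized methylation ratios
#'
#' The methylation ratio is mapped to the empirical logit
#' log((y + 0.5)/(r - y + 0.5)), residualized on the covariates by ordinary
#' least squares, and the genotype PVE is
#' clip(beta^2 Var(dosage/2) / Var(residual), 0, 1), reconciling the
#' logit-scale effect estimate with the observed methylation variation.
#' Setting \code{residual_scale = "proportion"} instead residualizes the
#' raw methylation ratio (the alternative convention).
#'
#' @param pt \code{\link{pair_table}}.
#' @param fits association table from \code{\link{map_meqtl}} (needs
#'   \code{beta}).
#' @param covariates sample covariate data.frame.
#' @param residual_scale "logit" (default) or "proportion".
#' @return numeric vector of PVE in [0, 1] (NA where undefined: zero
#'   residual variance or missing beta).
#' @export
compute_pve_genotype <- function(pt, fits, covariates = NULL,
                                 residual_scale = c("logit", "proportion")) {
  residual_scale <- match.arg(residual_scale)
  stopifnot(nrow(fits) == nrow(pt$pairs))
  X <- .bmm_design(covariates, pt$samples)
  n <- nrow(pt$pairs)
  pve <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    b <- fits$beta[i]
    if (is.na(b)) next
    y <- pt$y[i, ]; r <- pt$r[i, ]
    obs <- !is.na(r) & r > 0
    if (sum(obs) < 3) next
    mtil <- if (residual_scale == "logit") {
      log((y[obs] + 0.5) / (r[obs] - y[obs] + 0.5))
    } else {
      y[obs] / r[obs]
    }
    res <- stats::lm.fit(X[obs, , drop = FALSE], mtil)$residuals
    v_res <- stats::var(res)
    if (!is.finite(v_res) || v_res <= 0) next
    v_g <- b^2 * stats::var(pt$dosage[i, obs] / 2)
    pve[i] <- min(1, max(0, v_g / v_res))
  }
  pve
}

#' PVE decomposition across predictors on the latent scale
#'
#' For each pair, the latent (logit) scale variance is decomposed as
#' \deqn{PVE_k = Var(\hat\theta_k x_k) / (\sum_j Var(\hat\theta_j x_j) +
#'       \hat\sigma_g^2 + \hat\sigma_e^2)}
#' over the predictors genotype (dosage/2), age, sex and batch. Pairs whose
#' total estimated variance is not positive are flagged excluded.
#'
#' @param pt \code{\link{pair_table}}.
#' @param fits association table from a genotype-only
#'   \code{\link{map_meqtl}} run with covariate effects kept (columns
#'   \code{alpha_*}).
#' @param covariates sample covariate data.frame with columns among
#'   age, sex, batch.
#' @return data.frame with pve_genotype, pve_age, pve_sex, pve_batch,
#'   pve_residual, sigma2_total, included.
#' @export
compute_pve_covariates <- function(pt, fits, covariates) {
  stopifnot(nrow(fits) == nrow(pt$pairs))
  X <- .bmm_design(covariates, pt$samples)
  acols <- grep("^alpha_", names(fits), value = TRUE)
  ## map alpha columns back to design columns (drop intercept)
  dn <- sub("^alpha_", "", acols)
  keep <- dn != "(Intercept)"
  acols <- acols[keep]; dn <- dn[keep]
  n <- nrow(pt$pairs)
  out <- data.frame(pve_genotype = rep(NA_real_, n), pve_age = NA_real_,
                    pve_sex = NA_real_, pve_batch = NA_real_,
                    pve_residual = NA_real_, sigma2_total = NA_real_,
                    included = FALSE)
  classify <- function(nm) {
    if (grepl("age", nm, ignore.case = TRUE)) "age"
    else if (grepl("sex", nm, ignore.case = TRUE)) "sex"
    else if (grepl("batch", nm, ignore.case = TRUE)) "batch"
    else "other"
  }
  grp <- vapply(dn, classify, "")
  for (i in seq_len(n)) {
    if (is.na(fits$beta[i])) next
    obs <- !is.na(pt$r[i, ]) & pt$r[i, ] > 0
    if (sum(obs) < 3) next
    vg <- fits$beta[i]^2 * stats::var(pt$dosage[i, obs] / 2)
    vcov_k <- c(age = 0, sex = 0, batch = 0)
    for (j in seq_along(acols)) {
      if (grp[j] == "other") next
      a <- fits[[acols[j]]][i]
      if (is.na(a)) next
      vcov_k[grp[j]] <- vcov_k[grp[j]] +
        a^2 * stats::var(X[obs, dn[j]])
    }
    s2 <- fits$sigma_g2[i] + fits$sigma_e2[i]
    tot <- vg + sum(vcov_k) + s2
    if (!is.finite(tot) || tot <= 0) next
    out$pve_genotype[i] <- vg / tot
    out$pve_age[i] <- vcov_k["age"] / tot
    out$pve_sex[i] <- vcov_k["sex"] / tot
    out$pve_batch[i] <- vcov_k["batch"] / tot
    out$pve_residual[i] <- s2 / tot
    out$sigma2_total[i] <- tot
    out$included[i] <- s2 > 1e-6
  }
  out
}
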