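## cis-eQTL mapping: latent-factor adjustment of expression and a linear
## mixed model with a genomic-relatedness random effect.

#' Latent-factor adjustment of an expression matrix
#'
#' Protects age and sex, then removes broad latent structure: expression is
#' first residualized on (intercept + protected covariates) per gene, the
#' top \code{n_factors} principal factors of those residuals are extracted
#' (right singular vectors over samples), and the original expression is
#' residualized on the factors. \code{n_factors = 0} returns the input.
#'
#' @param expr genes x samples matrix.
#' @param covariates data.frame with the protected covariates (age, sex;
#'   optional sample_id column aligned to \code{colnames(expr)}).
#' @param n_factors number of factors to remove (< number of samples).
#' @return list with \code{adjusted} (genes x samples) and \code{factors}
#'   (samples x n_factors).
#' @export
latent_factors_residualize <- function(expr, covariates, n_factors = 5) {
  m <- ncol(expr)
  if (n_factors >= m) stop("n_factors must be smaller than the sample count")
  if (n_factors == 0) {
    return(list(adjusted = expr, factors = matrix(0, m, 0)))
  }
  X <- .bmm_design(covariates, colnames(expr))
  resid1 <- t(stats::lm.fit(X, t(expr))$residuals)
  sv <- svd(scale(t(resid1), center = TRUE, scale = FALSE), nu = n_factors, nv = 0)
  fac <- sv$u[, seq_len(n_factors), drop = FALSE]    # samples x k
  Xf <- cbind(1, fac)
  adjusted <- t(stats::lm.fit(Xf, t(expr))$residuals)
  dimnames(adjusted) <- dimnames(expr)
  list(adjusted = adjusted, factors = fac)
}

#' Pair SNPs with genes within a cis window
#'
#' A SNP pairs with a gene when its distance to the nearest gene-body
#' boundary (0 inside the body) is at most \code{cis_window}; with
#' \code{anchor = "tss"} the distance is measured to the TSS instead. SNPs
#' may map to multiple genes.
#'
#' @param snps data.frame snp_id, chrom, pos.
#' @param genes gene model data.frame (gene_id, chrom, start, end, strand,
#'   tss).
#' @param cis_window maximum distance in bp.
#' @param anchor "body" (default) or "tss".
#' @return data.frame snp_id, gene_id, distance.
#' @export
cis_pairing <- function(snps, genes, cis_window = 200000,
                        anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  out <- list(); k <- 0L
  for (j in seq_len(nrow(genes))) {
    on_chr <- snps[snps$chrom == genes$chrom[j], , drop = FALSE]
    if (!nrow(on_chr)) next
    d <- if (anchor == "body") {
      pmax(0, genes$start[j] - on_chr$pos, on_chr$pos - genes$end[j])
    } else {
      abs(on_chr$pos - genes$tss[j])
    }
    hit <- d <= cis_window
    if (!any(hit)) next
    k <- k + 1L
    out[[k]] <- data.frame(snp_id = on_chr$snp_id[hit],
                           gene_id = genes$gene_id[j],
                           distance = d[hit], stringsAsFactors = FALSE)
  }
  if (!k) return(data.frame(snp_id = character(0), gene_id = character(0),
                            distance = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## REML fit of y = X b + u + eps, u ~ N(0, sg2 K), eps ~ N(0, se2 I),
## profiled over the variance ratio delta = sg2/se2 in the eigenbasis of K.
## Uy, UX are the rotated response/design; d the eigenvalues of K.
.lmm_reml_fit <- function(Uy, UX, d, interval = c(-10, 10)) {
  n <- length(Uy); p <- ncol(UX)
  nll <- function(logdel) {
    lam <- exp(logdel) * d + 1           # V = se2 * diag(lam)
    w <- 1 / lam
    XtWX <- crossprod(UX, UX * w)
    XtWy <- crossprod(UX, Uy * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(1e30)
    b <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r2 <- sum(w * (Uy - UX %*% b)^2)
    se2 <- r2 / (n - p)
    ## REML criterion
    (n - p) * log(se2) + sum(log(lam)) + 2 * sum(log(diag(ch))) + (n - p)
  }
  op <- stats::optimize(nll, interval)
  ## boundary refinement toward sg2 = 0
  if (nll(interval[1]) <= op$objective + 1e-8) op$minimum <- interval[1]
  logdel <- op$minimum
  lam <- exp(logdel) * d + 1
  w <- 1 / lam
  XtWX <- crossprod(UX, UX * w)
  XtWy <- crossprod(UX, Uy * w)
  ch <- chol(XtWX)
  b <- backsolve(ch, forwardsolve(t(ch), XtWy))
  se2 <- sum(w * (Uy - UX %*% b)^2) / (n - p)
  covb <- chol2inv(ch) * se2
  list(beta = drop(b), se = sqrt(diag(covb)), sigma_g2 = exp(logdel) * se2,
       sigma_e2 = se2, logdelta = logdel)
}

#' Map cis-eQTL with a linear mixed model
#'
#' For each SNP--gene pair, fits
#' \deqn{y = \mu + x \beta_e + \alpha'c + u + \epsilon, \quad
#'       u \sim MVN(0, \sigma^2 K),}
#' on the latent-factor-adjusted expression, with covariates age, sex and
#' RIN and the genomic relationship matrix K, by REML profiled over the
#' variance ratio (eigen-rotation of K shared across tests). Monomorphic
#' SNPs are skipped. Wald p-values and Storey/BH q-values at
#' \code{fdr_level}.
#'
#' @param adjusted genes x samples matrix
#'   (\code{\link{latent_factors_residualize}} output).
#' @param dosage SNPs x samples dosage matrix.
#' @param pairs data.frame snp_id, gene_id (e.g. \code{\link{cis_pairing}}).
#' @param K_grm genomic relationship matrix
#'   (\code{\link{genomic_relationship}}).
#' @param covariates data.frame with age, sex, rin (and optionally
#'   sample_id).
#' @param fdr_level FDR level for the significance calls (default 0.20).
#' @return data.frame: snp_id, gene_id, beta, se, p, q, significant,
#'   sigma_g2, sigma_e2, n_samples.
#' @export
map_eqtl <- function(adjusted, dosage, pairs, K_grm, covariates = NULL,
                     fdr_level = 0.20) {
  samples <- colnames(adjusted)
  stopifnot(identical(samples, colnames(dosage)) || all(samples %in% colnames(dosage)))
  dosage <- dosage[, samples, drop = FALSE]
  e <- .k_eigen(K_grm, ridge = 1e-6)
  U <- e$vectors; d <- e$values
  Xc <- .bmm_design(covariates, samples)
  UXc <- crossprod(U, Xc)
  n <- length(samples)
  res <- vector("list", nrow(pairs))
  Uy_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene_id[i]; s <- pairs$snp_id[i]
    if (!g %in% rownames(adjusted) || !s %in% rownames(dosage)) next
    x <- dosage[s, ]
    if (length(unique(x[!is.na(x)])) < 2) next      # monomorphic
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    Uy <- get0(g, envir = Uy_cache)
    if (is.null(Uy)) {
      Uy <- drop(crossprod(U, adjusted[g, ]))
      assign(g, Uy, envir = Uy_cache)
    }
    UX <- cbind(drop(crossprod(U, x)), UXc)
    fit <- .lmm_reml_fit(Uy, UX, d)
    res[[i]] <- data.frame(
      snp_id = s, gene_id = g, beta = fit$beta[1], se = fit$se[1],
      p = 2 * stats::pnorm(-abs(fit$beta[1] / fit$se[1])),
      sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2, n_samples = n,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no testable SNP-gene pairs")
  rownames(out) <- NULL
  out$q <- bh_qvalues(out$p)
  out$significant <- !is.na(out$q) & out$q <= fdr_level
  out
}
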