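## The ASM-aware overdispersed binomial mixed model.

## Build the per-allele observation rows for a batch of pairs.
## ASM mode: one row per allele copy where allele-assignable reads exist
## (allele indicator a in {0,1}); heterozygotes without assignable reads
## contribute one row at a = 0.5 with their total counts; homozygotes one
## row at a in {0,1}. Genotype-only mode: one row per sample, a = dosage/2.
build_bmm_rows <- function(pt, mode = c("asm", "genotype_only")) {
  mode <- match.arg(mode)
  n <- nrow(pt$pairs)
  r <- pt$r; y <- pt$y; dmat <- pt$dosage
  obs <- !is.na(r) & r > 0
  pair_of <- function(idx) ((idx - 1L) %% n) + 1L
  samp_of <- function(idx) ((idx - 1L) %/% n) + 1L

  if (mode == "genotype_only") {
    idx <- which(obs)
    rows <- list(pair = pair_of(idx), samp = samp_of(idx),
                 y = y[idx], r = r[idx], a = dmat[idx] / 2)
    used_asm <- rep(FALSE, n)
  } else {
    hasA <- obs & dmat == 1 & !is.na(pt$asm_r_ref) & pt$asm_r_ref > 0
    hasB <- obs & dmat == 1 & !is.na(pt$asm_r_alt) & pt$asm_r_alt > 0
    het_noasm <- obs & dmat == 1 & !(hasA | hasB)
    hom <- obs & dmat != 1
    iH <- which(hom); iN <- which(het_noasm); iA <- which(hasA); iB <- which(hasB)
    rows <- list(
      pair = c(pair_of(iH), pair_of(iN), pair_of(iA), pair_of(iB)),
      samp = c(samp_of(iH), samp_of(iN), samp_of(iA), samp_of(iB)),
      y = c(y[iH], y[iN], pt$asm_y_ref[iA], pt$asm_y_alt[iB]),
      r = c(r[iH], r[iN], pt$asm_r_ref[iA], pt$asm_r_alt[iB]),
      a = c(dmat[iH] / 2, rep(0.5, length(iN)),
            rep(0, length(iA)), rep(1, length(iB)))
    )
    used_asm <- tabulate(pair_of(iA), n) + tabulate(pair_of(iB), n) > 0
  }
  ord <- order(rows$pair, rows$samp, rows$a)
  rows <- lapply(rows, `[`, ord)
  offsets <- c(0L, cumsum(tabulate(rows$pair, n)))
  ## polymorphism check among observed samples
  n_lev <- vapply(seq_len(n), function(i) {
    length(unique(dmat[i, obs[i, ]]))
  }, 0L)
  list(y = as.numeric(rows$y), r = as.numeric(rows$r), a = as.numeric(rows$a),
       sample0 = as.integer(rows$samp - 1L), offsets = as.integer(offsets),
       used_asm = used_asm, n_dosage_levels = n_lev)
}

## sample-level fixed design from a covariate data.frame (intercept first)
.bmm_design <- function(covariates, samples) {
  if (is.null(covariates)) {
    X <- matrix(1, length(samples), 1, dimnames = list(samples, "(Intercept)"))
    return(X)
  }
  if (!is.null(covariates$sample_id)) {
    stopifnot(all(samples %in% covariates$sample_id))
    covariates <- covariates[match(samples, covariates$sample_id), , drop = FALSE]
    covariates$sample_id <- NULL
  }
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  rownames(X) <- samples
  X
}

.k_eigen <- function(K, ridge = 1e-6) {
  K <- (K + t(K)) / 2
  e <- eigen(K + diag(ridge, nrow(K)), symmetric = TRUE)
  if (min(e$values) <= 0) stop("relatedness matrix not positive definite after ridge")
  e
}

#' Fit the ASM-aware binomial mixed model for one SNP--CpG pair
#'
#' Fits, by penalized quasi-likelihood, the overdispersed binomial mixed
#' model
#' \deqn{y_t \sim Binomial(r_t, \pi_t), \quad
#'       logit(\pi_t) = \mu + \beta a_t + \alpha' x_{i(t)} + u_{i(t)},}
#' \deqn{u \sim MVN(0, \sigma_g^2 K + \sigma_e^2 I),}
#' where rows t are allele copies: each heterozygote with allele-assignable
#' reads contributes one row per allele (allele indicator \eqn{a \in \{0,1\}}
#' as the genotype regressor), heterozygotes without assignable reads one
#' row at \eqn{a = 0.5}, and homozygotes one row at \eqn{a \in \{0,1\}}.
#' Random effects are shared across rows of a sample. The genotype-only
#' mode collapses to one row per sample with regressor dosage/2, so
#' \eqn{\beta} is per effect (non-reference) allele in both modes.
#'
#' @param y,r methylated / total read counts per sample (named or in the
#'   order of \code{rownames(K)}).
#' @param dosage non-reference-allele dosage (0/1/2) per sample.
#' @param K sample relatedness matrix (see
#'   \code{\link{build_relatedness_matrix}}).
#' @param covariates data.frame of sample covariates (e.g. batch, sex,
#'   age); an intercept is always included.
#' @param asm optional list with matrices or vectors \code{y_ref, r_ref,
#'   y_alt, r_alt}: per-allele counts for heterozygotes (NA elsewhere).
#' @param mode \code{"asm"} (default) or \code{"genotype_only"}.
#' @param tol convergence tolerance on the fixed effects and variance
#'   components (default 1e-5).
#' @param max_iter maximum PQL iterations (default 100).
#' @param ridge added to the diagonal of K for positive definiteness.
#' @param sigma optional length-2 numeric \code{c(sigma_g2, sigma_e2)}
#'   fixing the variance components instead of estimating them (both 0
#'   reduces the fit to a grouped logistic regression).
#' @param method variance-component criterion for the working model:
#'   \code{"reml"} (default, used for mapping) or \code{"ml"} (matches
#'   direct maximization of the integrated likelihood; mainly for
#'   small-sample cross-checks).
#' @return Object of class \code{meqtl_bmm} with elements \code{beta}
#'   (logit units per effect allele), \code{se}, \code{p} (two-sided Wald),
#'   \code{mu}, \code{alpha} (covariate effects), \code{sigma_g2},
#'   \code{sigma_e2}, \code{converged}, \code{n_obs}, \code{used_asm},
#'   \code{mode}.
#' @export
meqtl_bmm <- function(y, r, dosage, K, covariates = NULL, asm = NULL,
                      mode = c("asm", "genotype_only"),
                      tol = 1e-5, max_iter = 100, ridge = 1e-6,
                      sigma = NULL, method = c("reml", "ml")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  m <- nrow(K)
  stopifnot(length(y) == m, length(r) == m, length(dosage) == m)
  if (any(y > r, na.rm = TRUE)) stop("methylated counts exceed totals")
  obs <- !is.na(r) & r > 0
  if (length(unique(dosage[obs])) < 2) stop("monomorphic")
  samples <- rownames(K)
  if (is.null(samples)) samples <- paste0("s", seq_len(m))
  one <- function(v) matrix(v, nrow = 1)
  pt <- pair_table(
    pairs = data.frame(pair_id = "pair1", snp_id = "snp1", cpg_id = "cpg1",
                       chrom = "chr1", snp_pos = 1L, cpg_pos = 1L,
                       stringsAsFactors = FALSE),
    samples = samples, dosage = one(dosage), y = one(y), r = one(r),
    asm_y_ref = if (!is.null(asm)) one(asm$y_ref), asm_r_ref = if (!is.null(asm)) one(asm$r_ref),
    asm_y_alt = if (!is.null(asm)) one(asm$y_alt), asm_r_alt = if (!is.null(asm)) one(asm$r_alt)
  )
  rows <- build_bmm_rows(pt, mode)
  X <- .bmm_design(covariates, samples)
  e <- .k_eigen(K, ridge)
  fx <- if (is.null(sigma)) c(-1, -1) else sigma
  fit <- bmm_pql_batch(rows$y, rows$r, rows$a, rows$sample0, rows$offsets,
                       X, e$vectors, e$values, tol, max_iter,
                       fix_sg2 = fx[1], fix_se2 = fx[2],
                       use_ml = identical(method, "ml"))
  alpha <- fit[1, -(1:7)]
  names(alpha) <- colnames(X)
  out <- list(
    beta = fit[1, 1], se = fit[1, 2],
    p = 2 * stats::pnorm(-abs(fit[1, 1] / fit[1, 2])),
    mu = unname(alpha["(Intercept)"]),
    alpha = alpha[names(alpha) != "(Intercept)"],
    sigma_g2 = fit[1, 3], sigma_e2 = fit[1, 4],
    converged = fit[1, 5] == 1, n_obs = fit[1, 6], iterations = fit[1, 7],
    used_asm = rows$used_asm[1], mode = mode,
    rows = list(y = rows$y, r = rows$r, a = rows$a,
                sample = samples[rows$sample0 + 1L]),
    X = X, K = K, ridge = ridge,
    call = match.call()
  )
  class(out) <- "meqtl_bmm"
  out
}

## empirical-Bayes BLUP of the combined sample effect at the fitted
## parameter values (beta and variance components held fixed)
.bmm_blup <- function(object) {
  rows <- object$rows
  s_idx <- match(rows$sample, rownames(object$K))
  Xr <- cbind(rows$a, object$X[s_idx, , drop = FALSE])
  bvec <- c(object$beta, object$mu, object$alpha)
  eta_fix <- drop(Xr %*% bvec)
  m <- nrow(object$K)
  Sigma <- object$sigma_g2 * (object$K + diag(object$ridge, m)) +
    diag(object$sigma_e2 + 1e-10, m)
  Sinv <- solve(Sigma)
  u <- numeric(m)
  for (it in 1:50) {
    eta <- eta_fix + u[s_idx]
    mu_t <- stats::plogis(eta)
    w <- pmax(rows$r * mu_t * (1 - mu_t), 1e-6)
    z_res <- (eta - eta_fix) + (rows$y - rows$r * mu_t) / w
    T <- as.vector(tapply(w, factor(s_idx, levels = seq_len(m)), sum,
                          default = 0))
    q <- as.vector(tapply(w * z_res, factor(s_idx, levels = seq_len(m)),
                          sum, default = 0))
    u_new <- solve(Sinv + diag(T), q)
    if (max(abs(u_new - u)) < 1e-8) { u <- u_new; break }
    u <- u_new
  }
  list(u = u, eta = eta_fix + u[s_idx])
}

#' @export
fitted.meqtl_bmm <- function(object, ...) {
  stats::plogis(.bmm_blup(object)$eta)
}

#' @export
residuals.meqtl_bmm <- function(object,
                                type = c("pearson", "deviance", "response"),
                                ...) {
  type <- match.arg(type)
  pi_hat <- fitted(object)
  y <- object$rows$y; r <- object$rows$r
  switch(type,
    response = y / r - pi_hat,
    pearson = (y - r * pi_hat) / sqrt(pmax(r * pi_hat * (1 - pi_hat), 1e-12)),
    deviance = {
      ll <- stats::dbinom(y, r, pi_hat, log = TRUE)
      ll_sat <- stats::dbinom(y, r, ifelse(r > 0, y / r, 0), log = TRUE)
      sign(y / r - pi_hat) * sqrt(pmax(2 * (ll_sat - ll), 0))
    })
}

#' @export
predict.meqtl_bmm <- function(object, dosage = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(dosage)) {
    eta <- .bmm_blup(object)$eta
  } else {
    ## population-level prediction at new dosages, average covariate profile
    xbar <- colMeans(object$X)
    eta <- object$beta * dosage / 2 + drop(crossprod(xbar, c(object$mu, object$alpha)))
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
print.meqtl_bmm <- function(x, ...) {
  cat(sprintf("Binomial mixed model (%s mode%s)\n", x$mode,
              if (x$used_asm) ", with ASM rows" else ""))
  cat(sprintf("  beta = %.4f (SE %.4f), Wald p = %.3g\n", x$beta, x$se, x$p))
  cat(sprintf("  sigma_g^2 = %.4f, sigma_e^2 = %.4f, %s in %d iterations\n",
              x$sigma_g2, x$sigma_e2,
              if (x$converged) "converged" else "NOT converged",
              as.integer(x$iterations)))
  invisible(x)
}

#' @export
summary.meqtl_bmm <- function(object, ...) {
  co <- c("(Intercept)" = object$mu, genotype = object$beta, object$alpha)
  cat("Overdispersed binomial mixed model fit (PQL)\n\n")
  print(data.frame(estimate = co))
  cat(sprintf("\ngenotype: beta = %.4f, SE = %.4f, z = %.3f, p = %.3g\n",
              object$beta, object$se, object$beta / object$se, object$p))
  cat(sprintf("variance components: sigma_g^2 = %.4f (kinship), sigma_e^2 = %.4f (independent)\n",
              object$sigma_g2, object$sigma_e2))
  cat(sprintf("%d observation rows; %s\n", as.integer(object$n_obs),
              if (object$converged) "converged" else "not converged"))
  invisible(object)
}

#' @export
coef.meqtl_bmm <- function(object, ...) {
  c("(Intercept)" = object$mu, genotype = object$beta, object$alpha)
}

#' @export
vcov.meqtl_bmm <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("genotype", "genotype"))
}

#' Map meQTL over a pair table
#'
#' Fits the binomial mixed model to every SNP--CpG pair and returns the
#' association table. Monomorphic pairs are reported with NA estimates and
#' \code{status = "monomorphic"}; non-converged fits keep their estimates
#' but \code{p} is set to NA (they are excluded downstream).
#'
#' @param pt \code{\link{pair_table}}.
#' @param K sample relatedness matrix.
#' @param covariates sample covariate data.frame (batch, sex, age).
#' @param mode \code{"asm"} or \code{"genotype_only"}.
#' @param tol,max_iter,ridge fitting controls (see \code{\link{meqtl_bmm}}).
#' @param keep_alpha keep covariate effect columns (default TRUE).
#' @param sigma optional fixed variance components (see
#'   \code{\link{meqtl_bmm}}).
#' @return data.frame: pair identifiers, beta, se, p, sigma_g2, sigma_e2,
#'   converged, n_obs, used_asm, status, covariate effects.
#' @export
map_meqtl <- function(pt, K, covariates = NULL, mode = c("asm", "genotype_only"),
                      tol = 1e-5, max_iter = 100, ridge = 1e-6,
                      keep_alpha = TRUE, sigma = NULL) {
  mode <- match.arg(mode)
  e <- .k_eigen(K, ridge)
  X <- .bmm_design(covariates, pt$samples)
  .map_meqtl_eigen(pt, e, X, mode, tol, max_iter, keep_alpha, sigma)
}

## internal: mapping with a pre-decomposed K (shared across permutations);
## theta_init (n_pairs x 2 of sg2, se2) warm-starts the variance search
## with a reduced Nelder-Mead budget
.map_meqtl_eigen <- function(pt, e, X, mode, tol = 1e-5, max_iter = 100,
                             keep_alpha = TRUE, sigma = NULL,
                             theta_init = NULL) {
  rows <- build_bmm_rows(pt, mode)
  fx <- if (is.null(sigma)) c(-1, -1) else sigma
  ## warm-started refits: one short variance search from the observed
  ## optimum at the first iteration, then frozen (nm_later = 0)
  nm <- if (is.null(theta_init)) c(30L, 10L) else c(8L, 0L)
  fit <- bmm_pql_batch(rows$y, rows$r, rows$a, rows$sample0, rows$offsets,
                       X, e$vectors, e$values, tol, max_iter,
                       nm_iter_first = nm[1], nm_iter_later = nm[2],
                       fix_sg2 = fx[1], fix_se2 = fx[2],
                       theta_init = theta_init)
  poly <- rows$n_dosage_levels >= 2
  out <- data.frame(
    pt$pairs[, intersect(c("pair_id", "snp_id", "cpg_id", "chrom",
                           "snp_pos", "cpg_pos", "maf"), names(pt$pairs))],
    beta = fit[, 1], se = fit[, 2],
    sigma_g2 = fit[, 3], sigma_e2 = fit[, 4],
    converged = fit[, 5] == 1, n_obs = fit[, 6],
    used_asm = rows$used_asm, mode = mode,
    stringsAsFactors = FALSE
  )
  out$status <- ifelse(!poly, "monomorphic",
                       ifelse(is.na(fit[, 1]), "failed",
                              ifelse(out$converged, "ok", "not_converged")))
  out[!poly, c("beta", "se", "sigma_g2", "sigma_e2")] <- NA_real_
  out$p <- ifelse(out$status == "ok",
                  2 * stats::pnorm(-abs(out$beta / out$se)), NA_real_)
  if (keep_alpha && ncol(X) > 0) {
    al <- fit[, -(1:7), drop = FALSE]
    colnames(al) <- paste0("alpha_", colnames(X))
    al[!poly, ] <- NA_real_
    out <- cbind(out, al)
  }
  rownames(out) <- NULL
  out
}

#' Wald test for one fitted pair
#'
#' @param fit a \code{\link{meqtl_bmm}} object.
#' @return one-row data.frame with beta, se, p (NA when not converged),
#'   converged.
#' @export
test_snp_cpg <- function(fit) {
  stopifnot(inherits(fit, "meqtl_bmm"))
  data.frame(beta = fit$beta, se = fit$se,
             p = if (fit$converged) fit$p else NA_real_,
             converged = fit$converged)
}
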