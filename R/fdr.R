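## Multiple testing: permutation-based empirical FDR for meQTL and
## Storey/BH q-values for eQTL and correlation scans.

#' Build the permutation null for a pair table
#'
#' For each chromosome, generates \code{n_perm} sample permutations (seeded
#' at \code{seed + chromosome index}, so chromosomes are independent and
#' runs reproducible), applies each jointly to the dosages and ASM
#' assignments of the chromosome's pairs
#' (\code{\link{permute_pair_genotypes}}), refits the full model, and
#' collects the null p-values.
#'
#' @param pt \code{\link{pair_table}}.
#' @param K relatedness matrix.
#' @param covariates sample covariate data.frame.
#' @param n_perm permutations per chromosome.
#' @param seed base seed.
#' @param mode model mode passed to the fitter.
#' @param tol,max_iter fitting controls.
#' @param observed optional association table from \code{\link{map_meqtl}}
#'   on the same pairs; its variance-component estimates warm-start the
#'   permuted refits (methylation data are unchanged under permutation, so
#'   the observed components are the natural starting values).
#' @return data.frame with columns perm, chrom, pair_id, p (one row per
#'   permuted fit; non-converged fits carry NA).
#' @export
permute_genotypes <- function(pt, K, covariates = NULL, n_perm = 10,
                              seed = 1L, mode = c("asm", "genotype_only"),
                              tol = 1e-5, max_iter = 100, observed = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("n_perm must be >= 1")
  e <- .k_eigen(K)
  X <- .bmm_design(covariates, pt$samples)
  m <- length(pt$samples)
  chroms <- sort(unique(pt$pairs$chrom))
  out <- vector("list", length(chroms) * n_perm)
  k <- 0L
  for (ci in seq_along(chroms)) {
    idx <- which(pt$pairs$chrom == chroms[ci])
    sub <- subset_pairs(pt, idx)
    th <- NULL
    if (!is.null(observed)) {
      j <- match(sub$pairs$pair_id, observed$pair_id)
      th <- cbind(observed$sigma_g2[j], observed$sigma_e2[j])
    }
    set.seed(seed + ci)
    for (pm in seq_len(n_perm)) {
      perm <- sample.int(m)
      ptp <- permute_pair_genotypes(sub, perm)
      fits <- .map_meqtl_eigen(ptp, e, X, mode, tol, max_iter,
                               keep_alpha = FALSE, theta_init = th)
      k <- k + 1L
      out[[k]] <- data.frame(perm = pm, chrom = chroms[ci],
                             pair_id = fits$pair_id, p = fits$p,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Empirical FDR from a permutation null
#'
#' Storey-style empirical-null FDR: for a threshold t,
#' \deqn{FDR(t) = \hat\pi_0 \cdot \overline{\#\{p_{null} \le t\}} /
#'       \max(1, \#\{p_{obs} \le t\})}
#' with the null count averaged over permutations and
#' \eqn{\hat\pi_0 = \min(1, \#\{p_{obs} > 0.5\} /
#' \overline{\#\{p_{null} > 0.5\}})} (single anchor lambda = 0.5, robust
#' with few permutations). The q-value of each test is the minimum FDR(t)
#' over thresholds at or above its p-value (monotone by construction);
#' permutations are pooled across chromosomes into one genome-wide null.
#'
#' @param p_obs observed p-values (NA allowed; NA tests get NA q).
#' @param null data.frame from \code{\link{permute_genotypes}} (or any
#'   data.frame with columns perm and p), or a numeric vector of pooled
#'   null p-values (then \code{n_perm} must be given).
#' @param n_perm number of permutations when \code{null} is a bare vector.
#' @param fdr_level significance level for the calls column.
#' @return data.frame with p, q, significant.
#' @export
empirical_fdr <- function(p_obs, null, n_perm = NULL, fdr_level = 0.05) {
  if (is.data.frame(null)) {
    n_perm <- length(unique(null$perm))
    p_null <- null$p
  } else {
    if (is.null(n_perm)) stop("n_perm required when null is a vector")
    p_null <- null
  }
  p_null <- p_null[!is.na(p_null)]
  if (!length(p_null)) stop("empty permutation null")
  ok <- !is.na(p_obs)
  po <- p_obs[ok]
  if (!length(po)) stop("no observed p-values")

  pi0 <- min(1, (sum(po > 0.5) / max(1e-12, sum(p_null > 0.5) / n_perm)))
  ord <- order(po)
  ps <- po[ord]
  n_null_le <- findInterval(ps, sort(p_null))        # #{p_null <= t}
  n_obs_le <- findInterval(ps, ps)                   # #{p_obs <= t}, tie-safe
  fdr_t <- pi0 * (n_null_le / n_perm) / pmax(1, n_obs_le)
  q_sorted <- rev(cummin(rev(pmin(1, fdr_t))))
  q <- rep(NA_real_, length(p_obs))
  q[ok][ord] <- q_sorted
  data.frame(p = p_obs, q = q, significant = !is.na(q) & q <= fdr_level)
}

#' Storey q-values with BH fallback
#'
#' Storey's q-values with the smoother estimate of \eqn{\pi_0} (natural
#' cubic smoothing spline of \eqn{\hat\pi_0(\lambda)} over a lambda grid,
#' evaluated at the largest lambda). For short vectors (< 100 tests), where
#' the \eqn{\pi_0} smoother is unstable, Benjamini-Hochberg adjusted
#' p-values are returned instead.
#'
#' @param p p-values (NA allowed).
#' @return q-values, same length and order as \code{p}.
#' @export
bh_qvalues <- function(p) {
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  n <- sum(ok)
  if (n == 0) return(q)
  if (n < 100) {
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    return(q)
  }
  po <- p[ok]
  lambda <- seq(0.05, 0.95, 0.05)
  pi0_l <- vapply(lambda, function(l) mean(po > l) / (1 - l), 0)
  sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(sp, x = max(lambda))$y
  pi0 <- min(1, max(pi0, 1 / n))
  ord <- order(po)
  ranked <- pi0 * po[ord] * n / seq_len(n)
  q[ok][ord] <- rev(cummin(rev(pmin(1, ranked))))
  q
}
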