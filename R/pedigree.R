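## Pedigree handling and the additive relationship (tabular) method.

#' Simulate a multi-generation pedigree
#'
#' Founders are unrelated; each later individual draws a sire and dam from
#' previously born males and females, so parents always precede offspring.
#'
#' @param n_individuals total pedigree size (>= 2).
#' @param founder_fraction fraction of individuals that are founders.
#' @return data.frame with columns id, sire, dam (NA for founders), sex
#'   ("M"/"F"), birth_year.
#' @export
simulate_pedigree <- function(n_individuals, founder_fraction = 0.4) {
  stopifnot(n_individuals >= 2)
  n_f <- max(2L, round(founder_fraction * n_individuals))
  n_f <- min(n_f, n_individuals)
  sex <- character(n_individuals)
  ## guarantee both sexes among founders
  sex[seq_len(n_f)] <- c("M", "F", sample(c("M", "F"), n_f - 2L, replace = TRUE))
  sire <- dam <- rep(NA_integer_, n_individuals)
  year <- rep(NA_real_, n_individuals)
  year[seq_len(n_f)] <- 2000 + sample.int(4L, n_f, replace = TRUE) - 1L
  if (n_f < n_individuals) {
    for (i in (n_f + 1L):n_individuals) {
      born <- seq_len(i - 1L)
      males <- born[sex[born] == "M"]
      females <- born[sex[born] == "F"]
      sire[i] <- if (length(males) == 1L) males else sample(males, 1L)
      dam[i] <- if (length(females) == 1L) females else sample(females, 1L)
      sex[i] <- sample(c("M", "F"), 1L)
      year[i] <- max(year[sire[i]], year[dam[i]]) + sample.int(3L, 1L)
    }
  }
  data.frame(id = seq_len(n_individuals), sire = sire, dam = dam,
             sex = sex, birth_year = year, stringsAsFactors = FALSE)
}

#' Additive relationship matrix from a pedigree (tabular method)
#'
#' Recursive tabular method: A[i,i] = 1 + A[s,d]/2 and
#' A[i,j] = (A[j,s] + A[j,d])/2, with unknown parents contributing 0.
#' The pedigree must be acyclic with parents preceding offspring; rows are
#' reordered internally if needed and an error is raised on cycles.
#'
#' @param pedigree data.frame with columns id, sire, dam.
#' @return n x n additive relationship matrix with ids as dimnames.
#' @export
additive_relationship <- function(pedigree) {
  ped <- .toposort_pedigree(pedigree)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- as.character(ped$id)
  s <- idx[as.character(ped$sire)]
  d <- idx[as.character(ped$dam)]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(si)) A[j, si] else 0
      ad_ <- if (!is.na(di)) A[j, di] else 0
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
  }
  ## return in the original id order
  ord <- as.character(pedigree$id)
  A[ord, ord]
}

.toposort_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  n <- nrow(ped)
  placed <- logical(n)
  order <- integer(0)
  known <- function(p) is.na(p) | as.character(p) %in% as.character(ped$id[placed])
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- remaining[known(ped$sire[remaining]) & known(ped$dam[remaining])]
    if (!length(ready)) stop("cyclic pedigree: no individual has both parents placed")
    placed[ready] <- TRUE
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  ped[order, , drop = FALSE]
}

#' Sample-level relatedness matrix
#'
#' Expands the individual-level additive relationship matrix to samples via
#' a sample-to-individual map. Two samples of the same individual get
#' relatedness 1 (repeated-measure link); the diagonal is 1 and entries are
#' capped at 1.
#'
#' @param pedigree data.frame (id, sire, dam, ...).
#' @param sample_map data.frame with columns sample_id, individual_id.
#' @return sample x sample relatedness matrix (dimnames = sample ids).
#' @export
build_relatedness_matrix <- function(pedigree, sample_map) {
  stopifnot(all(c("sample_id", "individual_id") %in% names(sample_map)))
  if (!all(as.character(sample_map$individual_id) %in% as.character(pedigree$id))) {
    stop("sample_map references individuals absent from the pedigree")
  }
  A <- additive_relationship(pedigree)
  ind <- as.character(sample_map$individual_id)
  K <- A[ind, ind, drop = FALSE]
  same <- outer(ind, ind, "==")
  K[same] <- 1
  K <- pmin(K, 1)
  ## capping inbred diagonals at 1 can leave negative eigenvalues;
  ## restore positive semi-definiteness by alternating projections between
  ## the PSD cone (eigenvalue clipping) and the entry cap, ending on the
  ## PSD side so the result is always usable as a covariance
  for (iter in 1:20) {
    ev <- eigen(K, symmetric = TRUE)
    if (min(ev$values) >= -1e-10) break
    K <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    K <- (K + t(K)) / 2
    if (iter < 20) K <- pmin(K, 1)
  }
  dimnames(K) <- list(sample_map$sample_id, sample_map$sample_id)
  K
}

#' Genomic relationship matrix from dosages
#'
#' Centered and scaled genotype relationship matrix
#' \eqn{K = Z Z' / c} with \eqn{Z = X - 2p} and
#' \eqn{c = 2 \sum_j p_j (1 - p_j)}, the usual GRM used as the random-effect
#' covariance in expression mapping. Missing dosages are mean-imputed.
#'
#' @param dosage sites x samples dosage matrix (0/1/2).
#' @return samples x samples GRM.
#' @export
genomic_relationship <- function(dosage) {
  p <- rowMeans(dosage, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  X <- dosage[keep, , drop = FALSE]
  p <- p[keep]
  for (i in seq_len(nrow(X))) X[i, is.na(X[i, ])] <- 2 * p[i]
  Z <- X - 2 * p
  crossprod(Z) / (2 * sum(p * (1 - p)))
}

#' Write / read a pedigree TSV
#' @param pedigree data.frame as from \code{\link{simulate_pedigree}}.
#' @param path file path.
#' @return path (write) or data.frame (read).
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(pedigree, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
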