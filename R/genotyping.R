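## Genotype calling from bisulfite pileups with a wildcard strategy, ASM
## extraction for heterozygotes, and concordance metrics.
##
## Bisulfite chemistry makes one base ambiguous per strand: on the
## C-converted (OT) strand an observed T may be a true T or an unmethylated
## converted C; on the G-converted (OB) strand an observed A may be a true A
## or a converted G. The caller treats those observations as wildcard
## evidence supporting both alleles equally.

.BASES <- c("A", "C", "G", "T")
.GENOTYPES <- {
  gt <- t(utils::combn(c("A", "C", "G", "T"), 2))
  gt <- rbind(cbind(.b1 = c("A", "C", "G", "T"), .b2 = c("A", "C", "G", "T")), gt)
  gt[order(gt[, 1], gt[, 2]), , drop = FALSE]
}

## support of observed base b for allele a under strand context
.allele_support <- function(b, a, context, eps) {
  if (b == a) return(1 - eps)
  if (context == "C" && b == "T" && a == "C") return(1 - eps)
  if (context == "G" && b == "A" && a == "G") return(1 - eps)
  eps / 3
}

#' Genotype posteriors from bisulfite pileups (wildcard strategy)
#'
#' Per-read likelihood of each of the 10 unordered diploid genotypes: an
#' observed base supports an allele with weight 1 - eps when it matches it
#' (the converted base of the strand context supports both of its source
#' alleles equally) and eps/3 otherwise; a read's genotype likelihood is
#' the mean of its two allele supports, the site likelihood the product
#' over reads, and the posterior normalizes over a uniform genotype prior.
#' Rows of \code{counts} from different strand contexts are combined by
#' multiplying likelihoods.
#'
#' @param counts named numeric vector (A, C, G, T) of observed base counts,
#'   or a matrix with those columns (one row per strand record).
#' @param context strand context per row: "C" (OT strand, C->T wildcard),
#'   "G" (OB strand, G->A wildcard) or "none".
#' @param eps sequencing error rate in (0, 0.5).
#' @return named posterior vector over the 10 genotypes ("A/A", "A/C", ...),
#'   or all NA for a zero-depth pileup.
#' @export
genotype_likelihoods <- function(counts, context = "C", eps = 0.01) {
  stopifnot(eps > 0, eps < 0.5)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  stopifnot(all(.BASES %in% colnames(counts)), nrow(counts) == length(context))
  gt_names <- paste(.GENOTYPES[, 1], .GENOTYPES[, 2], sep = "/")
  loglik <- stats::setNames(numeric(nrow(.GENOTYPES)), gt_names)
  depth <- sum(counts[, .BASES])
  if (depth == 0) return(stats::setNames(rep(NA_real_, length(gt_names)), gt_names))
  for (rec in seq_len(nrow(counts))) {
    for (b in .BASES) {
      n_b <- counts[rec, b]
      if (n_b == 0) next
      for (g in seq_len(nrow(.GENOTYPES))) {
        s <- 0.5 * .allele_support(b, .GENOTYPES[g, 1], context[rec], eps) +
          0.5 * .allele_support(b, .GENOTYPES[g, 2], context[rec], eps)
        loglik[g] <- loglik[g] + n_b * log(s)
      }
    }
  }
  po <- exp(loglik - max(loglik))
  po / sum(po)
}

## depth-dependent posterior threshold: stringency grows with depth
.dynamic_threshold <- function(depth) {
  pmin(0.999, 1 - 10^(-1 - depth / 10))
}

#' Call genotypes from pileup records
#'
#' Combines the strand records of each (sample, site), computes the
#' wildcard genotype posterior, and emits a call when the depth is at least
#' \code{depth_min}, the posterior clears the depth-dependent threshold
#' \code{min(0.999, 1 - 10^(-1 - depth/10))}, and every called minor allele
#' has at least 2 unambiguously supporting reads; otherwise a no-call with
#' the failing filter recorded.
#'
#' @param pileups data.frame with columns sample_id, chrom, pos, context
#'   ("C"/"G"/"none") and base counts A, C, G, T; one row per strand record.
#' @param eps sequencing error rate.
#' @param depth_min minimum combined depth.
#' @return data.frame: sample_id, chrom, pos, genotype ("X/Y" or NA),
#'   posterior, depth, filter ("PASS", "low_depth", "ambiguous",
#'   "low_allele_support").
#' @export
call_genotypes <- function(pileups, eps = 0.01, depth_min = 5) {
  req <- c("sample_id", "chrom", "pos", "context", .BASES)
  stopifnot(all(req %in% names(pileups)))
  key <- interaction(pileups$sample_id, pileups$chrom, pileups$pos, drop = TRUE)
  groups <- split(seq_len(nrow(pileups)), key)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    rows <- pileups[groups[[gi]], , drop = FALSE]
    counts <- as.matrix(rows[, .BASES, drop = FALSE])
    depth <- sum(counts)
    rec <- data.frame(sample_id = rows$sample_id[1], chrom = rows$chrom[1],
                      pos = rows$pos[1], genotype = NA_character_,
                      posterior = NA_real_, depth = depth,
                      filter = "PASS", stringsAsFactors = FALSE)
    if (depth < depth_min) {
      rec$filter <- "low_depth"
      out[[gi]] <- rec
      next
    }
    po <- genotype_likelihoods(counts, rows$context, eps)
    best <- which.max(po)
    rec$posterior <- unname(po[best])
    gt <- strsplit(names(po)[best], "/")[[1]]
    if (rec$posterior < .dynamic_threshold(depth)) {
      rec$filter <- "ambiguous"
      out[[gi]] <- rec
      next
    }
    ## unambiguous read support per called allele (wildcard-converted bases
    ## of a strand do not support their source allele)
    support <- vapply(unique(gt), function(a) {
      s <- 0
      for (r in seq_len(nrow(rows))) {
        s <- s + counts[r, a]
        ## on the vulnerable strand the convertible allele's support comes
        ## only from its unconverted (methylated) base, already counted
      }
      ## subtract nothing: counts of base a are unambiguous unless base a
      ## IS the converted form of another allele in the genotype
      for (r in seq_len(nrow(rows))) {
        ctx <- rows$context[r]
        amb <- (ctx == "C" && a == "T" && "C" %in% gt) ||
          (ctx == "G" && a == "A" && "G" %in% gt)
        if (amb) s <- s - counts[r, a]
      }
      s
    }, 0)
    if (length(unique(gt)) == 2 && min(support) < 2) {
      rec$filter <- "low_allele_support"
      out[[gi]] <- rec
      next
    }
    rec$genotype <- paste(gt, collapse = "/")
    out[[gi]] <- rec
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract allele-specific methylation counts for heterozygotes
#'
#' Partitions a heterozygote's allele-tagged reads by the allele their
#' observed SNP base matches. Reads from a strand on which either called
#' allele is bisulfite-convertible (C on the OT strand, G on the OB
#' strand) are discarded wholesale: on such a strand the convertible
#' allele's unmethylated reads show the converted base (e.g. T at a C/T
#' SNP on the OT strand) and are inseparable from the other allele, while
#' keeping only its methylated reads would select on methylation state and
#' bias the allele's methylation fraction. Remaining reads are assigned by
#' exact base match; error bases matching neither allele are dropped.
#' Homozygous calls yield no record.
#'
#' @param reads data.frame of read tallies with columns sample_id, snp_id,
#'   context, obs_base, methylated (logical), n.
#' @param calls genotype calls (\code{\link{call_genotypes}}-shaped) with
#'   sample_id, snp_id or (chrom, pos), genotype.
#' @param snp_info data.frame snp_id, ref, alt mapping observed alleles to
#'   the ref/alt labels.
#' @return data.frame: sample_id, snp_id, meth_ref, total_ref, meth_alt,
#'   total_alt, one_allele_only flag; one row per heterozygous
#'   (sample, SNP) with at least one assignable read.
#' @export
extract_allele_specific_counts <- function(reads, calls, snp_info) {
  stopifnot(all(c("sample_id", "snp_id", "context", "obs_base",
                  "methylated", "n") %in% names(reads)))
  if (!"snp_id" %in% names(calls)) stop("calls need a snp_id column")
  het <- calls[!is.na(calls$genotype) &
                 vapply(strsplit(calls$genotype, "/"),
                        function(g) g[1] != g[2], TRUE), , drop = FALSE]
  if (!nrow(het)) return(NULL)
  key <- paste(reads$sample_id, reads$snp_id)
  het_key <- paste(het$sample_id, het$snp_id)
  reads <- reads[key %in% het_key, , drop = FALSE]
  if (!nrow(reads)) return(NULL)
  gt <- strsplit(het$genotype[match(paste(reads$sample_id, reads$snp_id),
                                    het_key)], "/")
  assigned <- mapply(function(b, ctx, g) {
    ## strand exclusion: either allele convertible on this strand
    if ((ctx == "C" && "C" %in% g) || (ctx == "G" && "G" %in% g)) {
      return(NA_character_)
    }
    hit <- g == b
    if (sum(hit) == 1) g[hit] else NA_character_
  }, reads$obs_base, reads$context, gt)
  keep <- !is.na(assigned)
  reads <- reads[keep, , drop = FALSE]
  assigned <- assigned[keep]
  if (!nrow(reads)) return(NULL)
  ref <- snp_info$ref[match(reads$snp_id, snp_info$snp_id)]
  is_ref <- assigned == ref
  agg <- stats::aggregate(
    cbind(meth_ref = reads$n * reads$methylated * is_ref,
          total_ref = reads$n * is_ref,
          meth_alt = reads$n * reads$methylated * (!is_ref),
          total_alt = reads$n * (!is_ref)),
    by = list(sample_id = reads$sample_id, snp_id = reads$snp_id), FUN = sum)
  agg$one_allele_only <- agg$total_ref == 0 | agg$total_alt == 0
  agg[order(agg$snp_id, agg$sample_id), , drop = FALSE]
}

#' Genotype concordance between two call sets
#'
#' Agreement over the positions called in both sets: overall, and
#' restricted to positions where the first (reference) set is homozygous.
#'
#' @param calls_a,calls_b data.frames with sample_id, chrom, pos, genotype
#'   (NA = no-call). \code{calls_a} is the reference set for the
#'   homozygous-site restriction.
#' @return list with overall_pct, homozygous_pct, n_compared, n_homozygous.
#' @export
genotype_concordance <- function(calls_a, calls_b) {
  norm_gt <- function(g) {
    vapply(strsplit(g, "/"), function(x) paste(sort(x), collapse = "/"), "")
  }
  a <- calls_a[!is.na(calls_a$genotype), , drop = FALSE]
  b <- calls_b[!is.na(calls_b$genotype), , drop = FALSE]
  key_a <- paste(a$sample_id, a$chrom, a$pos)
  key_b <- paste(b$sample_id, b$chrom, b$pos)
  common <- intersect(key_a, key_b)
  if (!length(common)) stop("no positions called in both sets")
  ga <- norm_gt(a$genotype[match(common, key_a)])
  gb <- norm_gt(b$genotype[match(common, key_b)])
  agree <- ga == gb
  hom <- vapply(strsplit(ga, "/"), function(x) x[1] == x[2], TRUE)
  list(overall_pct = 100 * mean(agree),
       homozygous_pct = if (any(hom)) 100 * mean(agree[hom]) else NA_real_,
       n_compared = length(common), n_homozygous = sum(hom))
}
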