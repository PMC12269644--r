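test_that("genotype posteriors normalize and recover clear signals", {
  counts <- c(A = 0, C = 0, G = 20, T = 0)
  po <- genotype_likelihoods(counts, context = "C", eps = 0.01)
  expect_equal(sum(po), 1)
  ## oracle: direct Bayes computation for the GG posterior
  support <- function(b, a) {
    if (b == a) return(0.99)
    if (b == "T" && a == "C") return(0.99)   # context "C" wildcard
    0.01 / 3
  }
  gts <- names(po)
  lik <- sapply(strsplit(gts, "/"), function(g) {
    (0.5 * support("G", g[1]) + 0.5 * support("G", g[2]))^20
  })
  expect_equal(unname(po["G/G"]), lik[gts == "G/G"] / sum(lik),
               tolerance = 1e-12)
  expect_gt(po["G/G"], 0.99)
})

test_that("A/G heterozygote evidence is recovered by enumeration", {
  counts <- c(A = 10, C = 0, G = 10, T = 0)
  po <- genotype_likelihoods(counts, context = "none", eps = 0.01)
  expect_equal(names(which.max(po)), "A/G")
  ## enumeration oracle over the 10 genotypes
  support <- function(b, a, eps = 0.01) if (b == a) 1 - eps else eps / 3
  lik <- sapply(strsplit(names(po), "/"), function(g) {
    (0.5 * support("A", g[1]) + 0.5 * support("A", g[2]))^10 *
      (0.5 * support("G", g[1]) + 0.5 * support("G", g[2]))^10
  })
  expect_equal(unname(po), unname(lik / sum(lik)), tolerance = 1e-12)
})

test_that("converted-strand C/T mixtures defer to opposite-strand evidence", {
  ## on the OT strand alone, T reads are wildcards: C/C (half-methylated)
  ## and C/T cannot be separated confidently in favour of C/T
  ot_only <- genotype_likelihoods(c(A = 0, C = 10, G = 0, T = 10),
                                  context = "C", eps = 0.01)
  expect_true(all(c("C/C", "C/T") %in% names(sort(ot_only, decreasing = TRUE)[1:2])))
  ## adding the OB strand (where C and T are both unambiguous) resolves it
  counts <- rbind(c(A = 0, C = 10, G = 0, T = 10),
                  c(A = 0, C = 10, G = 0, T = 10))
  both <- genotype_likelihoods(counts, context = c("C", "G"), eps = 0.01)
  expect_equal(names(which.max(both)), "C/T")
})

test_that("zero-depth pileups yield an undefined posterior", {
  po <- genotype_likelihoods(c(A = 0, C = 0, G = 0, T = 0), context = "C")
  expect_true(all(is.na(po)))
})

test_that("call filters: depth, dynamic threshold, minor-allele support", {
  mk <- function(A = 0, C = 0, G = 0, T = 0, ctx = "none") {
    data.frame(sample_id = "s1", chrom = "chr1", pos = 1, context = ctx,
               A = A, C = C, G = G, T = T)
  }
  expect_equal(call_genotypes(mk(A = 4), depth_min = 5)$filter, "low_depth")
  deep <- call_genotypes(mk(A = 30))
  expect_equal(deep$genotype, "A/A")
  expect_equal(deep$filter, "PASS")
  ## a near-het mixture with a single minor read is not called
  one_minor <- call_genotypes(mk(A = 4, G = 1))
  expect_true(is.na(one_minor$genotype))
  balanced <- call_genotypes(mk(A = 15, G = 15))
  expect_equal(balanced$genotype, "A/G")
  ## safety property: no emitted heterozygote ever rests on fewer than two
  ## unambiguous reads per allele
  grid <- expand.grid(A = 0:12, G = 0:12)
  grid <- grid[grid$A + grid$G >= 5, ]
  calls <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cbind(call_genotypes(mk(A = grid$A[i], G = grid$G[i])),
          nA = grid$A[i], nG = grid$G[i])
  }))
  hets <- calls[!is.na(calls$genotype) & calls$genotype == "A/G", ]
  expect_true(all(hets$nA >= 2 & hets$nG >= 2))
})

test_that("the dynamic posterior threshold grows with depth and caps", {
  thr <- asmqtl:::.dynamic_threshold(c(5, 20, 100))
  expect_true(all(diff(thr) >= 0))
  expect_equal(thr[3], 0.999)
  expect_equal(thr[1], 1 - 10^(-1.5))
})

test_that("ASM extraction tallies alleles and drops convertible strands", {
  reads <- data.frame(
    sample_id = "s1", snp_id = "snp1",
    context = c("none", "none", "none", "none"),
    obs_base = c("A", "A", "G", "G"),
    methylated = c(TRUE, FALSE, TRUE, FALSE),
    n = c(6, 2, 1, 7)
  )
  calls <- data.frame(sample_id = "s1", snp_id = "snp1", genotype = "A/G")
  info <- data.frame(snp_id = "snp1", ref = "A", alt = "G")
  rec <- extract_allele_specific_counts(reads, calls, info)
  expect_equal(rec$meth_ref, 6); expect_equal(rec$total_ref, 8)
  expect_equal(rec$meth_alt, 1); expect_equal(rec$total_alt, 8)
  expect_false(rec$one_allele_only)

  ## G-context reads are excluded for an A/G call (G converts there)
  reads$context <- "G"
  expect_null(extract_allele_specific_counts(reads, calls, info))

  ## all reads on one allele: record kept and flagged
  reads2 <- data.frame(sample_id = "s1", snp_id = "snp1", context = "none",
                       obs_base = "A", methylated = TRUE, n = 5)
  rec2 <- extract_allele_specific_counts(reads2, calls, info)
  expect_true(rec2$one_allele_only)
  expect_equal(rec2$total_alt, 0)

  ## homozygous calls yield nothing
  hom <- data.frame(sample_id = "s1", snp_id = "snp1", genotype = "A/A")
  expect_null(extract_allele_specific_counts(reads2, hom, info))
})

test_that("concordance handles identical and disjoint call sets", {
  calls <- data.frame(sample_id = "s1", chrom = "chr1", pos = c(1, 2, 3),
                      genotype = c("A/A", "A/G", "G/G"))
  cc <- genotype_concordance(calls, calls)
  expect_equal(cc$overall_pct, 100)
  expect_equal(cc$homozygous_pct, 100)
  expect_equal(cc$n_homozygous, 2)

  other <- transform(calls, pos = pos + 10)
  expect_error(genotype_concordance(calls, other), "no positions")

  ## unordered genotype strings still match
  flipped <- transform(calls, genotype = c("A/A", "G/A", "G/G"))
  expect_equal(genotype_concordance(calls, flipped)$overall_pct, 100)
})
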