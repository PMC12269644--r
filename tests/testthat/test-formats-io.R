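test_that("exact HWE test matches direct enumeration and known cases", {
  ## perfect Hardy-Weinberg proportions: p close to 1
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)

  ## oracle: enumerate heterozygote counts for (5, 1, 4) directly
  n_aa <- 5; n_ab <- 1; n_bb <- 4
  n <- n_aa + n_ab + n_bb
  n_minor <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- sapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    exp(lfactorial(n) - lfactorial(h) - lfactorial(hom_min) -
          lfactorial(hom_maj) + h * log(2) +
          lfactorial(n_minor) + lfactorial(2 * n - n_minor) -
          lfactorial(2 * n))
  })
  probs <- probs / sum(probs)
  p_oracle <- sum(probs[probs <= probs[hets == n_ab] + 1e-12])
  expect_equal(hwe_exact_test(n_aa, n_ab, n_bb), p_oracle, tolerance = 1e-10)

  ## monomorphic sites are uninformative
  expect_equal(hwe_exact_test(10, 0, 0), 1)
})

test_that("VCF reading applies MAF, HWE and missingness filters", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  ## 50 samples; site1 MAF 0.04; site2 perfect HWE; site3 6% missing
  n <- 50
  gt1 <- c(rep("0/1", 4), rep("0/0", n - 4))            # MAF 0.04
  gt2 <- c(rep("0/0", 12), rep("0/1", 26), rep("1/1", 12))
  gt3 <- c(rep("./.", 3), rep("0/1", 24), rep("0/0", 23))  # 6% missing
  write_test_vcf(tf, rep("chr1", 3), c(100, 200, 300),
                 rep("A", 3), rep("G", 3), rbind(gt1, gt2, gt3))
  gt <- read_vcf_genotypes(tf, maf_min = 0.05, hwe_p_min = 1e-8,
                           max_missing = 0.05)
  expect_equal(gt$sites$pos, 200)
  expect_setequal(gt$excluded$reason, c("maf", "missingness"))
  expect_equal(gt$excluded$pos[gt$excluded$reason == "maf"], 100)
  expect_equal(gt$excluded$pos[gt$excluded$reason == "missingness"], 300)
  ## dosage counts the non-reference allele
  expect_equal(unname(gt$dosage[1, 1]), 0L)
  expect_equal(sum(gt$dosage[1, ] == 1L), 26)
})

test_that("multi-allelic sites are skipped with a warning; bad lines error", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  gt <- rbind(rep(c("0/0", "0/1"), 10), rep(c("0/1", "1/1"), 10))
  write_test_vcf(tf, c("chr1", "chr1"), c(10, 20), c("A", "C"),
                 c("G,T", "T"), gt)
  expect_warning(res <- read_vcf_genotypes(tf, maf_min = 0, hwe_p_min = 0,
                                           max_missing = 1),
                 "multi-allelic")
  expect_equal(res$sites$pos, 20)

  bad <- withr::local_tempfile(fileext = ".vcf")
  lines <- readLines(tf)
  lines[5] <- paste(strsplit(lines[5], "\t")[[1]][1:5], collapse = "\t")
  writeLines(lines, bad)
  expect_error(read_vcf_genotypes(bad), "line 5")
})

test_that("VCF write/read round trip preserves dosages", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  n <- 30
  gt0 <- rbind(sample(c("0/0", "0/1", "1/1"), n, TRUE),
               sample(c("0/0", "0/1", "1/1"), n, TRUE))
  write_test_vcf(tf, c("chr1", "chr2"), c(5, 9), c("C", "A"), c("T", "G"), gt0)
  g1 <- read_vcf_genotypes(tf, maf_min = 0, hwe_p_min = 0, max_missing = 1)
  tf2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_genotypes(g1, tf2)
  g2 <- read_vcf_genotypes(tf2, maf_min = 0, hwe_p_min = 0, max_missing = 1)
  expect_equal(g1$dosage, g2$dosage)
  expect_equal(g1$sites$ref, g2$sites$ref)
})

test_that("BED coordinates convert to 1-based closed and back (involution)", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t50\t60\tpeak", "chr1\t999\t2000\tisland"), tf)
  a <- read_bed_intervals(tf)
  ## 0-based half-open [999, 2000) -> 1-based closed [1000, 2000]
  expect_equal(a$start, c(1000L, 51L))   # sorted by (chrom, start)
  expect_equal(a$end, c(2000L, 60L))
  expect_equal(a$chrom, c("chr1", "chr2"))

  tf2 <- withr::local_tempfile(fileext = ".bed")
  write_bed_intervals(a, tf2)
  b <- read_bed_intervals(tf2)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(a$label, b$label)
})

test_that("empty BED gives an empty annotation set without error", {
  tf <- withr::local_tempfile(fileext = ".bed")
  file.create(tf)
  a <- read_bed_intervals(tf)
  expect_s3_class(a, "annotation_set")
  expect_equal(nrow(a), 0)
})

test_that("gene models: TSS follows strand, stray exons are rejected", {
  tf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "gene", 5000, 9000, ".", "+", ".",
          'gene_id "gplus";', sep = "\t"),
    paste("chr1", "src", "exon", 5000, 5200, ".", "+", ".",
          'gene_id "gplus";', sep = "\t"),
    paste("chr1", "src", "exon", 12000, 12500, ".", "+", ".",
          'gene_id "gplus";', sep = "\t"),          # outside the body
    paste("chr1", "src", "gene", 5000, 9000, ".", "-", ".",
          'gene_id "gminus";', sep = "\t")
  ), tf)
  expect_warning(gm <- read_gene_models(tf), "exon")
  expect_equal(gm$genes$tss[gm$genes$gene_id == "gplus"], 5000)
  expect_equal(gm$genes$tss[gm$genes$gene_id == "gminus"], 9000)
  expect_equal(nrow(gm$exons), 1)
})

test_that("count matrices validate meth <= total and sample alignment", {
  td <- withr::local_tempdir()
  m <- matrix(c(3, 2, 0, 5), 2, 2, dimnames = list(c("c1", "c2"), c("a", "b")))
  tot <- matrix(c(10, 4, 1, 5), 2, 2, dimnames = dimnames(m))
  fm <- file.path(td, "m.tsv"); ft <- file.path(td, "t.tsv")
  write_count_matrix(m, fm, "cpg"); write_count_matrix(tot, ft, "cpg")
  mc <- read_count_matrix(fm, ft)
  expect_s3_class(mc, "methylation_counts")
  expect_equal(mc$meth["c1", "a"] / mc$total["c1", "a"], 0.3)

  bad <- m; bad["c2", "b"] <- 11
  fb <- file.path(td, "bad.tsv"); write_count_matrix(bad, fb, "cpg")
  expect_error(read_count_matrix(fb, ft), "c2.*b|b.*c2")

  tot2 <- tot[, 1, drop = FALSE]
  f2 <- file.path(td, "t2.tsv"); write_count_matrix(tot2, f2, "cpg")
  expect_error(read_count_matrix(fm, f2), "only one matrix")
})

test_that("results tables round-trip to at least 12 significant digits", {
  df <- data.frame(pair_id = c("p1", "p2"), n = c(10L, 20L),
                   beta = c(pi, -exp(1) * 1e-7),
                   p = c(0.123456789012345, 1e-300),
                   stringsAsFactors = FALSE)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(df, tf)
  back <- read_results_table(tf)
  expect_identical(back$n, df$n)
  expect_identical(back$pair_id, df$pair_id)
  expect_equal(back$beta, df$beta, tolerance = 1e-12)
  expect_equal(back$p, df$p, tolerance = 1e-12)
})

test_that("run_config validates its thresholds", {
  cfg <- run_config()
  expect_equal(cfg$asm_window, 100)
  expect_equal(cfg$meqtl_fdr, 0.05)
  expect_error(run_config(maf_min = 0.7))
  expect_error(run_config(constitutive_bounds = c(0.9, 0.1)))
})
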