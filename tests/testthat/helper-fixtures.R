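## Shared fixtures for the test suite; everything is generated in code.

## tiny three-generation pedigree: 1,2 founders; 3 their offspring;
## 4 founder; 5 = 3 x 4
tiny_pedigree <- function() {
  data.frame(id = 1:5,
             sire = c(NA, NA, 1L, NA, 3L),
             dam = c(NA, NA, 2L, NA, 4L),
             sex = c("M", "F", "M", "F", "F"),
             birth_year = c(2000, 2000, 2002, 2001, 2005))
}

## a one-pair pair_table with explicit counts (no ASM unless given)
one_pair_table <- function(y, r, dosage, asm = NULL) {
  m <- length(y)
  samples <- paste0("s", seq_len(m))
  one <- function(v) matrix(v, nrow = 1, dimnames = list("pair1", samples))
  pair_table(
    pairs = data.frame(pair_id = "pair1", snp_id = "snp1", cpg_id = "cpg1",
                       chrom = "chr1", snp_pos = 100L, cpg_pos = 120L,
                       stringsAsFactors = FALSE),
    samples = samples, dosage = one(dosage), y = one(y), r = one(r),
    asm_y_ref = if (!is.null(asm)) one(asm$y_ref),
    asm_r_ref = if (!is.null(asm)) one(asm$r_ref),
    asm_y_alt = if (!is.null(asm)) one(asm$y_alt),
    asm_r_alt = if (!is.null(asm)) one(asm$r_alt)
  )
}

identity_k <- function(m) {
  K <- diag(m)
  dimnames(K) <- list(paste0("s", seq_len(m)), paste0("s", seq_len(m)))
  K
}

## write a small VCF with the given genotype-string matrix (sites x samples)
write_test_vcf <- function(path, chrom, pos, ref, alt, gt) {
  samples <- paste0("S", seq_len(ncol(gt)))
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  for (i in seq_along(pos)) {
    lines <- c(lines, paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".",
                              "PASS", ".", "GT", gt[i, ]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

## Gauss-Hermite nodes/weights via the Golub-Welsch eigenvalue method
gauss_hermite <- function(k) {
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2 * sqrt(pi))
}
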