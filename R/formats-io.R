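## File formats and shared genomic primitives.
##
## Internal coordinate convention: 1-based, fully closed intervals everywhere.
## BED (0-based half-open) is converted at the boundary in both directions.
## An AnnotationSet is a data.frame with columns chrom, start, end, label,
## strand, sorted by (chrom, start).

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test on the number of heterozygotes given the minor
#' allele count, with full enumeration of admissible heterozygote counts.
#' The p-value sums the probabilities of all configurations no more probable
#' than the observed one (two-sided by probability ordering).
#'
#' @param n_aa,n_ab,n_bb genotype counts (homozygous ref, het, homozygous alt).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  ## minor allele count
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  n_minor <- min(n_a, n_b)
  if (n_minor == 0L) return(1)
  ## admissible heterozygote counts share parity with n_minor
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  ## log P(het = h | n, n_minor) up to a constant:
  ## C(n, h) C(n-h, (n_minor-h)/2) 2^h ... use the standard recurrence-free
  ## form via lchoose on genotype counts.
  n_hom_minor <- (n_minor - hets) / 2
  n_hom_major <- n - hets - n_hom_minor
  logp <- lfactorial(n) - lfactorial(hets) - lfactorial(n_hom_minor) -
    lfactorial(n_hom_major) + hets * log(2) +
    lfactorial(n_minor) + lfactorial(2L * n - n_minor) - lfactorial(2L * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_ab)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Read genotypes from a VCF file with site filters
#'
#' Parses biallelic SNP records, converts GT fields to dosages of the
#' non-reference (counted) allele, and applies minor-allele-frequency,
#' exact Hardy-Weinberg and missingness filters. Multi-allelic or non-SNP
#' records are skipped with a warning; failing sites are excluded and the
#' reason recorded in the returned exclusion ledger.
#'
#' @param path VCF 4.x file.
#' @param maf_min minimum minor allele frequency (sites strictly below are
#'   dropped).
#' @param hwe_p_min minimum exact HWE p-value.
#' @param max_missing maximum fraction of missing genotype calls (sites
#'   strictly above are dropped).
#' @param cfg optional \code{\link{run_config}}; supplies defaults for the
#'   three thresholds and the logging level.
#' @return A \code{genotype_table}: list with \code{dosage} (sites x samples
#'   integer matrix, NA = missing), \code{sites} (data.frame chrom, pos, ref,
#'   alt, maf, hwe_p, missing), \code{samples}, and \code{excluded}
#'   (data.frame chrom, pos, reason).
#' @export
read_vcf_genotypes <- function(path, maf_min = NULL, hwe_p_min = NULL,
                               max_missing = NULL, cfg = NULL) {
  if (is.null(cfg)) cfg <- run_config(logging = "quiet")
  if (is.null(maf_min)) maf_min <- cfg$maf_min
  if (is.null(hwe_p_min)) hwe_p_min <- cfg$hwe_p_min
  if (is.null(max_missing)) max_missing <- cfg$max_missing
  .vcf_prescan(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(rownames(gt), colnames(gt)))
  samples <- colnames(gt)

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt)
  if (any(!snp)) {
    warning(sprintf("skipped %d multi-allelic or non-SNP record(s)", sum(!snp)))
  }
  dose <- .gt_to_dosage(gt)
  sites <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt, stringsAsFactors = FALSE
  )

  n_aa <- rowSums(dose == 0L, na.rm = TRUE)
  n_ab <- rowSums(dose == 1L, na.rm = TRUE)
  n_bb <- rowSums(dose == 2L, na.rm = TRUE)
  n_called <- n_aa + n_ab + n_bb
  miss <- 1 - n_called / length(samples)
  af <- ifelse(n_called > 0, (n_ab + 2 * n_bb) / (2 * n_called), NA_real_)
  maf <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(nrow(dose)),
                function(i) hwe_exact_test(n_aa[i], n_ab[i], n_bb[i]), 0)

  reason <- rep(NA_character_, nrow(dose))
  reason[snp & n_called == 0] <- "no_calls"
  reason[snp & is.na(reason) & maf < maf_min] <- "maf"
  reason[snp & is.na(reason) & hwe < hwe_p_min] <- "hwe"
  reason[snp & is.na(reason) & miss > max_missing] <- "missingness"
  reason[!snp] <- "not_biallelic_snp"
  keep <- is.na(reason)

  excluded <- data.frame(chrom = sites$chrom[!keep], pos = sites$pos[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  asmqtl_log(cfg, "info", "read_vcf_genotypes: %d sites read, %d retained (%s)",
             nrow(sites), sum(keep),
             paste(sprintf("%s=%d", names(table(excluded$reason)),
                           as.integer(table(excluded$reason))), collapse = ", "))

  sites <- sites[keep, , drop = FALSE]
  sites$maf <- maf[keep]; sites$hwe_p <- hwe[keep]; sites$missing <- miss[keep]
  rownames(sites) <- NULL
  out <- list(dosage = dose[keep, , drop = FALSE], sites = sites,
              samples = samples, excluded = excluded)
  class(out) <- "genotype_table"
  out
}

## quick structural scan so malformed lines are reported with a line number
.vcf_prescan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!any(startsWith(lines, "#CHROM"))) {
    stop("malformed VCF: missing #CHROM header line in ", path)
  }
  ncol_header <- length(strsplit(lines[startsWith(lines, "#CHROM")][1], "\t")[[1]])
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t")[[1]])
    if (nf != ncol_header) {
      stop(sprintf("malformed VCF at line %d: %d fields, expected %d", i, nf,
                   ncol_header))
    }
  }
  invisible(TRUE)
}

.gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  d[clean %in% c("0/0")] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean %in% c("1/1")] <- 2L
  d
}

#' Write a genotype table to a minimal VCF
#'
#' @param gt a \code{genotype_table}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_vcf_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=asmqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$samples), collapse = "\t")
  ), con)
  gtstr <- matrix(".", nrow(gt$dosage), ncol(gt$dosage))
  gtstr[gt$dosage == 0L] <- "0/0"
  gtstr[gt$dosage == 1L] <- "0/1"
  gtstr[gt$dosage == 2L] <- "1/1"
  gtstr[is.na(gt$dosage)] <- "./."
  for (i in seq_len(nrow(gt$sites))) {
    writeLines(paste(c(gt$sites$chrom[i], gt$sites$pos[i], ".",
                       gt$sites$ref[i], gt$sites$alt[i], ".", "PASS", ".",
                       "GT", gtstr[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a BED file into an annotation set
#'
#' BED coordinates (0-based half-open) are converted to the package's
#' internal 1-based closed convention; records that are empty after
#' conversion are rejected with a warning; output is sorted by
#' (chrom, start).
#'
#' @param path BED3+ file.
#' @param label annotation category attached to every interval (column 4 of
#'   the BED, when present, overrides it per record).
#' @return data.frame with columns chrom, start, end, label, strand.
#' @export
read_bed_intervals <- function(path, label = "interval") {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(annotation_set(character(0), integer(0), integer(0), character(0)))
  }
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) {
    return(annotation_set(character(0), integer(0), integer(0), character(0)))
  }
  lab <- if (!is.null(gr$name) && !all(is.na(gr$name))) as.character(gr$name) else rep(label, length(gr))
  lab[is.na(lab)] <- label
  bad <- GenomicRanges::width(gr) < 1L
  if (any(bad)) {
    warning(sprintf("rejected %d empty interval(s) after BED conversion", sum(bad)))
  }
  gr <- gr[!bad]; lab <- lab[!bad]
  annotation_set(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr), GenomicRanges::end(gr), lab,
                 as.character(GenomicRanges::strand(gr)))
}

#' Construct an annotation set (1-based closed intervals)
#'
#' @param chrom,start,end,label,strand vectors of equal length; strand in
#'   {+,-,*}.
#' @return data.frame sorted by (chrom, start) with class
#'   \code{c("annotation_set","data.frame")}.
#' @export
annotation_set <- function(chrom, start, end, label, strand = "*") {
  n <- length(start)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(label) == 1L && n > 1L) label <- rep(label, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  stopifnot(length(chrom) == n, length(end) == n, length(label) == n,
            length(strand) == n)
  if (length(start) && any(start > end)) stop("interval start > end")
  if (length(start) && any(start < 1)) stop("positions are 1-based: start >= 1")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), label = as.character(label),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' Write an annotation set as BED (inverse of \code{read_bed_intervals})
#' @param x annotation_set.
#' @param path output BED file.
#' @return \code{path}, invisibly.
#' @export
write_bed_intervals <- function(x, path) {
  gr <- as_granges(x)
  gr$name <- x$label
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

## annotation_set/data.frame(chrom,start,end) -> GRanges (internal)
as_granges <- function(x) {
  str <- if ("strand" %in% names(x)) {
    s <- x$strand; s[!s %in% c("+", "-")] <- "*"; s
  } else "*"
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end), strand = str)
}

#' Read gene models from a GTF file
#'
#' Keeps gene and exon features; derives per gene the body interval, strand,
#' TSS (start of the body on the + strand, end on the - strand) and exon set.
#' Exons falling outside their gene body and genes without coordinates are
#' dropped with a warning.
#'
#' @param path GTF file with \code{gene} and \code{exon} features and a
#'   \code{gene_id} attribute.
#' @return list with \code{genes} (data.frame gene_id, chrom, start, end,
#'   strand, tss) and \code{exons} (data.frame gene_id, chrom, start, end).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  ty <- as.character(gr$type)
  g <- gr[ty == "gene"]
  e <- gr[ty == "exon"]
  ok <- !is.na(GenomicRanges::start(g)) & !is.na(GenomicRanges::end(g))
  if (any(!ok)) warning(sprintf("skipped %d gene(s) without coordinates", sum(!ok)))
  g <- g[ok]
  strand <- as.character(GenomicRanges::strand(g))
  genes <- data.frame(
    gene_id = as.character(g$gene_id),
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    strand = strand,
    tss = ifelse(strand == "-", GenomicRanges::end(g), GenomicRanges::start(g)),
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = as.character(e$gene_id),
    chrom = as.character(GenomicRanges::seqnames(e)),
    start = GenomicRanges::start(e), end = GenomicRanges::end(e),
    stringsAsFactors = FALSE
  )
  ## exon containment within its gene body
  idx <- match(exons$gene_id, genes$gene_id)
  contained <- !is.na(idx) & exons$chrom == genes$chrom[idx] &
    exons$start >= genes$start[idx] & exons$end <= genes$end[idx]
  if (any(!contained)) {
    warning(sprintf("rejected %d exon(s) outside their gene body", sum(!contained)))
  }
  exons <- exons[contained, , drop = FALSE]
  rownames(genes) <- rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Read methylated/total count matrices (or an expression matrix)
#'
#' TSV layout: rows are sites or genes (first column = id), columns are
#' samples. When both \code{path_meth} and \code{path_total} are given the
#' two matrices are aligned on row ids and sample names and validated
#' elementwise (\code{meth <= total}); a lone path is returned as a plain
#' numeric matrix. Missing entries (\code{NA}) are kept distinct from zero.
#'
#' @param path_meth TSV of methylated counts, or the single matrix to read.
#' @param path_total optional TSV of total counts.
#' @return With \code{path_total}: a \code{methylation_counts} list with
#'   matrices \code{meth} and \code{total}; otherwise a numeric matrix.
#' @export
read_count_matrix <- function(path_meth, path_total = NULL) {
  m <- .read_matrix_tsv(path_meth)
  if (is.null(path_total)) return(m)
  tot <- .read_matrix_tsv(path_total)
  if (!setequal(colnames(m), colnames(tot))) {
    only <- c(setdiff(colnames(m), colnames(tot)), setdiff(colnames(tot), colnames(m)))
    stop("sample(s) present in only one matrix: ", paste(only, collapse = ", "))
  }
  if (!setequal(rownames(m), rownames(tot))) {
    stop("row ids differ between methylated and total matrices")
  }
  tot <- tot[rownames(m), colnames(m), drop = FALSE]
  bad <- which(!is.na(m) & !is.na(tot) & m > tot, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("methylated > total at site %s, sample %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  methylation_counts(m, tot)
}

.read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Construct a methylation-counts container
#'
#' @param meth,total numeric matrices (sites x samples), \code{meth <= total};
#'   NA marks a site not measured in a sample.
#' @return list with class \code{methylation_counts}.
#' @export
methylation_counts <- function(meth, total) {
  stopifnot(identical(dim(meth), dim(total)))
  if (any(!is.na(meth) & !is.na(total) & meth > total)) {
    stop("methylated counts exceed totals")
  }
  out <- list(meth = meth, total = total)
  class(out) <- "methylation_counts"
  out
}

#' Write a numeric matrix as a TSV with an id column
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_name name for the id column.
#' @return \code{path}, invisibly.
#' @export
write_count_matrix <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read an association-result table (round-trip safe)
#'
#' Floating point columns are serialized with 17 significant digits so that
#' a write-then-read round trip reproduces integers bit-identically and
#' doubles to at least 12 significant digits.
#'
#' @param df results data.frame.
#' @param path TSV path.
#' @return \code{path} (write) or the data.frame (read).
#' @export
write_results_table <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  for (j in which(num)) out[[j]][is.na(df[[j]])] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
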