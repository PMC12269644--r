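## Genomic-annotation enrichment: CpG-context and gene-feature annotation,
## SNP-in-CpG detection, one-tailed Fisher tests, and the gene-level
## permutation test.

#' Annotate sites against genomic compartments
#'
#' Each position receives exactly one CpG-context class (precedence island
#' > shore > shelf > open sea, shores extending \code{shore_len} bp from
#' island edges and shelves \code{shelf_len} bp beyond shores), a set of
#' gene-feature classes (promoter = \code{promoter_len} bp upstream of the
#' TSS; exon; intron_utr = in the gene body but not in an exon), an
#' optional chromatin-state label, and open-chromatin / DMR flags.
#'
#' @param positions data.frame site_id, chrom, pos.
#' @param islands CpG-island \code{\link{annotation_set}} (or NULL).
#' @param genes gene models from \code{\link{read_gene_models}} (or NULL).
#' @param chromatin_states annotation_set of state intervals (labels =
#'   state names) or NULL.
#' @param open_chromatin,dmrs annotation_sets or NULL.
#' @param cfg \code{\link{run_config}} (promoter/shore/shelf geometry).
#' @return data.frame: site_id, chrom, pos, cpg_context, promoter, exon,
#'   intron_utr, chromatin_state, in_open_chromatin, in_dmr.
#' @export
annotate_sites <- function(positions, islands = NULL, genes = NULL,
                           chromatin_states = NULL, open_chromatin = NULL,
                           dmrs = NULL, cfg = run_config()) {
  gr <- GenomicRanges::GRanges(positions$chrom,
                               IRanges::IRanges(positions$pos, positions$pos))
  n <- nrow(positions)
  hits_any <- function(set) {
    if (is.null(set) || !nrow(set)) return(rep(FALSE, n))
    IRanges::overlapsAny(gr, as_granges(set))
  }
  ## CpG context with island > shore > shelf precedence
  ctx <- rep("open_sea", n)
  if (!is.null(islands) && nrow(islands)) {
    isl <- as_granges(islands)
    shore <- c(
      GenomicRanges::flank(isl, cfg$shore_len, start = TRUE),
      GenomicRanges::flank(isl, cfg$shore_len, start = FALSE)
    )
    shelf <- c(
      GenomicRanges::flank(isl, cfg$shelf_len + cfg$shore_len, start = TRUE),
      GenomicRanges::flank(isl, cfg$shelf_len + cfg$shore_len, start = FALSE)
    )
    shelf <- GenomicRanges::setdiff(shelf, shore)
    ctx[IRanges::overlapsAny(gr, GenomicRanges::trim(shelf))] <- "shelf"
    ctx[IRanges::overlapsAny(gr, GenomicRanges::trim(shore))] <- "shore"
    ctx[IRanges::overlapsAny(gr, isl)] <- "island"
  }
  promoter <- exon <- intron_utr <- rep(FALSE, n)
  if (!is.null(genes) && nrow(genes$genes)) {
    gdf <- genes$genes
    prom_start <- ifelse(gdf$strand == "-", gdf$tss + 1,
                         gdf$tss - cfg$promoter_len)
    prom_end <- ifelse(gdf$strand == "-", gdf$tss + cfg$promoter_len,
                       gdf$tss - 1)
    ok <- prom_start <= prom_end & prom_start >= 1
    prom <- GenomicRanges::GRanges(gdf$chrom[ok],
                                   IRanges::IRanges(pmax(1, prom_start[ok]),
                                                    prom_end[ok]))
    promoter <- IRanges::overlapsAny(gr, prom)
    body <- GenomicRanges::GRanges(gdf$chrom,
                                   IRanges::IRanges(gdf$start, gdf$end))
    in_body <- IRanges::overlapsAny(gr, body)
    if (nrow(genes$exons)) {
      ex <- GenomicRanges::GRanges(genes$exons$chrom,
                                   IRanges::IRanges(genes$exons$start,
                                                    genes$exons$end))
      exon <- IRanges::overlapsAny(gr, ex)
    }
    intron_utr <- in_body & !exon
  }
  state <- rep(NA_character_, n)
  if (!is.null(chromatin_states) && nrow(chromatin_states)) {
    hs <- GenomicRanges::findOverlaps(gr, as_granges(chromatin_states),
                                      select = "first")
    state[!is.na(hs)] <- chromatin_states$label[hs[!is.na(hs)]]
  }
  data.frame(
    site_id = positions$site_id, chrom = positions$chrom, pos = positions$pos,
    cpg_context = ctx, promoter = promoter, exon = exon,
    intron_utr = intron_utr, chromatin_state = state,
    in_open_chromatin = hits_any(open_chromatin), in_dmr = hits_any(dmrs),
    stringsAsFactors = FALSE
  )
}

#' Does a SNP disrupt its associated CpG?
#'
#' TRUE when the SNP position is the CpG's C position or the position
#' immediately after it (the G of the dinucleotide).
#'
#' @param snp_pos,cpg_pos integer vectors (recycled).
#' @return logical vector.
#' @export
snp_disrupts_cpg <- function(snp_pos, cpg_pos) {
  snp_pos == cpg_pos | snp_pos == cpg_pos + 1L
}

#' One-tailed Fisher enrichment test
#'
#' 2x2 enrichment of membership in set A between inside/outside set B.
#' The odds ratio is the sample (unconditional) OR with a Haldane 0.5
#' correction applied when any cell is zero; the p-value is the exact
#' hypergeometric tail; the CI comes from the normal approximation on the
#' log OR.
#'
#' @param in_a,in_b logical vectors over the same sites, or a 2x2 table
#'   given as \code{c(a, b, c, d)} = (A&B, notA&B, A&notB, notA&notB) via
#'   \code{table_counts}.
#' @param table_counts optional length-4 numeric overriding in_a/in_b.
#' @param direction "greater" (enrichment, default) or "less" (depletion).
#' @return list: odds_ratio, log2_or, ci_lo, ci_hi (log2 scale), p, table.
#' @export
fisher_enrichment <- function(in_a = NULL, in_b = NULL, table_counts = NULL,
                              direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (is.null(table_counts)) {
    stopifnot(length(in_a) == length(in_b))
    a <- sum(in_a & in_b); b <- sum(!in_a & in_b)
    cc <- sum(in_a & !in_b); dd <- sum(!in_a & !in_b)
  } else {
    stopifnot(length(table_counts) == 4)
    a <- table_counts[1]; b <- table_counts[2]
    cc <- table_counts[3]; dd <- table_counts[4]
  }
  tab <- matrix(c(a, cc, b, dd), 2, 2,
                dimnames = list(A = c("yes", "no"), B = c("yes", "no")))
  p <- stats::fisher.test(tab, alternative = direction)$p.value
  h <- if (any(tab == 0)) 0.5 else 0
  or <- ((a + h) * (dd + h)) / ((b + h) * (cc + h))
  se_log <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (cc + h) + 1 / (dd + h))
  ci <- log(or) + c(-1, 1) * 1.96 * se_log
  list(odds_ratio = or, log2_or = log2(or),
       ci_lo = ci[1] / log(2), ci_hi = ci[2] / log(2), p = p, table = tab)
}

#' Gene-level permutation test for meQTL density
#'
#' For every gene with at least \code{min_cpgs_per_gene} tested CpGs within
#' \code{gene_flank} bp of its body, compares the observed proportion of
#' significant CpGs with the distribution of proportions under
#' \code{n_gene_perm} genome-wide shuffles of the CpG significance labels:
#' enriched if the observed proportion exceeds the gene's 95th-order
#' statistic of the permuted proportions, depleted if below the 5th.
#'
#' @param cpgs data.frame cpg_id, chrom, pos, significant (one row per
#'   tested CpG).
#' @param genes gene model data.frame (gene_id, chrom, start, end).
#' @param cfg \code{\link{run_config}} (n_gene_perm, min_cpgs_per_gene,
#'   gene_flank).
#' @param seed RNG seed for the shuffles.
#' @return data.frame: gene_id, n_tested, n_significant, proportion,
#'   perm_lo, perm_hi (5th/95th order statistics), classification in
#'   \{"enriched","depleted","neither"\}.
#' @export
gene_level_permutation <- function(cpgs, genes, cfg = run_config(),
                                   seed = cfg$seed) {
  stopifnot(!any(duplicated(cpgs$cpg_id)))
  gr <- GenomicRanges::GRanges(cpgs$chrom, IRanges::IRanges(cpgs$pos, cpgs$pos))
  flank <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$start - cfg$gene_flank),
                     genes$end + cfg$gene_flank))
  ov <- GenomicRanges::findOverlaps(gr, flank)
  memb <- split(S4Vectors::queryHits(ov), genes$gene_id[S4Vectors::subjectHits(ov)])
  memb <- memb[vapply(memb, length, 0L) >= cfg$min_cpgs_per_gene]
  if (!length(memb)) {
    return(data.frame(gene_id = character(0), n_tested = integer(0),
                      n_significant = integer(0), proportion = numeric(0),
                      perm_lo = numeric(0), perm_hi = numeric(0),
                      classification = character(0)))
  }
  sig <- as.logical(cpgs$significant)
  obs <- vapply(memb, function(ix) mean(sig[ix]), 0)
  n_perm <- cfg$n_gene_perm
  perm_props <- matrix(NA_real_, length(memb), n_perm)
  set.seed(seed)
  for (k in seq_len(n_perm)) {
    shuf <- sample(sig)
    perm_props[, k] <- vapply(memb, function(ix) mean(shuf[ix]), 0)
  }
  ## 5th / 95th order statistics of the permuted values
  lo <- apply(perm_props, 1, function(v) sort(v)[max(1L, floor(0.05 * n_perm))])
  hi <- apply(perm_props, 1, function(v) sort(v)[min(n_perm, ceiling(0.95 * n_perm))])
  cls <- ifelse(obs > hi, "enriched", ifelse(obs < lo, "depleted", "neither"))
  data.frame(
    gene_id = names(memb),
    n_tested = vapply(memb, length, 0L),
    n_significant = vapply(memb, function(ix) sum(sig[ix]), 0L),
    proportion = obs, perm_lo = lo, perm_hi = hi,
    classification = cls, stringsAsFactors = FALSE, row.names = NULL
  )
}
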