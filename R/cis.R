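# Copy-number / expression integration: cis-gene calling, Z rescaling,
# locus-level LOH reporting, and GMT gene-set enrichment.
#
# A gene is a cis-gene when (1) the Pearson correlation between its total
# copy number and its log2 expression across samples exceeds 0.4, and (2) at
# least one of two Welch t-tests is significant at P < 0.05 without
# multiplicity correction: loss vs normal expression, or normal vs gain
# expression. Gain/loss/normal at the gene uses a delta = 0.5 copy tolerance
# around the sample's ploidy so a non-degenerate normal class exists. The
# smaller of the two P-values is rescaled to Z = -qnorm(P) for display.

#' Total copy number of one gene across samples
#'
#' The gene is matched to the segment containing its midpoint in each sample;
#' samples with no covering segment are missing (NA).
#'
#' @param gene one-row annotation (gene, chrom, start, end).
#' @param profiles list of [sample_profile()].
#' @return named numeric vector of total copy numbers per sample (NA where
#'   uncovered).
#' @export
match_gene_copynumber <- function(gene, profiles) {
  m <- gene_copy_matrix(gene[1, , drop = FALSE], profiles)
  v <- m[1, ]
  if (all(is.na(v))) {
    warning("gene ", gene$gene[1], " is uncovered in every sample")
  }
  v
}

#' Copy-number matrix for many genes
#'
#' @param genes annotation data.frame.
#' @param profiles list of [sample_profile()].
#' @return numeric matrix genes x samples of total copy numbers at each
#'   gene's midpoint (NA where uncovered).
#' @export
gene_copy_matrix <- function(genes, profiles) {
  mid <- floor((genes$start + genes$end) / 2)
  out <- matrix(NA_real_, nrow(genes), length(profiles),
                dimnames = list(genes$gene,
                                vapply(profiles, `[[`, "", "sample")))
  for (j in seq_along(profiles)) {
    seg <- profiles[[j]]$segments
    for (ch in unique(genes$chrom)) {
      gi <- which(genes$chrom == ch)
      s <- seg[seg$chrom == ch, , drop = FALSE]
      if (!nrow(s)) next
      s <- s[order(s$start), , drop = FALSE]
      k <- findInterval(mid[gi], s$start)
      hit <- k >= 1 & mid[gi] <= s$end[pmax(k, 1)]
      out[gi[hit], j] <- s$total[k[hit]]
    }
  }
  out
}

#' Rescale a P-value to the standard-normal quantile scale
#'
#' Z = -F^{-1}(p) with F the standard normal CDF; strictly decreasing in p,
#' Z(0.05) = 1.64, Z(0.5) = 0.
#'
#' @param p probabilities strictly inside (0, 1); vectorized.
#' @return Z scores.
#' @export
pvals_to_z <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p must be strictly inside (0, 1)")
  }
  -stats::qnorm(p)
}

#' Cis-association test for one gene
#'
#' @param copy per-sample total copy numbers at the gene.
#' @param expr per-sample log2 expression values (same order).
#' @param calls per-sample labels in {"gain", "loss", "normal"} at the gene.
#' @param min_group minimum samples per t-test arm (default 3); a t-test
#'   whose arms are smaller contributes no P-value.
#' @param r_threshold correlation criterion (default 0.4, exceeded strictly).
#' @param p_threshold per-test significance level (default 0.05, no
#'   multiplicity correction: the criterion is designed to be liberal).
#' @return one-row data.frame: n, r, p_loss, p_gain, min_p, z, cis.
#' @export
cis_test <- function(copy, expr, calls, min_group = 3,
                     r_threshold = 0.4, p_threshold = 0.05) {
  ok <- is.finite(copy) & is.finite(expr)
  n <- sum(ok)
  copy <- copy[ok]
  expr <- expr[ok]
  calls <- calls[ok]
  r <- if (n >= 3 && stats::sd(copy) > 0 && stats::sd(expr) > 0) {
    stats::cor(copy, expr)
  } else NA_real_
  welch_p <- function(x, y) {
    if (length(x) < min_group || length(y) < min_group) return(NA_real_)
    if (stats::sd(c(x, y)) == 0) return(NA_real_)
    stats::t.test(x, y)$p.value
  }
  p_loss <- welch_p(expr[calls == "loss"], expr[calls == "normal"])
  p_gain <- welch_p(expr[calls == "normal"], expr[calls == "gain"])
  ps <- c(p_loss, p_gain)
  min_p <- if (all(is.na(ps))) NA_real_ else min(ps, na.rm = TRUE)
  z <- if (is.na(min_p) || min_p <= 0 || min_p >= 1) NA_real_ else pvals_to_z(min_p)
  cis <- !is.na(r) && r > r_threshold && !is.na(min_p) && min_p < p_threshold
  data.frame(n = n, r = r, p_loss = p_loss, p_gain = p_gain,
             min_p = min_p, z = z, cis = cis)
}

#' Call cis-genes for a cohort
#'
#' For every gene with both coordinates and expression, pairs its per-sample
#' total copy number (segment containing the gene midpoint) with its log2
#' expression, applies the compound cis criterion, and flags genes located in
#' recurrent aberrant regions.
#'
#' @param expr gene-level log2 expression matrix (rows = genes, columns =
#'   samples); collapse probe-level data with [collapse_probes()] first.
#' @param profiles list of [sample_profile()].
#' @param genes annotation data.frame.
#' @param regions optional recurrent regions from [recurrent_regions()];
#'   sets the `in_recurrent_region` flag by >= 1 bp overlap.
#' @param delta copy tolerance for the gain/loss/normal grouping at the gene
#'   (default 0.5).
#' @param min_group,min_n minimum t-test arm size and minimum matched-sample
#'   count per gene.
#' @return data.frame with one row per analyzable gene: `gene, n, r, p_loss,
#'   p_gain, min_p, z, cis, in_recurrent_region`.
#' @export
call_cis_genes <- function(expr, profiles, genes, regions = NULL,
                           delta = 0.5, min_group = 3, min_n = 10) {
  sample_ids <- vapply(profiles, `[[`, "", "sample")
  shared <- intersect(colnames(expr), sample_ids)
  if (!length(shared)) stop("expression matrix and profiles share no samples")
  profiles <- profiles[match(shared, sample_ids)]
  genes <- genes[genes$gene %in% rownames(expr), , drop = FALSE]
  if (!nrow(genes)) stop("no annotated genes present in the expression matrix")
  cn <- gene_copy_matrix(genes, profiles)
  ploidies <- vapply(profiles, compute_ploidy, 0, use_supplied = FALSE)
  e <- expr[genes$gene, shared, drop = FALSE]
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    copy <- cn[i, ]
    calls <- ifelse(copy > ploidies + delta, "gain",
                    ifelse(copy < ploidies - delta, "loss", "normal"))
    rec <- cis_test(copy, e[i, ], calls, min_group = min_group)
    if (rec$n < min_n) rec$cis <- FALSE
    rows[[i]] <- cbind(data.frame(gene = genes$gene[i], stringsAsFactors = FALSE), rec)
  }
  out <- do.call(rbind, rows)
  out$in_recurrent_region <- FALSE
  if (!is.null(regions) && nrow(regions)) {
    g <- genes[match(out$gene, genes$gene), ]
    lev <- union(g$chrom, regions$chrom)
    gr_gene <- GenomicRanges::GRanges(factor(g$chrom, lev),
                                      IRanges::IRanges(g$start, g$end))
    gr_reg <- GenomicRanges::GRanges(factor(regions$chrom, lev),
                                     IRanges::IRanges(regions$start, regions$end))
    out$in_recurrent_region <- GenomicRanges::countOverlaps(gr_gene, gr_reg) > 0
  }
  rownames(out) <- NULL
  out
}

#' LOH status of a gene locus across samples
#'
#' A sample has LOH at the gene when the segment containing the gene midpoint
#' has minor allele copy number 0 with total >= 1 (one allele completely
#' lost; homozygous deletions are not LOH).
#'
#' @param profiles list of [sample_profile()].
#' @param gene one-row annotation.
#' @return logical vector per sample (NA where the locus is uncovered).
#' @export
gene_loh <- function(profiles, gene) {
  mid <- floor((gene$start[1] + gene$end[1]) / 2)
  vapply(profiles, function(p) {
    s <- p$segments
    s <- s[s$chrom == gene$chrom[1] & s$start <= mid & s$end >= mid, , drop = FALSE]
    if (!nrow(s)) return(NA)
    s$nMinor[1] == 0 && s$total[1] >= 1
  }, NA)
}

#' Fraction of samples with LOH at a gene, as a printed percentage
#'
#' @param profiles list of [sample_profile()].
#' @param gene one-row annotation.
#' @return list with `k` (samples with LOH), `n` (informative samples) and
#'   `percent` (= [fraction_percent()] of k/n).
#' @export
loh_fraction <- function(profiles, gene) {
  st <- gene_loh(profiles, gene)
  k <- sum(st, na.rm = TRUE)
  n <- sum(!is.na(st))
  list(k = k, n = n, percent = fraction_percent(k, n))
}

#' Percentage of a count fraction at reporting precision
#'
#' @param k,n numerator and denominator counts.
#' @param digits decimals to keep (default 1, the usual reporting precision).
#' @return `round(100 * k / n, digits)`, e.g. 55/58 -> 94.8.
#' @export
fraction_percent <- function(k, n, digits = 1) {
  stopifnot(n > 0, k >= 0, k <= n)
  round(100 * k / n, digits)
}

#' Gene-set enrichment of a cis-gene list
#'
#' One-sided Fisher exact test per gene set on the 2x2 table (in set / not) x
#' (cis / not) over the analysis universe, with Benjamini-Hochberg correction
#' across sets.
#'
#' @param cis character vector of cis-gene symbols.
#' @param universe character vector of all analyzed genes (cis is intersected
#'   with it).
#' @param sets named list of character vectors (e.g. from [read_gmt()]); each
#'   set is intersected with the universe.
#' @return data.frame `set, universe_size, set_size, cis_count, overlap, p,
#'   p_bh` sorted by p.
#' @export
enrich_gene_sets <- function(cis, universe, sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  cis <- intersect(unique(cis), universe)
  n_univ <- length(universe)
  n_cis <- length(cis)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- length(intersect(s, cis))
    tab <- matrix(c(ov, length(s) - ov,
                    n_cis - ov, n_univ - length(s) - n_cis + ov), 2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(set = nm, universe_size = n_univ, set_size = length(s),
               cis_count = n_cis, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
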