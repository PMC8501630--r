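# Cross-sample aberration frequency tracks and recurrent aberrant regions.
#
# The genome is cut into atomic intervals by the union of all samples'
# segment breakpoints (GenomicRanges::disjoin). For each atomic interval the
# gain (loss) frequency is the number of samples whose covering segment is
# called gain (loss), divided by the number of samples covering the interval
# at all. Maximal runs of adjacent atomic intervals at frequency >= p form
# recurrent aberrant regions (default p = 0.30, inclusive).

#' Aberration frequency track across samples
#'
#' @param profiles list of [sample_profile()] (>= 1).
#' @param delta calling tolerance in copies, shared by all samples (default
#'   0: the strict gain/loss rule).
#' @return a `frequency_track` data.frame: `chrom, start, end, n, freq_gain,
#'   freq_loss`, one row per atomic interval covered by >= 1 sample.
#' @export
aberration_frequency <- function(profiles, delta = 0) {
  if (length(profiles) == 0) stop("need at least one sample profile")
  calls <- do.call(rbind, lapply(profiles, call_profile, delta = delta))
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start, calls$end),
                               call = calls$call)
  atoms <- GenomicRanges::disjoin(gr)
  n <- GenomicRanges::countOverlaps(atoms, gr)
  n_gain <- GenomicRanges::countOverlaps(atoms, gr[gr$call == "gain"])
  n_loss <- GenomicRanges::countOverlaps(atoms, gr[gr$call == "loss"])
  track <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(atoms)),
    start = GenomicRanges::start(atoms),
    end = GenomicRanges::end(atoms),
    n = n,
    freq_gain = n_gain / n,
    freq_loss = n_loss / n,
    stringsAsFactors = FALSE
  )
  structure(track, class = c("frequency_track", "data.frame"))
}

#' Extract recurrent aberrant regions from a frequency track
#'
#' Maximal runs of adjacent atomic intervals whose gain (or loss) frequency
#' is at least `p`, per direction. Adjacency requires the next interval to
#' start exactly one base after the previous ends; single-interval regions
#' are retained.
#'
#' @param track a frequency track from [aberration_frequency()].
#' @param p recurrence threshold in (0, 1]; comparison is `>= p` (default
#'   0.30).
#' @return data.frame `chrom, start, end, direction, peak_freq, mean_freq,
#'   genes, cytobands` sorted by position (genes/cytobands empty until
#'   [annotate_regions()]).
#' @export
recurrent_regions <- function(track, p = 0.30) {
  stopifnot(p > 0, p <= 1)
  one_direction <- function(freq, direction) {
    sel <- freq >= p
    if (!any(sel)) return(NULL)
    idx <- which(sel)
    adjacent <- c(FALSE,
                  track$chrom[idx[-1]] == track$chrom[idx[-length(idx)]] &
                    track$start[idx[-1]] == track$end[idx[-length(idx)]] + 1)
    run <- cumsum(!adjacent)
    do.call(rbind, lapply(split(idx, run), function(ii) {
      w <- track$end[ii] - track$start[ii] + 1
      data.frame(chrom = track$chrom[ii[1]],
                 start = track$start[ii[1]],
                 end = track$end[ii[length(ii)]],
                 direction = direction,
                 peak_freq = max(freq[ii]),
                 mean_freq = sum(freq[ii] * w) / sum(w),
                 genes = "", cytobands = "",
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(one_direction(track$freq_gain, "gain"),
               one_direction(track$freq_loss, "loss"))
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), peak_freq = numeric(),
                      mean_freq = numeric(), genes = character(),
                      cytobands = character(), stringsAsFactors = FALSE)
  } else {
    out <- out[order(match(out$chrom, unique(track$chrom)), out$start), ]
  }
  rownames(out) <- NULL
  out
}

#' Annotate recurrent regions with overlapping genes and cytobands
#'
#' A gene is listed when its interval overlaps the region by >= 1 bp
#' (1-based inclusive on both sides).
#'
#' @param regions data.frame from [recurrent_regions()].
#' @param genes annotation data.frame from [read_gene_annotation()].
#' @return `regions` with `genes` and `cytobands` filled (comma-separated).
#' @export
annotate_regions <- function(regions, genes) {
  if (nrow(regions) == 0 || nrow(genes) == 0) return(regions)
  lev <- union(regions$chrom, genes$chrom)
  reg_gr <- GenomicRanges::GRanges(factor(regions$chrom, lev),
                                   IRanges::IRanges(regions$start, regions$end))
  gene_gr <- GenomicRanges::GRanges(factor(genes$chrom, lev),
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(reg_gr, gene_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (i in seq_len(nrow(regions))) {
    g <- genes[sh[qh == i], , drop = FALSE]
    regions$genes[i] <- paste(g$gene, collapse = ",")
    cb <- unique(g$cytoband[!is.na(g$cytoband)])
    regions$cytobands[i] <- paste(cb, collapse = ",")
  }
  regions
}

#' Plot an aberration frequency track
#'
#' Gain frequency upward in red, loss frequency downward in green, with a
#' dashed horizontal line at the recurrence threshold.
#'
#' @param track a frequency track from [aberration_frequency()].
#' @param p threshold line (default 0.30).
#' @param file optional PNG path; if NULL, plots to the active device.
#' @export
plot_frequency_track <- function(track, p = 0.30, file = NULL) {
  chroms <- unique(track$chrom)
  sizes <- vapply(chroms, function(ch) max(track$end[track$chrom == ch]), 0)
  offset <- stats::setNames(cumsum(c(0, sizes[-length(sizes)])), chroms)
  x0 <- offset[track$chrom] + track$start
  x1 <- offset[track$chrom] + track$end
  if (!is.null(file)) grDevices::png(file, width = 1200, height = 400)
  graphics::plot(NULL, xlim = c(0, sum(sizes)), ylim = c(-1, 1),
                 xlab = "genome position", ylab = "aberration frequency",
                 xaxt = "n")
  graphics::segments(x0, 0, x1, 0, col = "grey80")
  graphics::rect(x0, 0, x1, track$freq_gain, col = "red", border = NA)
  graphics::rect(x0, -track$freq_loss, x1, 0, col = "green4", border = NA)
  graphics::abline(h = c(p, -p), lty = 2)
  graphics::abline(v = offset[-1], col = "grey70")
  graphics::axis(1, at = offset + sizes / 2, labels = sub("^chr", "", chroms),
                 tick = FALSE, cex.axis = 0.7)
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}
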