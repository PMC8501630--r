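# Ploidy estimation and ploidy-relative aberration calling.
#
# Tumor ploidy for calling purposes is the length-weighted median of the
# segment total copy numbers: the smallest total copy value v such that the
# summed length of segments with total <= v reaches half the covered length
# (lower-median tie rule; integer on integer input). A segment is a gain when
# its total exceeds ploidy + delta and a loss when it falls below
# ploidy - delta.

#' Length-weighted lower median
#'
#' Smallest value v such that the cumulative weight of observations <= v is
#' at least half the total weight.
#'
#' @param x numeric values.
#' @param w non-negative weights (segment lengths).
#' @return the weighted lower median.
#' @export
weighted_median_lower <- function(x, w) {
  stopifnot(length(x) == length(w), length(x) > 0, all(w >= 0), sum(w) > 0)
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= sum(w) / 2)[1]]
}

#' Tumor ploidy of a sample profile
#'
#' Returns the length-weighted median total copy number across the profile's
#' segments. When the profile carries a supplied ploidy (e.g. the upstream
#' tool's own estimate) and `use_supplied = TRUE`, the supplied value takes
#' precedence and the computed median is attached as attribute `computed`.
#'
#' @param profile a [sample_profile()].
#' @param use_supplied prefer a supplied ploidy over the computed median.
#' @return ploidy in copies (real).
#' @export
compute_ploidy <- function(profile, use_supplied = TRUE) {
  seg <- profile$segments
  if (nrow(seg) == 0) stop("cannot compute ploidy of an empty profile")
  computed <- weighted_median_lower(seg$total, seg$end - seg$start + 1)
  if (use_supplied && !is.na(profile$ploidy)) {
    return(structure(profile$ploidy, computed = computed))
  }
  computed
}

#' Call one segment gain/loss/normal relative to ploidy
#'
#' Gain iff total > ploidy + delta; loss iff total < ploidy - delta; normal
#' otherwise. With `delta = 0` this is the strict rule: a total exactly equal
#' to ploidy is not "exceeding" and is normal.
#'
#' @param total segment total copy number(s); vectorized.
#' @param ploidy ploidy in copies (> 0).
#' @param delta non-negative tolerance in copies.
#' @return character vector in {"gain", "loss", "normal"}.
#' @export
call_segment <- function(total, ploidy, delta = 0) {
  stopifnot(ploidy > 0, delta >= 0)
  ifelse(total > ploidy + delta, "gain",
         ifelse(total < ploidy - delta, "loss", "normal"))
}

#' Call all segments of a profile
#'
#' Calling uses the length-weighted-median ploidy computed from the segments
#' (the measure against which gains and losses are defined); pass `ploidy` to
#' override, e.g. with a supplied estimate.
#'
#' @param profile a [sample_profile()].
#' @param delta tolerance in copies (default 0: strict rule).
#' @param ploidy optional ploidy override.
#' @return data.frame `sample, chrom, start, end, total, call, delta`, one
#'   row per segment in profile order.
#' @export
call_profile <- function(profile, delta = 0, ploidy = NULL) {
  if (is.null(ploidy)) ploidy <- compute_ploidy(profile, use_supplied = FALSE)
  seg <- profile$segments
  data.frame(
    sample = seg$sample, chrom = seg$chrom, start = seg$start, end = seg$end,
    total = seg$total,
    call = call_segment(seg$total, ploidy, delta),
    delta = delta,
    stringsAsFactors = FALSE
  )
}

#' Export aberration calls for a cohort as TSV
#' @param profiles list of [sample_profile()].
#' @param path output path.
#' @param delta tolerance in copies.
#' @export
write_calls_table <- function(profiles, path, delta = 0) {
  calls <- do.call(rbind, lapply(profiles, call_profile, delta = delta))
  write_tsv0(calls, path)
}
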