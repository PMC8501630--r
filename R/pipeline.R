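# End-to-end pipeline orchestration: calls -> frequency/recurrence -> scores
# -> group comparisons -> cis integration -> enrichment, with a run manifest.

#' Pipeline configuration
#'
#' @param segments path to a segment table, or a list of [sample_profile()].
#' @param out_dir output directory (created if absent).
#' @param annotation path to a BED4+1 annotation, or an annotation
#'   data.frame.
#' @param expression path to a gene-level log2 expression TSV, or a matrix.
#' @param probe_map optional probe-to-gene map (path or named vector); when
#'   given, the expression input is treated as probe-level and collapsed.
#' @param metadata path to a sample metadata TSV (needs a `sample` column),
#'   or a data.frame.
#' @param gene_sets path to a GMT file, or a named list of gene sets.
#' @param layout path to an arm layout, or a [genome_layout()] (default
#'   packaged 43-arm layout).
#' @param p recurrence threshold in (0, 1] (default 0.30).
#' @param delta_recurrence call tolerance for the recurrence stage (default
#'   0, the strict rule).
#' @param delta_cis call tolerance for the cis grouping (default 0.5).
#' @param w0 focal width cap in bp (default 3e6).
#' @param group_by metadata column to stratify score comparisons on.
#' @param covariates metadata columns to residualize scores on before
#'   comparison (e.g. `c("ploidy", "acf")`).
#' @param alpha family-wise significance level (default 0.05).
#' @param seed integer seed recorded in the manifest and set before running.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(segments, out_dir, annotation = NULL,
                            expression = NULL, probe_map = NULL,
                            metadata = NULL, gene_sets = NULL, layout = NULL,
                            p = 0.30, delta_recurrence = 0, delta_cis = 0.5,
                            w0 = 3e6, group_by = NULL, covariates = NULL,
                            alpha = 0.05, seed = 1) {
  if (!(p > 0 && p <= 1)) stop("recurrence threshold p must be in (0, 1]")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (delta_recurrence < 0 || delta_cis < 0) stop("delta must be >= 0")
  structure(list(segments = segments, out_dir = out_dir,
                 annotation = annotation, expression = expression,
                 probe_map = probe_map, metadata = metadata,
                 gene_sets = gene_sets, layout = layout, p = p,
                 delta_recurrence = delta_recurrence, delta_cis = delta_cis,
                 w0 = w0, group_by = group_by, covariates = covariates,
                 alpha = alpha, seed = seed),
            class = "pipeline_config")
}

resolve_input <- function(x, reader, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("missing ", what, " input: ", x)
    return(reader(x))
  }
  x
}

#' Run the full analysis pipeline
#'
#' Executes, in order: ploidy-relative aberration calls, cross-sample
#' frequency track and recurrent regions, genome-wide and arm-wise complexity
#' scores, stratified group comparisons (optionally covariate-adjusted),
#' cis-gene integration, and gene-set enrichment. Each stage writes a TSV to
#' `out_dir`; a `manifest.tsv` records the configuration, seed and per-stage
#' row counts. Stages whose inputs are not configured (no metadata grouping,
#' no expression, no gene sets) are skipped.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) named list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- config$layout
  if (is.null(layout)) layout <- default_layout()
  if (is.character(layout)) layout <- read_arm_layout(layout)
  metadata <- resolve_input(config$metadata,
                            function(p) utils::read.delim(p, stringsAsFactors = FALSE),
                            "metadata")
  profiles <- if (is.character(config$segments)) {
    read_segment_table(config$segments, layout, metadata = metadata)
  } else config$segments
  annotation <- resolve_input(config$annotation, read_gene_annotation, "annotation")
  expr <- resolve_input(config$expression, read_expression, "expression")
  gene_sets <- resolve_input(config$gene_sets, read_gmt, "gene sets")
  probe_map <- resolve_input(config$probe_map, read_probe_map, "probe map")
  if (!is.null(expr) && !is.null(probe_map)) expr <- collapse_probes(expr, probe_map)
  sample_ids <- vapply(profiles, `[[`, "", "sample")
  if (!is.null(expr)) {
    shared <- intersect(colnames(expr), sample_ids)
    if (!length(shared)) {
      stop("expression samples and segment samples do not overlap: [",
           paste(utils::head(colnames(expr), 3), collapse = ","), "...] vs [",
           paste(utils::head(sample_ids, 3), collapse = ","), "...]")
    }
  }
  out <- list()
  counts <- c()
  emit <- function(df, name) {
    write_tsv0(df, file.path(config$out_dir, paste0(name, ".tsv")))
    counts[[name]] <<- nrow(df)
    df
  }

  message("stage 1/6: aberration calls (delta = ", config$delta_recurrence, ")")
  calls <- do.call(rbind, lapply(profiles, call_profile,
                                 delta = config$delta_recurrence))
  ploidy_tab <- data.frame(
    sample = sample_ids,
    ploidy_supplied = vapply(profiles, `[[`, 0, "ploidy"),
    ploidy_median = vapply(profiles, compute_ploidy, 0, use_supplied = FALSE),
    acf = vapply(profiles, `[[`, 0, "acf"))
  out$calls <- emit(calls, "calls")
  emit(ploidy_tab, "ploidy")

  message("stage 2/6: frequency track and recurrent regions (p = ", config$p, ")")
  track <- aberration_frequency(profiles, delta = config$delta_recurrence)
  out$track <- emit(track, "frequency_track")
  regions <- recurrent_regions(track, config$p)
  if (!is.null(annotation)) regions <- annotate_regions(regions, annotation)
  out$regions <- emit(regions, "recurrent_regions")

  message("stage 3/6: complexity scores (w0 = ", config$w0, ")")
  cfg <- score_config(config$w0)
  out$scores_genome <- emit(score_cohort(profiles, "genome", layout, cfg),
                            "scores_genome")
  out$scores_arm <- emit(score_cohort(profiles, "arm", layout, cfg),
                         "scores_arm")

  if (!is.null(config$group_by)) {
    message("stage 4/6: group comparisons by ", config$group_by)
    if (is.null(metadata)) stop("group_by requires a metadata table")
    groups <- stats::setNames(as.character(metadata[[config$group_by]]),
                              metadata$sample)
    sg <- out$scores_genome
    sa <- out$scores_arm
    if (!is.null(config$covariates)) {
      cov <- metadata[, c("sample", config$covariates), drop = FALSE]
      for (cl in config$covariates) cov[[cl]] <- as.numeric(cov[[cl]])
      sg <- adjust_scores(sg, cov)
      sa <- adjust_scores(sa, cov)
    }
    out$compare_genome <- emit(
      compare_groups(sg, groups, alpha = config$alpha), "comparisons_genome")
    out$compare_arm <- emit(
      compare_groups(sa, groups, alpha = config$alpha), "comparisons_arm")
  } else message("stage 4/6: skipped (no group_by)")

  if (!is.null(expr) && !is.null(annotation)) {
    message("stage 5/6: cis-gene integration (delta = ", config$delta_cis, ")")
    out$cis <- emit(call_cis_genes(expr, profiles, annotation,
                                   regions = out$regions,
                                   delta = config$delta_cis), "cis_genes")
  } else message("stage 5/6: skipped (needs expression + annotation)")

  if (!is.null(out$cis) && !is.null(gene_sets)) {
    message("stage 6/6: gene-set enrichment over ", length(gene_sets), " sets")
    out$enrichment <- emit(
      enrich_gene_sets(out$cis$gene[out$cis$cis], out$cis$gene, gene_sets),
      "enrichment")
  } else message("stage 6/6: skipped (needs cis results + gene sets)")

  manifest <- data.frame(
    key = c("seed", "p", "delta_recurrence", "delta_cis", "w0", "alpha",
            "group_by", "covariates", "n_samples", "package_version",
            paste0("rows_", names(counts))),
    value = c(config$seed, config$p, config$delta_recurrence, config$delta_cis,
              config$w0, config$alpha,
              ifelse(is.null(config$group_by), "", config$group_by),
              paste(config$covariates, collapse = ","),
              length(profiles),
              as.character(utils::packageVersion("cnacomplexity")),
              unlist(counts)),
    stringsAsFactors = FALSE)
  write_tsv0(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(out)
}
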