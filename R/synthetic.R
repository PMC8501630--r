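# Synthetic cohort generator.
#
# Emulates allele-specific segmentation output (the integer post-segmentation
# world, not raw array intensities): per sample a genome tiled by integer
# (major, minor) segments over the layout's arms, with a multimodal ploidy
# mixture (default modes at 2, 3.5 and 5.5 copies), arm-level gains/losses,
# focal events, focal-complex oscillating events, LOH and allelic-asymmetry
# events drawn by Poisson counts, plus matched log2 expression with known cis
# effects. Every cohort carries a full ground-truth table.

#' Specification of one sample group
#'
#' @param name group name (also the sample-id prefix).
#' @param n number of samples.
#' @param ploidy_means,ploidy_weights ploidy mixture components (copies) and
#'   their weights (must sum to 1). Default modes 2 / 3.5 / 5.5.
#' @param arm_rate expected whole-arm +-1 events per genome.
#' @param focal_rate expected focal +-1 events per genome.
#' @param focal_complex_rate expected focal-complex (oscillating) events per
#'   genome.
#' @param focal_len focal event length range in bp.
#' @param complex_k range of oscillating segment counts per focal-complex
#'   event.
#' @param loh_rate expected LOH events per genome (half copy-neutral).
#' @param asym_rate expected allelic-asymmetry events per genome.
#' @param labels named list of metadata labels to stamp on every sample
#'   (e.g. `list(TP53 = "mutated")`).
#' @return a `group_spec` list.
#' @export
group_spec <- function(name, n,
                       ploidy_means = c(2, 3.5, 5.5),
                       ploidy_weights = c(0.6, 0.3, 0.1),
                       arm_rate = 8, focal_rate = 6, focal_complex_rate = 2,
                       focal_len = c(5e5, 1e7), complex_k = c(3, 7),
                       loh_rate = 3, asym_rate = 3, labels = list()) {
  stopifnot(n >= 1, length(ploidy_means) == length(ploidy_weights),
            abs(sum(ploidy_weights) - 1) < 1e-8,
            all(c(arm_rate, focal_rate, focal_complex_rate, loh_rate, asym_rate) >= 0),
            focal_len[1] > 0, focal_len[2] >= focal_len[1],
            complex_k[1] >= 2)
  structure(list(name = name, n = n, ploidy_means = ploidy_means,
                 ploidy_weights = ploidy_weights, arm_rate = arm_rate,
                 focal_rate = focal_rate, focal_complex_rate = focal_complex_rate,
                 focal_len = focal_len, complex_k = complex_k,
                 loh_rate = loh_rate, asym_rate = asym_rate, labels = labels),
            class = "group_spec")
}

#' Demo group specifications
#'
#' Two strata mimicking a high-burden, ploidy-shifted group (labelled TP53
#' mutated) versus a quieter near-diploid group (TP53 wildtype), 30 samples
#' each by default with roughly threefold different event rates.
#'
#' @param n samples per group.
#' @return list of two [group_spec()] objects.
#' @export
demo_group_specs <- function(n = 30) {
  list(
    group_spec("TP53mut", n,
               ploidy_weights = c(0.45, 0.40, 0.15),
               arm_rate = 12, focal_rate = 8, focal_complex_rate = 4,
               loh_rate = 5, asym_rate = 4,
               labels = list(TP53 = "mutated", histology = "adenocarcinoma")),
    group_spec("TP53wt", n,
               ploidy_weights = c(0.80, 0.17, 0.03),
               arm_rate = 4, focal_rate = 2.5, focal_complex_rate = 1,
               loh_rate = 1.5, asym_rate = 1.2,
               labels = list(TP53 = "wildtype", histology = "adenocarcinoma"))
  )
}

# split segments at [s, e] on one chromosome and transform the inside parts
# with fn(major, minor) -> c(major, minor); alleles floored at 0 and
# reordered so major >= minor
apply_interval <- function(seg, chrom, s, e, fn) {
  hit <- which(seg$chrom == chrom & seg$end >= s & seg$start <= e)
  if (!length(hit)) return(seg)
  parts <- list(seg[-hit, , drop = FALSE])
  for (i in hit) {
    row <- seg[i, , drop = FALSE]
    if (row$start < s) {
      left <- row; left$end <- s - 1
      parts[[length(parts) + 1L]] <- left
    }
    mid <- row
    mid$start <- max(row$start, s)
    mid$end <- min(row$end, e)
    ab <- fn(mid$nMajor, mid$nMinor)
    ab <- pmax(0, ab)
    mid$nMajor <- max(ab)
    mid$nMinor <- min(ab)
    parts[[length(parts) + 1L]] <- mid
    if (row$end > e) {
      right <- row; right$start <- e + 1
      parts[[length(parts) + 1L]] <- right
    }
  }
  out <- do.call(rbind, parts)
  out <- out[order(match(out$chrom, unique(seg$chrom)), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate one synthetic sample profile
#'
#' The genome (the layout's arms) is tiled with a baseline drawn from the
#' ploidy mixture: each arm gets total copy `floor(T)` or `floor(T) + 1`
#' (probability = the fractional part of the drawn component mean T), split
#' as evenly as possible between the alleles. Poisson-count events are then
#' applied: whole-arm +-1 gains/losses, focal +-1 events, focal-complex
#' events (k alternating +1/-1 sub-segments), LOH (minor allele to 0,
#' copy-neutral with probability 0.5) and allelic asymmetry (+1 major copy
#' where the minor allele is retained). Events longer than their arm are
#' clipped. The emitted supplied ploidy is the length-weighted mean total
#' copy number (a real-valued, segmentation-tool-like estimate); the
#' aberrant cell fraction is drawn from a Beta distribution with mean ~0.53.
#'
#' @param layout a [genome_layout()].
#' @param spec a [group_spec()].
#' @param seed integer seed; a fixed seed reproduces the profile exactly.
#' @param sample_id sample identifier.
#' @param exclude_chroms chromosomes left ungenerated (default "chrY":
#'   autosomes + X).
#' @return list with `profile` (a [sample_profile()]) and `truth` (data.frame
#'   of injected events).
#' @export
generate_profile <- function(layout, spec, seed, sample_id = "S1",
                             exclude_chroms = "chrY") {
  set.seed(seed)
  arms <- layout[!(layout$chrom %in% exclude_chroms), , drop = FALSE]
  target <- sample(seq_along(spec$ploidy_means), 1, prob = spec$ploidy_weights)
  target <- spec$ploidy_means[target]
  frac <- target - floor(target)
  tot <- floor(target) + stats::rbinom(nrow(arms), 1, frac)
  seg <- data.frame(chrom = arms$chrom, start = arms$start, end = arms$end,
                    nMajor = ceiling(tot / 2), nMinor = floor(tot / 2),
                    stringsAsFactors = FALSE)
  truth <- list()
  note <- function(type, chrom, s, e, detail) {
    truth[[length(truth) + 1L]] <<- data.frame(
      sample = sample_id, type = type, chrom = chrom, start = s, end = e,
      detail = detail, stringsAsFactors = FALSE)
  }
  pick_arm <- function() arms[sample.int(nrow(arms), 1), ]
  focal_window <- function(arm) {
    len <- min(stats::runif(1, spec$focal_len[1], spec$focal_len[2]),
               arm$end - arm$start + 1)
    s <- floor(stats::runif(1, arm$start, arm$end - len + 1))
    c(s, s + ceiling(len) - 1)
  }
  # whole-arm gains/losses
  for (i in seq_len(stats::rpois(1, spec$arm_rate))) {
    arm <- pick_arm()
    if (stats::runif(1) < 0.5) {
      seg <- apply_interval(seg, arm$chrom, arm$start, arm$end,
                            function(a, b) c(a + 1, b))
      note("arm_gain", arm$chrom, arm$start, arm$end, "+1 major")
    } else {
      seg <- apply_interval(seg, arm$chrom, arm$start, arm$end,
                            function(a, b) if (b > 0) c(a, b - 1) else c(a - 1, b))
      note("arm_loss", arm$chrom, arm$start, arm$end, "-1")
    }
  }
  # focal +-1 events
  for (i in seq_len(stats::rpois(1, spec$focal_rate))) {
    arm <- pick_arm()
    w <- focal_window(arm)
    if (stats::runif(1) < 0.5) {
      seg <- apply_interval(seg, arm$chrom, w[1], w[2], function(a, b) c(a + 1, b))
      note("focal_gain", arm$chrom, w[1], w[2], "+1 major")
    } else {
      seg <- apply_interval(seg, arm$chrom, w[1], w[2],
                            function(a, b) if (b > 0) c(a, b - 1) else c(a - 1, b))
      note("focal_loss", arm$chrom, w[1], w[2], "-1")
    }
  }
  # focal-complex oscillating events: k alternating +1 / -1 sub-segments
  for (i in seq_len(stats::rpois(1, spec$focal_complex_rate))) {
    arm <- pick_arm()
    k <- sample(spec$complex_k[1]:spec$complex_k[2], 1)
    w <- focal_window(arm)
    sub <- floor(seq(w[1], w[2] + 1, length.out = k + 1))
    for (j in seq_len(k)) {
      delta <- if (j %% 2 == 1) 1 else -1
      s <- sub[j]; e <- sub[j + 1] - 1
      if (e < s) next
      seg <- apply_interval(seg, arm$chrom, s, e, function(a, b) {
        if (delta > 0) c(a + 1, b) else if (b > 0) c(a, b - 1) else c(a - 1, b)
      })
    }
    note("focal_complex", arm$chrom, w[1], w[2], paste0("k=", k))
  }
  # LOH: minor allele lost; copy-neutral with probability 0.5
  for (i in seq_len(stats::rpois(1, spec$loh_rate))) {
    arm <- pick_arm()
    whole <- stats::runif(1) < 0.5
    w <- if (whole) c(arm$start, arm$end) else {
      len <- min(stats::runif(1, 5e6, 5e7), arm$end - arm$start + 1)
      s <- floor(stats::runif(1, arm$start, arm$end - len + 1))
      c(s, s + ceiling(len) - 1)
    }
    neutral <- stats::runif(1) < 0.5
    seg <- apply_interval(seg, arm$chrom, w[1], w[2], function(a, b) {
      if (neutral) c(a + b, 0) else c(a, 0)
    })
    note("loh", arm$chrom, w[1], w[2],
         if (neutral) "copy-neutral" else "minor lost")
  }
  # allelic asymmetry: +1 major copy where the minor allele is retained
  for (i in seq_len(stats::rpois(1, spec$asym_rate))) {
    arm <- pick_arm()
    len <- min(stats::runif(1, 1e7, 5e7), arm$end - arm$start + 1)
    s <- floor(stats::runif(1, arm$start, arm$end - len + 1))
    e <- s + ceiling(len) - 1
    seg <- apply_interval(seg, arm$chrom, s, e,
                          function(a, b) if (b >= 1) c(a + 1, b) else c(a, b))
    note("asym", arm$chrom, s, e, "+1 major where minor >= 1")
  }
  seg <- merge_equal_segments(cbind(seg, total = seg$nMajor + seg$nMinor))
  L <- seg$end - seg$start + 1
  supplied_ploidy <- sum(L * (seg$nMajor + seg$nMinor)) / sum(L)
  acf <- stats::rbeta(1, 5.3, 4.7)
  md <- spec$labels
  md$group <- spec$name
  profile <- sample_profile(sample_id,
                            seg[, c("chrom", "start", "end", "nMajor", "nMinor")],
                            ploidy = supplied_ploidy, acf = acf, metadata = md)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(), type = character(), chrom = character(),
               start = numeric(), end = numeric(), detail = character(),
               stringsAsFactors = FALSE)
  list(profile = profile, truth = truth_df)
}

#' Generate a synthetic cohort with matched expression
#'
#' Profiles are generated per [group_spec()]; for each gene g and sample s
#' the log2 expression is `mu_g + beta_g * (c_gs - P_s) + N(0, noise_sd)`,
#' where `c_gs` is the total copy number at the gene midpoint, `P_s` the
#' sample's supplied ploidy, and `beta_g = beta` for a randomly chosen
#' `cis_fraction` of genes (0 otherwise). Baseline means `mu_g ~ N(7, 1)`.
#'
#' @param layout a [genome_layout()].
#' @param specs list of [group_spec()] objects.
#' @param annotation gene annotation data.frame (placement of the expression
#'   genes).
#' @param cis_fraction proportion of genes given a true cis effect.
#' @param beta cis effect size in log2 expression units per copy.
#' @param noise_sd expression noise SD in log2 units.
#' @param seed master seed; all randomness (profiles included) derives from
#'   it.
#' @param exclude_chroms passed to [generate_profile()].
#' @return list with `profiles` (named list), `expression` (genes x samples
#'   matrix), `metadata` (data.frame), and `truth` (list: `events`,
#'   `cis_genes` data.frame with per-gene beta, `noise_sd`, `seed`).
#' @export
generate_cohort <- function(layout, specs, annotation, cis_fraction = 0.2,
                            beta = 1, noise_sd = 0.3, seed = 1,
                            exclude_chroms = "chrY") {
  stopifnot(nrow(annotation) > 0, cis_fraction >= 0, cis_fraction <= 1)
  if (inherits(specs, "group_spec")) specs <- list(specs)
  set.seed(seed)
  n_total <- sum(vapply(specs, `[[`, 0, "n"))
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  profiles <- list()
  meta <- list()
  events <- list()
  k <- 0
  for (sp in specs) {
    for (i in seq_len(sp$n)) {
      k <- k + 1
      sid <- sprintf("%s_%02d", sp$name, i)
      g <- generate_profile(layout, sp, seed = seeds[k], sample_id = sid,
                            exclude_chroms = exclude_chroms)
      profiles[[sid]] <- g$profile
      events[[sid]] <- g$truth
      meta[[sid]] <- c(list(sample = sid, group = sp$name,
                            ploidy = g$profile$ploidy, acf = g$profile$acf),
                       sp$labels)
    }
  }
  metadata <- do.call(rbind, lapply(meta, function(m)
    as.data.frame(m, stringsAsFactors = FALSE)))
  rownames(metadata) <- NULL
  # expression with known cis effects (resync RNG after the variable-length
  # profile draws so expression depends only on the master seed)
  set.seed(seed + 1L)
  n_genes <- nrow(annotation)
  n_cis <- round(cis_fraction * n_genes)
  cis_idx <- sample.int(n_genes, n_cis)
  beta_g <- numeric(n_genes)
  beta_g[cis_idx] <- beta
  cn <- gene_copy_matrix(annotation, profiles)
  ploidies <- vapply(profiles, `[[`, 0, "ploidy")
  mu <- stats::rnorm(n_genes, 7, 1)
  dev <- sweep(cn, 2, ploidies)
  dev[is.na(dev)] <- 0
  expr <- mu + beta_g * dev +
    matrix(stats::rnorm(n_genes * length(profiles), 0, noise_sd),
           n_genes, length(profiles))
  dimnames(expr) <- list(annotation$gene, names(profiles))
  truth <- list(
    events = do.call(rbind, events),
    cis_genes = data.frame(gene = annotation$gene, beta = beta_g,
                           stringsAsFactors = FALSE),
    noise_sd = noise_sd, seed = seed
  )
  rownames(truth$events) <- NULL
  list(profiles = profiles, expression = expr, metadata = metadata, truth = truth)
}

#' Place synthetic genes on a layout
#'
#' Genes are placed uniformly over the layout's arms (count per arm
#' proportional to arm length), with lengths drawn uniformly from
#' `gene_length`; cytoband labels are the arm labels.
#'
#' @param layout a [genome_layout()].
#' @param n_genes number of genes.
#' @param gene_length length range in bp.
#' @param seed integer seed.
#' @param exclude_chroms chromosomes to leave gene-free (default "chrY").
#' @return annotation data.frame `gene, chrom, start, end, cytoband`.
#' @export
simulate_annotation <- function(layout, n_genes = 1000,
                                gene_length = c(1e4, 2e5), seed = 1,
                                exclude_chroms = "chrY") {
  set.seed(seed)
  arms <- layout[!(layout$chrom %in% exclude_chroms), , drop = FALSE]
  len <- arms$end - arms$start + 1
  counts <- as.vector(stats::rmultinom(1, n_genes, len / sum(len)))
  rows <- lapply(seq_len(nrow(arms)), function(i) {
    if (counts[i] == 0) return(NULL)
    gl <- stats::runif(counts[i], gene_length[1], gene_length[2])
    s <- floor(stats::runif(counts[i], arms$start[i], arms$end[i] - gl))
    data.frame(chrom = arms$chrom[i], start = s, end = floor(s + gl),
               cytoband = paste0(sub("^chr", "", arms$chrom[i]), arms$arm[i]),
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  ann <- ann[order(match(ann$chrom, unique(arms$chrom)), ann$start), ]
  ann$gene <- sprintf("G%04d", seq_len(nrow(ann)))
  rownames(ann) <- NULL
  ann[, c("gene", "chrom", "start", "end", "cytoband")]
}
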