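# Core data types and readers/writers: genome/arm layout, allele-specific
# segment tables, gene annotation (BED), expression matrices, probe maps, GMT.
#
# Coordinate convention: everything internal is 1-based inclusive (the
# convention of allele-specific segment tables). BED input/output is 0-based
# half-open and is converted at the boundary.

ARM_COLS <- c("chrom", "arm", "start", "end")
SEG_COLS <- c("sample", "chrom", "start", "end", "nMajor", "nMinor", "total")

#' Construct a genome layout of chromosome arms
#'
#' A genome layout is the set of chromosome arms over which arm-wise scores
#' are computed. Arms are 1-based inclusive intervals; within a chromosome
#' they must be non-overlapping with the p arm (when present) before the q
#' arm. Acrocentric chromosomes may carry only a q arm.
#'
#' @param arms data.frame with columns `chrom`, `arm` ("p" or "q"), `start`,
#'   `end` (1-based inclusive).
#' @return A `genome_layout` object (a validated data.frame).
#' @export
genome_layout <- function(arms) {
  stopifnot(is.data.frame(arms))
  if (!all(ARM_COLS %in% names(arms))) {
    stop("layout needs columns: ", paste(ARM_COLS, collapse = ", "))
  }
  arms <- arms[, ARM_COLS]
  arms$chrom <- as.character(arms$chrom)
  arms$arm <- as.character(arms$arm)
  arms$start <- as.numeric(arms$start)
  arms$end <- as.numeric(arms$end)
  if (!all(arms$arm %in% c("p", "q"))) stop("arm labels must be 'p' or 'q'")
  if (any(arms$end < arms$start)) stop("arm end < start in layout")
  if (any(arms$start < 1)) stop("arm coordinates must be >= 1")
  chrom_order <- unique(arms$chrom)
  for (ch in chrom_order) {
    a <- arms[arms$chrom == ch, ]
    a <- a[order(match(a$arm, c("p", "q"))), ]
    if (anyDuplicated(a$arm)) stop("duplicate arm for ", ch)
    if (nrow(a) == 2 && a$end[1] >= a$start[2]) {
      stop("overlapping p/q arms on ", ch)
    }
    if (nrow(a) == 2 && a$arm[1] != "p") stop("p must precede q on ", ch)
  }
  arms <- arms[order(match(arms$chrom, chrom_order), match(arms$arm, c("p", "q"))), ]
  rownames(arms) <- NULL
  structure(arms, class = c("genome_layout", "data.frame"))
}

#' Default hg19-style chromosome-arm layout
#'
#' Cytoband-derived arm table for the 24 human chromosomes with the five
#' acrocentric p arms (13p, 14p, 15p, 21p, 22p) omitted: 43 arms in total.
#' Arm boundaries flank the centromere, so the centromere gap itself is
#' covered by neither arm.
#'
#' @param include_y keep the two chrY arms (default TRUE).
#' @return A [genome_layout()] with 43 arms (41 when `include_y = FALSE`).
#' @export
default_layout <- function(include_y = TRUE) {
  path <- system.file("extdata", "arms_hg19.tsv", package = "cnacomplexity")
  arms <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!include_y) arms <- arms[arms$chrom != "chrY", ]
  genome_layout(arms)
}

#' Read a chromosome-arm layout from file
#'
#' Accepts either a 4-column TSV with header `chrom arm start end`
#' (1-based inclusive) or a UCSC `cytoBand.txt`-style file (5 headerless
#' columns: chrom, start, end, band, gieStain; 0-based half-open), from which
#' arms are derived as the span of the `p*` / `q*` bands, excluding `acen`
#' bands.
#'
#' @param path file path.
#' @return A [genome_layout()].
#' @export
read_arm_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(fields) >= 4 && identical(tolower(fields[1]), "chrom")) {
    arms <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(genome_layout(arms))
  }
  bands <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bands) < 4) stop("unrecognized layout format: ", path)
  names(bands)[1:4] <- c("chrom", "start", "end", "band")
  if (ncol(bands) >= 5) {
    names(bands)[5] <- "stain"
    bands <- bands[bands$stain != "acen", ]
  }
  bands$arm <- substr(bands$band, 1, 1)
  bands <- bands[bands$arm %in% c("p", "q"), ]
  agg_s <- stats::aggregate(start ~ chrom + arm, bands, min)
  agg_e <- stats::aggregate(end ~ chrom + arm, bands, max)
  arms <- merge(agg_s, agg_e, by = c("chrom", "arm"))
  arms$start <- arms$start + 1  # BED-style 0-based half-open -> 1-based inclusive
  genome_layout(arms[, ARM_COLS])
}

#' Construct a sample profile
#'
#' One tumor's ordered allele-specific segments plus (optional) ploidy,
#' aberrant cell fraction and metadata.
#'
#' @param sample sample identifier.
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `nMajor`, `nMinor` (1-based inclusive; integer copy numbers, major >=
#'   minor >= 0). A `total` column is derived.
#' @param ploidy supplied tumor ploidy (real, > 0) or NA. Typically the
#'   upstream segmentation tool's own estimate.
#' @param acf aberrant cell fraction in [0, 1] or NA.
#' @param metadata named list (histology, TP53/EGFR/KRAS status, smoking, ...).
#' @return A `sample_profile` object.
#' @export
sample_profile <- function(sample, segments, ploidy = NA_real_, acf = NA_real_,
                           metadata = list()) {
  stopifnot(is.character(sample), length(sample) == 1L, is.data.frame(segments))
  need <- c("chrom", "start", "end", "nMajor", "nMinor")
  if (!all(need %in% names(segments))) {
    stop("segments need columns: ", paste(need, collapse = ", "))
  }
  seg <- segments
  seg$chrom <- as.character(seg$chrom)
  for (col in c("start", "end", "nMajor", "nMinor")) seg[[col]] <- as.numeric(seg[[col]])
  validate_segments(seg, sample)
  seg$total <- seg$nMajor + seg$nMinor
  seg$sample <- rep(sample, nrow(seg))
  seg <- seg[order(match(seg$chrom, unique(seg$chrom)), seg$start), SEG_COLS]
  rownames(seg) <- NULL
  if (!is.na(ploidy) && ploidy <= 0) stop("ploidy must be > 0")
  if (!is.na(acf) && (acf < 0 || acf > 1)) stop("aberrant cell fraction must be in [0,1]")
  structure(
    list(sample = sample, segments = seg, ploidy = as.numeric(ploidy),
         acf = as.numeric(acf), metadata = metadata),
    class = "sample_profile"
  )
}

validate_segments <- function(seg, sample = "?") {
  if (nrow(seg) == 0) return(invisible(seg))
  if (any(is.na(seg$start) | is.na(seg$end) | is.na(seg$nMajor) | is.na(seg$nMinor))) {
    stop("missing values in segments of sample ", sample)
  }
  if (any(seg$end < seg$start)) {
    bad <- which(seg$end < seg$start)[1]
    stop("segment end < start (sample ", sample, ", row ", bad, ")")
  }
  if (any(seg$nMinor < 0) || any(seg$nMajor < seg$nMinor)) {
    stop("allele copies must satisfy major >= minor >= 0 (sample ", sample, ")")
  }
  if (any(seg$nMajor != round(seg$nMajor)) || any(seg$nMinor != round(seg$nMinor))) {
    stop("allele copy numbers must be integers (sample ", sample, ")")
  }
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("overlapping segments on ", ch, " in sample ", sample)
    }
  }
  invisible(seg)
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("sample_profile ", x$sample, ": ", nrow(x$segments), " segments, ploidy=",
      ifelse(is.na(x$ploidy), "NA", format(x$ploidy, digits = 4)),
      ", acf=", ifelse(is.na(x$acf), "NA", format(x$acf, digits = 3)), "\n", sep = "")
  invisible(x)
}

#' Read an allele-specific segment table
#'
#' Tab-delimited with a header naming at least sample, chromosome, start,
#' end, major and minor columns (`sample chr startpos endpos nMajor nMinor`,
#' with common synonyms accepted), and optional per-sample `ploidy` / `acf`
#' columns. Coordinates are 1-based inclusive.
#'
#' @param path file path.
#' @param layout a [genome_layout()]; segments on chromosomes absent from the
#'   layout are rejected.
#' @param metadata optional data.frame keyed by a `sample` column; its
#'   remaining columns are attached to each profile's metadata.
#' @return Named list of [sample_profile()] objects, one per distinct sample.
#' @export
read_segment_table <- function(path, layout = default_layout(), metadata = NULL) {
  if (!file.exists(path)) stop("segment table not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  cols <- resolve_seg_columns(names(raw))
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad)) {
      stop("malformed ", what, " at line ", bad[1] + 1L, " of ", path)
    }
    v
  }
  seg <- data.frame(
    sample = raw[[cols["sample"]]],
    chrom = raw[[cols["chrom"]]],
    start = num(cols["start"], "start position"),
    end = num(cols["end"], "end position"),
    nMajor = num(cols["nMajor"], "major allele copy number"),
    nMinor = num(cols["nMinor"], "minor allele copy number"),
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(unique(seg$chrom), layout$chrom)
  if (length(unknown)) {
    stop("chromosomes not in layout: ", paste(unknown, collapse = ", "))
  }
  if (any(seg$end < seg$start)) {
    bad <- which(seg$end < seg$start)[1]
    stop("segment end < start at line ", bad + 1L, " of ", path)
  }
  ploidy_col <- intersect(c("ploidy"), tolower(names(raw)))
  acf_col <- intersect(c("acf", "aberrantcellfraction"), tolower(names(raw)))
  names(raw) <- tolower(names(raw))
  profiles <- lapply(split(seq_len(nrow(seg)), seg$sample), function(idx) {
    s <- seg[idx, ]
    pl <- if (length(ploidy_col)) suppressWarnings(as.numeric(raw[[ploidy_col[1]]][idx[1]])) else NA_real_
    af <- if (length(acf_col)) suppressWarnings(as.numeric(raw[[acf_col[1]]][idx[1]])) else NA_real_
    md <- list()
    if (!is.null(metadata)) {
      row <- metadata[metadata$sample == s$sample[1], , drop = FALSE]
      if (nrow(row) == 1) md <- as.list(row[, setdiff(names(row), "sample"), drop = FALSE])
    }
    sample_profile(s$sample[1], s[, c("chrom", "start", "end", "nMajor", "nMinor")],
                   ploidy = pl, acf = af, metadata = md)
  })
  profiles[unique(seg$sample)]
}

resolve_seg_columns <- function(nm) {
  low <- tolower(nm)
  pick <- function(cands, what) {
    hit <- which(low %in% cands)
    if (!length(hit)) stop("segment table lacks a ", what, " column")
    nm[hit[1]]
  }
  c(sample = pick(c("sample", "sampleid", "sample_id"), "sample"),
    chrom = pick(c("chr", "chrom", "chromosome"), "chromosome"),
    start = pick(c("startpos", "start", "start_pos"), "start"),
    end = pick(c("endpos", "end", "end_pos"), "end"),
    nMajor = pick(c("nmajor", "major", "nmaj"), "major allele"),
    nMinor = pick(c("nminor", "minor", "nmin"), "minor allele"))
}

#' Write profiles as a segment table
#'
#' Inverse of [read_segment_table()]: emits
#' `sample chr startpos endpos nMajor nMinor ploidy acf` TSV.
#'
#' @param profiles list of [sample_profile()].
#' @param path output path.
#' @export
write_segment_table <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    s <- p$segments
    data.frame(sample = s$sample, chr = s$chrom, startpos = s$start,
               endpos = s$end, nMajor = s$nMajor, nMinor = s$nMinor,
               ploidy = p$ploidy, acf = p$acf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation (BED4+1)
#'
#' Headerless BED dialect: `chrom start end name [cytoband]`, 0-based
#' half-open; converted to internal 1-based inclusive coordinates.
#'
#' @param path file path.
#' @return data.frame `gene, chrom, start, end, cytoband` sorted by
#'   (chromosome, start). Duplicate gene symbols are an error.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty annotation file: ", path)
    return(data.frame(gene = character(), chrom = character(), start = numeric(),
                      end = numeric(), cytoband = character(), stringsAsFactors = FALSE))
  }
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED annotation needs >= 4 columns")
  ann <- data.frame(
    gene = as.character(bed[[4]]),
    chrom = as.character(bed[[1]]),
    start = as.numeric(bed[[2]]) + 1,  # 0-based half-open -> 1-based inclusive
    end = as.numeric(bed[[3]]),
    cytoband = if (ncol(bed) >= 5) as.character(bed[[5]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(bed[[2]] < 0)) stop("negative coordinates in annotation")
  if (any(ann$end < ann$start)) stop("gene end < start in annotation")
  if (anyDuplicated(ann$gene)) {
    stop("duplicate gene symbols: ",
         paste(unique(ann$gene[duplicated(ann$gene)]), collapse = ", "))
  }
  ann <- ann[order(match(ann$chrom, unique(ann$chrom)), ann$start), ]
  rownames(ann) <- NULL
  ann
}

#' Write gene annotation as BED4+1 (0-based half-open)
#' @param ann annotation data.frame as from [read_gene_annotation()].
#' @param path output path.
#' @export
write_gene_annotation <- function(ann, path) {
  bed <- data.frame(ann$chrom, ann$start - 1, ann$end, ann$gene,
                    ifelse(is.na(ann$cytoband), ".", ann$cytoband))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a log2 expression matrix
#'
#' TSV with the probe/gene identifier in the first column and one column per
#' sample; values are assumed already log2-scaled.
#'
#' @param path file path.
#' @return numeric matrix, rows = identifiers, columns = samples.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate row identifiers in expression matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicate sample columns in expression matrix")
  m
}

#' Write an expression matrix as TSV
#' @param expr matrix with row and column names.
#' @param path output path.
#' @param id_col header for the identifier column.
#' @export
write_expression <- function(expr, path, id_col = "gene") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map (2-column TSV: probe, gene)
#' @param path file path.
#' @return named character vector mapping probe -> gene symbol.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("probe map needs 2 columns (probe, gene)")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Collapse a probe-level expression matrix to gene level
#'
#' Probes with no gene mapping are dropped; a gene measured by k probes gets
#' the arithmetic mean of the k log2 values in each sample.
#'
#' @param expr probe-level matrix (rows = probes).
#' @param probe_to_gene named character vector, probe -> gene.
#' @return gene-level matrix, one row per gene.
#' @export
collapse_probes <- function(expr, probe_to_gene) {
  mapped <- intersect(rownames(expr), names(probe_to_gene))
  if (!length(mapped)) stop("no expression probes are present in the probe map")
  e <- expr[mapped, , drop = FALSE]
  genes <- probe_to_gene[mapped]
  sums <- rowsum(e, group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then member gene symbols, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

write_tsv0 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
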