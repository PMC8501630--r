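test_that("gene copy number is taken from the segment containing the midpoint", {
  p <- mk_profile(mk_seg("chr1", 1, 100, 2, 1),
                  mk_seg("chr1", 101, 200, 1, 1))
  gene_in <- data.frame(gene = "G1", chrom = "chr1", start = 10, end = 40)
  expect_equal(unname(match_gene_copynumber(gene_in, list(p))), 3)

  # gene spanning the breakpoint: midpoint (125) decides
  spanning <- data.frame(gene = "G2", chrom = "chr1", start = 90, end = 160)
  expect_equal(unname(match_gene_copynumber(spanning, list(p))), 2)

  # coverage gap -> missing
  gap <- data.frame(gene = "G3", chrom = "chr1", start = 300, end = 400)
  expect_warning(v <- match_gene_copynumber(gap, list(p)), "uncovered")
  expect_true(is.na(v))
})

test_that("P-to-Z rescaling matches the standard normal quantile scale", {
  expect_equal(pvals_to_z(0.05), 1.6449, tolerance = 1e-4)
  expect_equal(pvals_to_z(0.5), 0)
  expect_equal(pvals_to_z(0.025), 1.96, tolerance = 1e-2)
  # strictly decreasing and antisymmetric
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(pvals_to_z(p)) < 0))
  expect_equal(pvals_to_z(p) + pvals_to_z(1 - p), rep(0, length(p)),
               tolerance = 1e-12)
  expect_error(pvals_to_z(0), "inside")
  expect_error(pvals_to_z(1.2), "inside")
})

test_that("the compound cis criterion behaves on simulated, degenerate and near-miss genes", {
  set.seed(41)
  n <- 100
  copy <- sample(c(1, 2, 3), n, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  calls <- c("loss", "normal", "gain")[copy]
  expr <- 1.0 * (copy - 2) + rnorm(n, 0, 0.5)
  rec <- cis_test(copy, expr, calls)
  expect_true(rec$cis)
  expect_gt(rec$r, 0.4)
  expect_lt(rec$min_p, 0.05)
  expect_equal(rec$z, -qnorm(rec$min_p))

  # constant copy number: r undefined, not cis
  flat <- cis_test(rep(2, n), expr, rep("normal", n))
  expect_true(is.na(flat$r))
  expect_false(flat$cis)

  # strong t-test but weak correlation fails the compound rule
  set.seed(42)
  weak_expr <- 0.15 * (copy - 2) + rnorm(n, 0, 0.5)
  weak <- cis_test(copy, weak_expr, calls)
  if (!is.na(weak$r) && weak$r <= 0.4) expect_false(weak$cis)

  # a t-test arm below min_group contributes no P-value
  copy2 <- c(rep(2, 50), 3, 3)
  calls2 <- c(rep("normal", 50), "gain", "gain")
  rec2 <- cis_test(copy2, rnorm(52), calls2)
  expect_true(is.na(rec2$p_gain) && is.na(rec2$p_loss))
  expect_false(rec2$cis)
})

test_that("the cis flag is invariant under affine rescaling of expression", {
  set.seed(43)
  n <- 60
  copy <- sample(1:3, n, replace = TRUE)
  calls <- c("loss", "normal", "gain")[copy]
  expr <- 0.8 * (copy - 2) + rnorm(n, 0, 0.4)
  base <- cis_test(copy, expr, calls)
  shifted <- cis_test(copy, expr + 100, calls)
  scaled <- cis_test(copy, expr * 3.7, calls)
  expect_equal(base$cis, shifted$cis)
  expect_equal(base$cis, scaled$cis)
  expect_equal(base$r, shifted$r, tolerance = 1e-12)
  expect_equal(base$r, scaled$r, tolerance = 1e-12)
})

test_that("cohort-level cis calling flags genes in recurrent regions and validates samples", {
  lay <- toy_layout()
  ann <- data.frame(gene = c("G1", "G2"), chrom = "c1",
                    start = c(100, 600), end = c(150, 650),
                    cytoband = NA, stringsAsFactors = FALSE)
  set.seed(44)
  profs <- lapply(1:12, function(i) {
    gain <- i <= 6
    sample_profile(paste0("s", i),
                   mk_seg("c1", c(1, 201), c(200, 1000),
                          c(if (gain) 2 else 1, 1), c(1, 1)))
  })
  expr <- matrix(rnorm(2 * 12, 7, 0.3), 2, 12,
                 dimnames = list(ann$gene, paste0("s", 1:12)))
  expr["G1", 1:6] <- expr["G1", 1:6] + 1.5  # expression follows the gain
  regions <- data.frame(chrom = "c1", start = 1, end = 300, direction = "gain",
                        peak_freq = 0.5, mean_freq = 0.5, genes = "",
                        cytobands = "", stringsAsFactors = FALSE)
  res <- call_cis_genes(expr, profs, ann, regions = regions)
  expect_true(res$cis[res$gene == "G1"])
  expect_false(res$cis[res$gene == "G2"])
  expect_true(res$in_recurrent_region[res$gene == "G1"])
  expect_false(res$in_recurrent_region[res$gene == "G2"])

  colnames(expr) <- paste0("x", 1:12)
  expect_error(call_cis_genes(expr, profs, ann), "share no samples")
})

test_that("locus LOH fractions report counts and one-decimal percentages", {
  gene <- data.frame(gene = "TSG", chrom = "c1", start = 100, end = 200)
  profs <- c(
    lapply(1:3, function(i) sample_profile(paste0("l", i),
                                           mk_seg("c1", 1, 1000, 2, 0))),
    lapply(1:2, function(i) sample_profile(paste0("n", i),
                                           mk_seg("c1", 1, 1000, 1, 1))),
    list(sample_profile("hd", mk_seg("c1", 1, 1000, 0, 0)))  # homdel is not LOH
  )
  st <- gene_loh(profs, gene)
  expect_equal(sum(st), 3)
  fr <- loh_fraction(profs, gene)
  expect_equal(fr$k, 3)
  expect_equal(fr$n, 6)
  expect_equal(fr$percent, 50.0)
  expect_equal(fraction_percent(55, 58), 94.8)
  expect_equal(fraction_percent(27, 96), 28.1)
})

test_that("Fisher enrichment matches the hypergeometric tail and BH step-up arithmetic", {
  universe <- sprintf("g%03d", 1:100)
  cis <- universe[1:20]
  sets <- list(hot = c(universe[13:20], universe[90:91]),  # overlap 8, size 10
               cold = universe[95:99])                     # overlap 0, size 5
  res <- enrich_gene_sets(cis, universe, sets)
  hot <- res[res$set == "hot", ]
  expect_equal(hot$overlap, 8)
  expect_equal(hot$p, hyper_tail(100, 10, 20, 8), tolerance = 1e-12)
  cold <- res[res$set == "cold", ]
  expect_gte(cold$p, 0.5)  # depletion is not enrichment

  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  expect_error(enrich_gene_sets(cis, character(0), sets), "empty")
})
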