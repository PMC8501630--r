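test_that("a null spec with ploidy mass at 2 yields a flat balanced diploid genome", {
  spec <- group_spec("null", 1, ploidy_means = 2, ploidy_weights = 1,
                     arm_rate = 0, focal_rate = 0, focal_complex_rate = 0,
                     loh_rate = 0, asym_rate = 0)
  g <- generate_profile(default_layout(), spec, seed = 1)
  seg <- g$profile$segments
  expect_true(all(seg$nMajor == 1 & seg$nMinor == 1))
  expect_equal(nrow(g$truth), 0)
  sc <- score_genome_wide(g$profile)
  expect_equal(unname(unlist(sc[, c("var", "steep", "curv", "dev", "gain",
                                    "loss", "loh", "asym")])), rep(0, 8))
})

test_that("generation is byte-identical under a fixed seed", {
  lay <- default_layout()
  spec <- demo_group_specs()[[1]]
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  g1 <- generate_profile(lay, spec, seed = 99, sample_id = "T")
  g2 <- generate_profile(lay, spec, seed = 99, sample_id = "T")
  write_segment_table(list(g1$profile), f1)
  write_segment_table(list(g2$profile), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g1$truth, g2$truth)

  ann <- simulate_annotation(lay, n_genes = 50, seed = 3)
  c1 <- generate_cohort(lay, group_spec("g", 3), ann, seed = 5)
  c2 <- generate_cohort(lay, group_spec("g", 3), ann, seed = 5)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$truth$cis_genes, c2$truth$cis_genes)
})

test_that("emitted segment tables pass the real reader's validation (round-trip)", {
  lay <- default_layout()
  coh <- generate_cohort(lay, demo_group_specs(n = 3),
                         simulate_annotation(lay, 30, seed = 2), seed = 11)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_segment_table(coh$profiles, tmp)
  back <- read_segment_table(tmp, lay)
  expect_setequal(names(back), names(coh$profiles))
  for (s in names(back)) {
    expect_equal(back[[s]]$segments, coh$profiles[[s]]$segments)
    expect_equal(back[[s]]$ploidy, coh$profiles[[s]]$ploidy, tolerance = 1e-6)
  }
})

test_that("supplied ploidies cluster at the configured mixture components", {
  lay <- default_layout()
  spec <- group_spec("mix", 1, ploidy_means = c(2, 3.5, 5.5),
                     ploidy_weights = c(1 / 3, 1 / 3, 1 / 3),
                     arm_rate = 3, focal_rate = 2, focal_complex_rate = 1,
                     loh_rate = 1, asym_rate = 1)
  ploidies <- vapply(1:40, function(i) {
    generate_profile(lay, spec, seed = 1000 + i)$profile$ploidy
  }, 0)
  dist_to_mode <- vapply(ploidies, function(p) min(abs(p - c(2, 3.5, 5.5))), 0)
  expect_gt(mean(dist_to_mode <= 0.25), 0.9)
  # all three modes actually drawn
  nearest <- vapply(ploidies, function(p) which.min(abs(p - c(2, 3.5, 5.5))), 0L)
  expect_setequal(unique(nearest), 1:3)
})

test_that("every injected event maps onto emitted segments", {
  lay <- default_layout()
  g <- generate_profile(lay, demo_group_specs()[[1]], seed = 77, sample_id = "T")
  seg <- g$profile$segments
  for (i in seq_len(nrow(g$truth))) {
    ev <- g$truth[i, ]
    cover <- seg[seg$chrom == ev$chrom & seg$start <= ev$end & seg$end >= ev$start, ]
    covered <- sum(pmin(cover$end, ev$end) - pmax(cover$start, ev$start) + 1)
    expect_equal(covered, ev$end - ev$start + 1, info = ev$type)
  }
})

test_that("a focal-complex event raises curv on its chromosome only", {
  lay <- default_layout()
  spec_cx <- group_spec("cx", 1, ploidy_means = 2, ploidy_weights = 1,
                        arm_rate = 0, focal_rate = 0, focal_complex_rate = 2,
                        complex_k = c(5, 5), loh_rate = 0, asym_rate = 0)
  gcx <- generate_profile(lay, spec_cx, seed = 21)
  expect_gt(sum(gcx$truth$type == "focal_complex"), 0)
  sa <- score_arm_wise(gcx$profile, lay)
  sa$chrom <- paste0("chr", sub("[pq]$", "", sa$region))
  expect_gt(sum(sa$curv > 0, na.rm = TRUE), 0)
  quiet <- sa[!(sa$chrom %in% gcx$truth$chrom) & !is.na(sa$curv), ]
  expect_true(all(quiet$curv == 0))
})

test_that("cohorts with contrasting event rates separate on the dev score end to end", {
  lay <- default_layout()
  specs <- list(
    group_spec("hi", 15, ploidy_means = 2, ploidy_weights = 1,
               arm_rate = 12, focal_rate = 8, focal_complex_rate = 4,
               loh_rate = 5, asym_rate = 4, labels = list(TP53 = "mutated")),
    group_spec("lo", 15, ploidy_means = 2, ploidy_weights = 1,
               arm_rate = 4, focal_rate = 2.5, focal_complex_rate = 1,
               loh_rate = 1.5, asym_rate = 1.2, labels = list(TP53 = "wildtype"))
  )
  coh <- generate_cohort(lay, specs, simulate_annotation(lay, 40, seed = 4),
                         seed = 17)
  scores <- score_cohort(coh$profiles, "genome")
  groups <- setNames(coh$metadata$TP53, coh$metadata$sample)
  res <- compare_groups(scores, groups)
  dev_row <- res[res$index == "dev", ]
  expect_equal(dev_row$direction, "mutated")
  expect_true(dev_row$significant)
})

test_that("a cis-free cohort yields expression independent of copy number", {
  lay <- default_layout()
  ann <- simulate_annotation(lay, 200, seed = 6)
  coh <- generate_cohort(lay, group_spec("g", 40, ploidy_means = 2,
                                         ploidy_weights = 1),
                         ann, cis_fraction = 0, seed = 23)
  res <- call_cis_genes(coh$expression, coh$profiles, ann)
  expect_lte(mean(res$cis), 0.02)
})
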