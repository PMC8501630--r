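region_chr1 <- function(end = 100e6) data.frame(chrom = "chr1", start = 1, end = end)

test_that("a flat balanced diploid region scores zero on every index", {
  p <- mk_profile(mk_seg("chr1", 1, 100e6, 1, 1))
  sc <- score_region(p, region_chr1(), ploidy = 2)
  expect_equal(unname(sc), rep(0, 8))
})

test_that("a single focal gain on a diploid arm reproduces the hand-derived scores", {
  # 100 Mb arm: (1,1) x 45 Mb, (2,1) x 10 Mb, (1,1) x 45 Mb; P = 2, w0 = 3 Mb
  p <- mk_profile(mk_seg("chr1", 1, 45e6, 1, 1),
                  mk_seg("chr1", 45e6 + 1, 55e6, 2, 1),
                  mk_seg("chr1", 55e6 + 1, 100e6, 1, 1))
  sc <- score_region(p, region_chr1(), ploidy = 2, config = score_config(3e6))
  expect_equal(sc[["var"]], 0.10)
  expect_equal(sc[["steep"]], 0.06)
  expect_equal(sc[["curv"]], 0.03)
  expect_equal(sc[["dev"]], 0.10)
  expect_equal(sc[["gain"]], 0.10)
  expect_equal(sc[["loss"]], 0)
  expect_equal(sc[["loh"]], 0)
  expect_equal(sc[["asym"]], 0.10)
})

test_that("copy-neutral LOH triggers only the loh index", {
  p <- mk_profile(mk_seg("chr1", 1, 80e6, 1, 1),
                  mk_seg("chr1", 80e6 + 1, 100e6, 2, 0))
  sc <- score_region(p, region_chr1(), ploidy = 2)
  expect_equal(unname(sc[c("var", "steep", "curv", "dev", "gain", "loss")]),
               rep(0, 6))
  expect_equal(sc[["loh"]], 0.4)
  expect_equal(sc[["asym"]], 0)
})

test_that("homozygous deletions count as loss, never as loh", {
  p <- mk_profile(mk_seg("chr1", 1, 80e6, 1, 1),
                  mk_seg("chr1", 80e6 + 1, 100e6, 0, 0))
  sc <- score_region(p, region_chr1(), ploidy = 2)
  expect_equal(sc[["loh"]], 0)
  expect_equal(sc[["loss"]], 0.4)
})

test_that("all eight scores match the per-base oracle on random profiles", {
  w0 <- 50
  for (seed in 1:50) {
    fx <- random_tiling_profile(seed)
    seg <- fx$profile$segments
    region <- do.call(rbind, lapply(unique(seg$chrom), function(ch)
      data.frame(chrom = ch, start = 1, end = max(seg$end[seg$chrom == ch]))))
    ploidy <- oracle_ploidy(fx$a + fx$b)
    got <- score_region(fx$profile, region, ploidy = ploidy,
                        config = score_config(w0))
    want <- oracle_scores(fx$ch, fx$a, fx$b, ploidy, w0)
    expect_equal(got, want, tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(got[["dev"]], got[["gain"]] + got[["loss"]], tolerance = 1e-12)
  }
})

test_that("scores are invariant under segment splitting and sub-cap length rescaling", {
  p <- mk_profile(mk_seg("chr1", 1, 400, 1, 1),
                  mk_seg("chr1", 401, 500, 2, 1),
                  mk_seg("chr1", 501, 900, 1, 0))
  region <- data.frame(chrom = "chr1", start = 1, end = 900)
  base <- score_region(p, region, ploidy = 2, config = score_config(3e6))

  # split the middle segment into two adjacent halves with identical (a,b)
  split <- mk_profile(mk_seg("chr1", 1, 400, 1, 1),
                      mk_seg("chr1", 401, 450, 2, 1),
                      mk_seg("chr1", 451, 500, 2, 1),
                      mk_seg("chr1", 501, 900, 1, 0))
  expect_equal(score_region(split, region, ploidy = 2,
                            config = score_config(3e6)), base)

  # uniform x10 rescaling with every length still below the w0 cap
  scaled <- mk_profile(mk_seg("chr1", 1, 4000, 1, 1),
                       mk_seg("chr1", 4001, 5000, 2, 1),
                       mk_seg("chr1", 5001, 9000, 1, 0))
  region10 <- data.frame(chrom = "chr1", start = 1, end = 9000)
  expect_equal(score_region(scaled, region10, ploidy = 2,
                            config = score_config(3e6)), base)
})

test_that("focal complex events raise steep and curv; whole-arm gains do not raise curv", {
  flat <- mk_seg("chr1", 1, 100e6, 1, 1)
  region <- region_chr1()
  base <- score_region(mk_profile(flat), region, ploidy = 2)

  # oscillating cluster: five alternating short segments
  osc <- mk_profile(mk_seg("chr1", 1, 40e6, 1, 1),
                    mk_seg("chr1", 40e6 + 1, 41e6, 2, 1),
                    mk_seg("chr1", 41e6 + 1, 42e6, 1, 1),
                    mk_seg("chr1", 42e6 + 1, 43e6, 2, 1),
                    mk_seg("chr1", 43e6 + 1, 44e6, 1, 1),
                    mk_seg("chr1", 44e6 + 1, 100e6, 1, 1))
  sc_osc <- score_region(osc, region, ploidy = 2)
  expect_gt(sc_osc[["steep"]], base[["steep"]])
  expect_gt(sc_osc[["curv"]], base[["curv"]])

  # whole-arm gain: dev/gain move, curv does not
  armgain <- mk_profile(mk_seg("chr1", 1, 100e6, 2, 1))
  sc_arm <- score_region(armgain, region, ploidy = 2)
  expect_gt(sc_arm[["gain"]], 0)
  expect_gt(sc_arm[["dev"]], 0)
  expect_equal(sc_arm[["curv"]], 0)
})

test_that("genome-wide scoring returns exactly eight deterministic values", {
  fx <- random_tiling_profile(7)
  sc1 <- score_genome_wide(fx$profile)
  sc2 <- score_genome_wide(fx$profile)
  expect_equal(sc1, sc2)
  expect_equal(sc1$region, "genome")
  expect_length(unlist(sc1[, c("var", "steep", "curv", "dev", "gain",
                               "loss", "loh", "asym")]), 8)
})

test_that("arm-wise scoring emits one row per layout arm with missing-arm handling", {
  lay <- toy_layout()
  p <- mk_profile(mk_seg("c1", 1, 500, 1, 1),       # only c1 covered
                  mk_seg("c1", 501, 700, 2, 1),
                  mk_seg("c1", 701, 1000, 1, 1))
  sa <- score_arm_wise(p, lay)
  idx_cols <- c("var", "steep", "curv", "dev", "gain", "loss", "loh", "asym")
  expect_equal(nrow(sa), 3)
  expect_true(all(is.na(sa[sa$region == "c2q", idx_cols])))
  # aberration confined to c1q: c1p scores 0 except possibly dev family
  c1p <- sa[sa$region == "c1p", ]
  expect_equal(unname(unlist(c1p[, c("var", "steep", "curv", "gain",
                                     "loss", "loh", "asym")])), rep(0, 7))
})

test_that("J4 = J5 + J6 holds for every sample and region", {
  lay <- toy_layout()
  for (seed in 1:10) {
    fx <- random_tiling_profile(seed + 300)
    sg <- score_genome_wide(fx$profile)
    expect_equal(sg$dev, sg$gain + sg$loss, tolerance = 1e-12)
  }
})
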