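# Shared fixtures and independent oracles.

mk_seg <- function(chrom, start, end, a, b) {
  data.frame(chrom = chrom, start = start, end = end, nMajor = a, nMinor = b,
             stringsAsFactors = FALSE)
}

mk_profile <- function(..., sample = "s1", ploidy = NA_real_, acf = NA_real_,
                       metadata = list()) {
  sample_profile(sample, do.call(rbind, list(...)), ploidy = ploidy,
                 acf = acf, metadata = metadata)
}

# a tiny two-chromosome layout for unit tests (1-based inclusive)
toy_layout <- function() {
  genome_layout(data.frame(
    chrom = c("c1", "c1", "c2"),
    arm = c("p", "q", "q"),
    start = c(1, 501, 1),
    end = c(500, 1000, 800)
  ))
}

# --- independent per-base oracle for ploidy and the eight scores ------------
# Operates on per-base vectors (chromosome id, major, minor), never on the
# package's segment machinery.

oracle_ploidy <- function(ct) sort(ct)[ceiling(length(ct) / 2)]

oracle_scores <- function(ch, a, b, ploidy, w0) {
  ct <- a + b
  W <- length(ct)
  m <- oracle_ploidy(ct)
  j1 <- mean(abs(ct - m))
  j4 <- mean(abs(ct - ploidy))
  j5 <- mean(pmax(0, ct - ploidy))
  j6 <- mean(pmax(0, ploidy - ct))
  j7 <- mean((b == 0 & ct >= 1) * (a - b))
  j8 <- mean((b >= 1) * (a - b))
  j2 <- 0
  j3 <- 0
  for (cc in unique(ch)) {
    i <- which(ch == cc)
    r <- rle(paste(a[i], b[i]))
    L <- r$lengths
    starts <- cumsum(c(1, L[-length(L)]))
    ctr <- ct[i][starts]
    n <- length(L)
    if (n >= 2) j2 <- j2 + sum(abs(diff(ctr)) * pmin(L[-n], L[-1], w0))
    if (n >= 3) {
      for (j in 2:(n - 1)) {
        lo <- min(ctr[j - 1], ctr[j + 1])
        hi <- max(ctr[j - 1], ctr[j + 1])
        e <- if (ctr[j] < lo) lo - ctr[j] else if (ctr[j] > hi) ctr[j] - hi else 0
        j3 <- j3 + e * min(L[j], w0)
      }
    }
  }
  c(var = j1, steep = j2 / W, curv = j3 / W, dev = j4, gain = j5, loss = j6,
    loh = j7, asym = j8)
}

# random genome (<= 1e4 bases) tiling 1-2 chromosomes; returns both the
# segment-level profile and the per-base expansion for the oracle
random_tiling_profile <- function(seed, max_bases = 1e4, amin = 0) {
  set.seed(seed)
  n_chrom <- sample(1:2, 1)
  segs <- list()
  ch_v <- a_v <- b_v <- integer(0)
  for (k in seq_len(n_chrom)) {
    chrom <- paste0("c", k)
    n_seg <- sample(3:8, 1)
    lens <- sample(5:floor(max_bases / (n_chrom * n_seg)), n_seg, replace = TRUE)
    a <- sample(amin:4, n_seg, replace = TRUE)
    b <- vapply(a, function(ai) sample(0:ai, 1), 0L)
    start <- cumsum(c(1, lens[-n_seg]))
    segs[[k]] <- mk_seg(chrom, start, start + lens - 1, a, b)
    ch_v <- c(ch_v, rep(k, sum(lens)))
    a_v <- c(a_v, rep(a, lens))
    b_v <- c(b_v, rep(b, lens))
  }
  list(profile = sample_profile("rnd", do.call(rbind, segs)),
       ch = ch_v, a = a_v, b = b_v)
}

# exact hypergeometric upper tail: P(X >= k) for overlap of a size-n draw
# with a size-K set in a universe of N
hyper_tail <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# write a small segment TSV fixture
write_seg_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
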