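flat_track <- function(value, nbins = 100, bin = 50, chrom = "cX") {
  signal_track(rep(chrom, nbins), (seq_len(nbins) - 1L) * bin,
               rep(value, nbins), bin)
}

test_that("RPKM normalisation follows the formula and its invariances", {
  t1 <- rpkm_normalize(10, total_mapped_reads = 1e6, bin_size = 1000)
  expect_equal(t1$value, 10)
  # doubling counts and library size leaves the track unchanged
  set.seed(41)
  counts <- data.frame(chrom = "c1", start = seq(0, 900, 100),
                       count = rpois(10, 30))
  a <- rpkm_normalize(counts, 2e6, 100)
  counts2 <- counts; counts2$count <- counts2$count * 2
  b <- rpkm_normalize(counts2, 4e6, 100)
  expect_equal(a$value, b$value)
  # independently coded one-line oracle
  expect_equal(a$value, counts$count / ((100 / 1000) * (2e6 / 1e6)))
  expect_error(rpkm_normalize(counts, 0, 100), "total_mapped_reads")
})

test_that("bedGraph IO round-trips a track and re-bins irregular input", {
  tr <- flat_track(5, nbins = 20)
  tr$value <- seq_len(20)
  tr <- signal_track(tr$chrom, tr$start, seq_len(20), 50)
  f <- tempfile(fileext = ".bedgraph")
  write_signal_track(tr, f)
  back <- read_signal_track(f)
  expect_equal(back$value, tr$value)
  expect_equal(attr(back, "bin_size"), 50L)
  # irregular intervals: one 100 bp interval at value 2 and one 50 bp at 8
  writeLines(c("c1\t0\t100\t2", "c1\t100\t150\t8"),
             f2 <- tempfile(fileext = ".bedgraph"))
  rb <- read_signal_track(f2, bin_size = 50)
  expect_equal(rb$value, c(2, 2, 8))
  # length-weighted averaging across a bin boundary
  writeLines(c("c1\t0\t25\t4", "c1\t25\t50\t8"), f3 <- tempfile(fileext = ".bedgraph"))
  rb3 <- read_signal_track(f3, bin_size = 50)
  expect_equal(rb3$value, 6)
})

test_that("call_peaks finds rectangular blocks exactly and obeys knobs", {
  tr <- flat_track(1, nbins = 100)
  expect_equal(nrow(call_peaks(tr, threshold_rpkm = 5)), 0L)
  v <- rep(1, 100); v[21:30] <- 10; v[41:44] <- 10
  tr2 <- signal_track(rep("cX", 100), (0:99) * 50, v, 50)
  pk <- call_peaks(tr2, threshold_rpkm = 5)
  expect_equal(pk$start, c(1000L, 2000L))
  expect_equal(pk$end, c(1500L, 2200L))
  expect_equal(pk$summit, c(1000L, 2000L))  # leftmost max bin
  # min_width drops the narrow one
  expect_equal(nrow(call_peaks(tr2, 5, min_width = 300)), 1L)
  # merge_gap joins across the valley (gap 10 bins = 500 bp)
  merged <- call_peaks(tr2, 5, merge_gap = 500)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(1000L, 2200L))
  # raising the threshold drops peaks in order of height
  v3 <- rep(1, 500)
  for (i in 1:5) v3[(i * 80):(i * 80 + 5)] <- i * 10
  tr3 <- signal_track(rep("cX", 500), (0:499) * 50, v3, 50)
  n_pk <- vapply(c(5, 15, 25, 35, 45),
                 function(th) nrow(call_peaks(tr3, th)), integer(1))
  expect_equal(n_pk, 5:1)
})

test_that("call_peaks boundaries are idempotent on a rasterized re-track", {
  set.seed(43)
  v <- rpois(200, 4); v[50:60] <- 30; v[120:130] <- 25
  tr <- signal_track(rep("cX", 200), (0:199) * 50, v, 50)
  pk <- call_peaks(tr, 15)
  raster <- rep(0, 200)
  for (i in seq_len(nrow(pk))) {
    raster[(pk$start[i] / 50 + 1):(pk$end[i] / 50)] <- pk$max_rpkm[i]
  }
  tr2 <- signal_track(rep("cX", 200), (0:199) * 50, raster, 50)
  pk2 <- call_peaks(tr2, 15)
  expect_equal(pk2$start, pk$start)
  expect_equal(pk2$end, pk$end)
})

test_that("meta_profile returns constants exactly and flags n = 1", {
  tr <- flat_track(5, nbins = 400)
  anchors <- data.frame(chrom = "cX", start = c(5000, 8000), end = c(5013, 8013))
  mp <- meta_profile(tr, anchors, half_window = 1000, profile_bin = 50)
  expect_true(all(mp$mean == 5))
  expect_true(all(mp$se == 0))
  expect_true(all(mp$n == 2))
  one <- meta_profile(tr, anchors[1, , drop = FALSE], half_window = 500,
                      profile_bin = 50)
  expect_true(all(one$n == 1))
  expect_true(all(one$se == 0))
  expect_error(meta_profile(tr, anchors, half_window = 99, profile_bin = 50),
               "multiple")
})

test_that("meta_profile reproduces a pure distance function of the anchor", {
  # track value = distance from bin start to the single anchor midpoint
  bin <- 50L
  nb <- 400L
  mid <- 10000L
  vals <- abs((seq_len(nb) - 1L) * bin - mid)
  tr <- signal_track(rep("cX", nb), (seq_len(nb) - 1L) * bin, vals, bin)
  anchors <- data.frame(chrom = "cX", start = mid, end = mid)  # midpoint = mid
  mp <- meta_profile(tr, anchors, half_window = 2000, profile_bin = bin)
  # at offset o the sampled position mid+o falls in the bin holding value |o|
  expect_equal(mp$mean, abs(mp$offset))
})

test_that("anchors near chromosome ends contribute only in-range bins", {
  tr <- flat_track(5, nbins = 40)  # 2 kb chromosome
  anchors <- data.frame(chrom = "cX", start = 100, end = 113)
  mp <- meta_profile(tr, anchors, half_window = 1000, profile_bin = 50)
  expect_true(all(mp$offset >= -106))
  expect_true(max(mp$offset) == 1000)
})

test_that("rex membership is decided by >= 1 bp overlap", {
  peaks <- data.frame(peak = "p1", chrom = "cX", start = 1000L, end = 2000L,
                      summit = 1500L, max_rpkm = 50)
  anchors <- data.frame(chrom = "cX",
                        start = c(1200L, 987L, 988L, 2000L, 1999L),
                        end = c(1213L, 1000L, 1001L, 2013L, 2012L))
  got <- assign_rex_membership(anchors, peaks)
  expect_equal(got, c("in-rex", "not-in-rex", "in-rex", "not-in-rex", "in-rex"))
  # brute-force overlap oracle on random intervals
  set.seed(44)
  a <- data.frame(chrom = "c1", start = sample(0:500, 100, TRUE))
  a$end <- a$start + 13L
  p <- data.frame(peak = paste0("p", 1:5), chrom = "c1",
                  start = sample(0:400, 5), max_rpkm = 1)
  p$end <- p$start + sample(30:80, 5)
  p$summit <- p$start
  got <- assign_rex_membership(a, p)
  oracle <- vapply(seq_len(nrow(a)), function(i) {
    any(a$start[i] < p$end & a$end[i] > p$start)
  }, logical(1))
  expect_equal(got == "in-rex", oracle)
})

test_that("annotate_rex lists ordered motifs, gaps, and motif-free peaks", {
  peaks <- data.frame(peak = c("rex_a", "rex_b", "rex_c"), chrom = "cX",
                      start = c(1000L, 5000L, 9000L),
                      end = c(2000L, 6000L, 10000L),
                      summit = c(1400L, 5500L, 9100L),
                      max_rpkm = c(90, 40, 20))
  hits <- data.frame(chrom = "cX",
                     start = c(1200L, 1246L, 5100L),
                     end = c(1213L, 1259L, 5113L),
                     strand = c("+", "-", "+"), score = 0,
                     ln_p = c(-19.09, -13.80, -14.25),
                     motif = c("MEX", "MEXII", "MEX"))
  ann <- annotate_rex(peaks, hits)
  expect_equal(ann$n_motifs, c(2L, 1L, 0L))
  expect_equal(ann$gaps_bp, c("33", "", ""))  # 1246 - 1213 = 33 bp apart
  expect_match(ann$motifs[1], "MEX\\[-19.09\\]\\(\\+\\),MEXII\\[-13.80\\]\\(-\\)")
  expect_equal(ann$motifs[3], "")
  long <- attr(ann, "motif_table")
  expect_equal(nrow(long), 3L)
  expect_equal(long$gap_to_next[long$peak == "rex_a"], c(33L, NA))
})

test_that("discovery windows are summit-centred, clipped and written as FASTA", {
  g <- c(cX = random_dna(20000))
  peaks <- data.frame(peak = c("p1", "p2"), chrom = "cX",
                      start = c(9000L, 0L), end = c(11000L, 400L),
                      summit = c(10000L, 100L), max_rpkm = 10)
  fa <- tempfile(fileext = ".fa")
  win <- discovery_windows(peaks, g, width = 500, path = fa)
  expect_equal(as.character(win[[1]]), toupper(substr(g[["cX"]], 9751, 10250)))
  expect_equal(names(win)[1], "p1|cX:9750-10250")
  expect_equal(Biostrings::width(win)[2], 350L)  # clipped at the left edge
  expect_equal(attr(win, "clipped"), c(FALSE, TRUE))
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(back), 2L)
  bad <- peaks; bad$summit[1] <- 99999L
  expect_error(discovery_windows(bad, g), "bounds")
})
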