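# a small configuration keeps the generator tests fast; the full-scale
# layout is exercised in the enrichment-recovery acceptance test
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             chroms = data.frame(name = c("chrX", "chrI"),
                                 class = c("X", "autosome"),
                                 length = c(1e5, 1e5)),
             x_density_per_mb = 300, a_density_per_mb = 50,
             n_rex = 3L, ...)
}

test_that("generation is a pure function of (config, seed)", {
  cfg <- small_config(seed = 9)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  c <- simulate_genome(cfg, seed = 10)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("zero density yields an empty truth set", {
  cfg <- sim_config(chroms = data.frame(name = "chrA", class = "autosome",
                                        length = 5e4),
                    a_density_per_mb = 0, n_rex = 0L)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("an impossible density raises a placement error", {
  cfg <- sim_config(chroms = data.frame(name = "chrA", class = "autosome",
                                        length = 200),
                    a_density_per_mb = 2e5, n_rex = 0L)
  expect_error(simulate_genome(cfg), "density too high")
})

test_that("planted truth intervals hold the planted words, without overlap", {
  cfg <- small_config(seed = 13)
  sim <- simulate_genome(cfg)
  g <- sim$genome
  k <- cfg$matrix$length
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    seq <- as.character(Biostrings::subseq(g[[tr$chrom]], tr$start + 1, tr$end))
    expect_equal(if (tr$strand == "+") seq else rc_string(seq), tr$word)
  }
  for (ch in unique(sim$truth$chrom)) {
    tt <- sim$truth[sim$truth$chrom == ch, ]
    tt <- tt[order(tt$start), ]
    expect_true(all(diff(tt$start) >= k))
  }
  # rex bookkeeping: every rex id in truth has a site record spanning it
  expect_true(all(stats::na.omit(sim$truth$rex_id) %in% sim$rex_sites$rex_id))
  in_rex <- sim$truth[sim$truth$in_rex, ]
  for (i in seq_len(nrow(in_rex))) {
    site <- sim$rex_sites[sim$rex_sites$rex_id == in_rex$rex_id[i], ]
    expect_true(in_rex$start[i] >= site$start && in_rex$end[i] <= site$end)
  }
})

test_that("planted consensus words are recovered in full by the scanner", {
  cfg <- small_config(seed = 14)
  sim <- simulate_genome(cfg)
  hits <- scan_genome(sim$genome, cfg$matrix,
                      threshold = max_theoretical_ln_p(cfg$matrix))
  # every hit at the consensus threshold sits on a planted interval
  planted <- paste(sim$truth$chrom, sim$truth$start)
  expect_true(all(paste(hits$chrom, hits$start) %in% planted))
  # and every planted exact-consensus word is found
  cons <- sim$truth[sim$truth$word == consensus_word(cfg$matrix), ]
  expect_true(all(paste(cons$chrom, cons$start) %in%
                    paste(hits$chrom, hits$start)))
})

test_that("simulated coverage is flat without bumps and reproducible", {
  lens <- c(chrX = 2e5)
  a <- simulate_coverage(lens, rex_sites = NULL, seed = 71)
  b <- simulate_coverage(lens, rex_sites = NULL, seed = 71)
  expect_identical(a$counts, b$counts)
  # mean RPKM within 3 SE of the expected background level
  bg <- attr(a$truth, "background_rpkm")
  se <- sd(a$track$value) / sqrt(nrow(a$track))
  expect_lt(abs(mean(a$track$value) - bg), 3 * se)
})

test_that("coverage bumps appear at the planted summits", {
  lens <- c(chrX = 4e5)
  sites <- data.frame(rex_id = c("r1", "r2"), chrom = "chrX",
                      summit = c(1e5, 3e5))
  cov <- simulate_coverage(lens, sites, background_rate = 20,
                           amplitude = 160, seed = 72)
  pk <- call_peaks(cov$track, threshold_rpkm = 4 * attr(cov$truth,
                                                        "background_rpkm"),
                   min_width = 200)
  expect_equal(nrow(pk), 2L)
  expect_lt(max(abs(pk$summit - sites$summit)), 500)
})

test_that("noise-free qPCR tables close the loop with the quantification module", {
  true_lv <- c(rex_a = 0.04, rex_b = 0.01, ctrl1 = 0.02, ctrl2 = 0.02)
  sim <- simulate_qpcr(true_lv, noise_cv = 0, n_replicates = 3, seed = 81)
  curve <- fit_standard_curve(sim$standards)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-9)
  lv <- sim$samples
  lv$level <- quantify_ct(lv$ct, curve)
  norm <- normalize_to_controls(lv, c("ctrl1", "ctrl2"))
  sm <- summarize_levels(norm)
  expect_equal(sm$mean[match(names(true_lv), sm$site)],
               unname(true_lv / mean(true_lv[c("ctrl1", "ctrl2")])),
               tolerance = 1e-9)
  expect_equal(sm$sd, rep(0, 4), tolerance = 1e-9)
})

test_that("noisy qPCR recovers relative levels within sampling error", {
  true_lv <- c(rex_a = 0.05, rex_b = 0.01, ctrl1 = 0.02, ctrl2 = 0.02)
  rel <- true_lv / mean(true_lv[c("ctrl1", "ctrl2")])
  set.seed(82)
  sim <- simulate_qpcr(true_lv, noise_cv = 0.1, n_replicates = 3)
  curve <- fit_standard_curve(sim$standards)
  lv <- sim$samples
  lv$level <- quantify_ct(lv$ct, curve)
  sm <- summarize_levels(normalize_to_controls(lv, c("ctrl1", "ctrl2")))
  for (s in names(true_lv)) {
    i <- sm$site == s
    band <- max(3 * sm$sd[i], 0.3 * rel[[s]])
    expect_lt(abs(sm$mean[i] - rel[[s]]), band + 1e-12)
  }
})
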