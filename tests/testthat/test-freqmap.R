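sites_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  class(df) <- c("pool_sites", "data.frame")
  df
}

test_that("site frequency is alternate over total reads per pool", {
  s <- sites_df(contig = "c", pos = 1:3,
                ref_mut = c(1L, 40L, 20L), alt_mut = c(35L, 0L, 20L),
                ref_wt = c(10L, 10L, 10L), alt_wt = c(30L, 0L, 0L))
  expect_equal(site_frequency(s, "mutant"), c(35 / 36, 0, 0.5),
               tolerance = 1e-12)
  expect_equal(round(site_frequency(s, "mutant")[1], 4), 0.9722)
  expect_equal(site_frequency(s, "wildtype"), c(0.75, 0, 0))
})

test_that("depth and shared-high-frequency filters follow the rules", {
  s <- sites_df(
    contig = "c", pos = 1:4,
    #       <30x mutant | high both | high mutant only | boundary 30x/80%
    ref_mut = c(9L, 15L, 1L, 6L),
    alt_mut = c(20L, 85L, 35L, 24L),
    ref_wt = c(20L, 8L, 42L, 6L),
    alt_wt = c(25L, 92L, 18L, 24L))
  out <- filter_sites(s)
  # site 1 fails the 30x rule, site 2 is >=80% in both pools,
  # site 3 is the causal-locus signature (high in one pool only),
  # site 4 sits exactly on both boundaries: depth 30 kept, 80% in both
  # pools removed (inclusive threshold)
  expect_identical(out$pos, 3L)
  fc <- attr(out, "filter_counts")
  expect_identical(unname(fc["removed_low_depth"]), 1L)
  expect_identical(unname(fc["removed_both_high"]), 2L)
})

test_that("binning averages per anchor bin and drops sparse bins", {
  anchors <- data.frame(contig = c("cA", "cB"), chromosome = "5H",
                        cm = c(96.6, 42.2), stringsAsFactors = FALSE)
  n1 <- 40
  n2 <- 29
  s <- sites_df(
    contig = c(rep("cA", n1), rep("cB", n2), "orphan"),
    pos = seq_len(n1 + n2 + 1),
    ref_mut = 4L, alt_mut = 36L, ref_wt = 30L, alt_wt = 10L)
  expect_message(bins <- bin_frequencies(s, anchors), "1 site")
  # the 29-site bin is dropped, the unanchored site excluded
  expect_identical(nrow(bins), 1L)
  expect_identical(bins$chromosome, "5H")
  expect_identical(bins$bin_start, 96)
  expect_identical(bins$n_snps, 40L)
  expect_equal(bins$mean_freq_mut, 0.9, tolerance = 1e-12)
  expect_equal(bins$score, 0.9 - 0.25, tolerance = 1e-12)
  expect_identical(attr(bins, "n_unanchored"), 1L)
  expect_identical(attr(bins, "n_bins_dropped"), 1L)
})

test_that("bin boundaries are half-open in centimorgan", {
  anchors <- data.frame(contig = c("a", "b"), chromosome = "1H",
                        cm = c(96.999, 97.0), stringsAsFactors = FALSE)
  s <- sites_df(contig = rep(c("a", "b"), each = 30), pos = 1:60,
                ref_mut = 10L, alt_mut = 30L, ref_wt = 30L, alt_wt = 10L)
  bins <- bin_frequencies(s, anchors)
  expect_identical(bins$bin_start, c(96, 97))
})

test_that("peak detection maximises the pool frequency difference", {
  bins <- structure(data.frame(
    chromosome = c("1H", "3H", "5H"), bin_start = c(5, 40, 97),
    n_snps = 31L, mean_freq_mut = c(0.55, 0.96, 0.60),
    mean_freq_wt = c(0.50, 0.32, 0.50),
    score = c(0.05, 0.64, 0.10), stringsAsFactors = FALSE),
    class = c("poolmap_freqmap", "data.frame"), bin_width = 1.0)
  pk <- detect_peak(bins)
  expect_identical(pk$chromosome, "3H")
  expect_identical(pk$bin_start, 40)
  expect_equal(pk$bin_mid, 40.5)
  expect_equal(pk$score, 0.64)

  # ties break by chromosome order then lower bin start
  bins$score <- 0.3
  bins$bin_start <- c(7, 5, 5)
  pk <- detect_peak(bins)
  expect_identical(pk$chromosome, "1H")
  expect_identical(pk$bin_start, 7)

  # a flat genome warns and an empty bin table errors
  bins$score <- c(0.01, 0.005, 0.0)
  expect_warning(detect_peak(bins), "no convincing")
  expect_error(detect_peak(bins[0, ]), "no bins")
})

test_that("bin means and the peak are invariant to site order", {
  sim <- simulate_dataset(seed = 21)
  sites <- filter_sites(sim$sites)
  bins <- suppressMessages(bin_frequencies(sites, sim$anchors))
  set.seed(1)
  perm <- sites[sample(nrow(sites)), ]
  bins_perm <- suppressMessages(bin_frequencies(perm, sim$anchors))
  expect_equal(bins_perm, bins, ignore_attr = TRUE)
  expect_identical(detect_peak(bins_perm)$bin_start,
                   detect_peak(bins)$bin_start)
})

test_that("swapping the pools negates every bin score", {
  sim <- simulate_dataset(seed = 22)
  swapped <- sim$sites
  names(swapped)[match(c("ref_mut", "alt_mut", "ref_wt", "alt_wt"),
                       names(swapped))] <-
    c("ref_wt", "alt_wt", "ref_mut", "alt_mut")
  b1 <- suppressMessages(bin_frequencies(filter_sites(sim$sites),
                                         sim$anchors))
  b2 <- suppressMessages(bin_frequencies(filter_sites(swapped),
                                         sim$anchors))
  expect_equal(b2$score, -b1$score, tolerance = 1e-12)
})
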