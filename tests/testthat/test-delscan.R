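track <- function(contig, pos, depth) {
  data.frame(contig = rep_len(contig, length(pos)),
             pos = as.integer(pos),
             depth = as.integer(rep_len(depth, length(pos))),
             stringsAsFactors = FALSE)
}

test_that("covered intervals are maximal wildtype runs clipped to targets", {
  targets <- data.frame(contig = "c1", start = 10L, end = 30L,
                        stringsAsFactors = FALSE)
  wt <- track("c1", c(14, 15, 16), c(5, 6, 7))
  mut <- track("c1", 15, 2)
  iv <- covered_intervals(mut, wt, targets)
  expect_identical(nrow(iv), 1L)
  expect_identical(iv$start, 14L)
  expect_identical(iv$end, 16L)
  expect_identical(iv$length, 3L)
  expect_equal(iv$mean_depth_wt, 6.0)
  expect_equal(iv$mean_depth_mut, 2 / 3, tolerance = 1e-12)

  # a run straddling the target edge is clipped before averaging
  wt <- track("c1", 5:12, rep(4, 8))
  iv <- covered_intervals(track("c1", integer(), integer()), wt, targets)
  expect_identical(iv$start, 10L)
  expect_identical(iv$end, 12L)
  expect_equal(iv$mean_depth_wt, 4.0)
  expect_equal(iv$mean_depth_mut, 0.0)
})

test_that("continuous coverage across two adjacent targets is split", {
  targets <- data.frame(contig = "c1", start = c(10L, 22L),
                        end = c(20L, 30L), stringsAsFactors = FALSE)
  wt <- track("c1", 5:35, rep(9, 31))
  iv <- covered_intervals(track("c1", integer(), integer()), wt, targets)
  expect_identical(nrow(iv), 2L)
  expect_identical(iv$start, c(10L, 22L))
  expect_identical(iv$end, c(20L, 30L))
  bf <- brute_force_scan(track("c1", integer(), integer()), wt, targets,
                         min_length = 1, wt_min = 0, mut_max = Inf,
                         ratio_min = 0)
  expect_equal(iv$start, bf$start)
  expect_equal(iv$end, bf$end)
})

test_that("deletion calls implement both conditions with precedence", {
  iv <- structure(data.frame(
    contig = paste0("c", 1:6),
    start = 1L, end = 1L,
    length = c(349L, 200L, 200L, 149L, 200L, 200L),
    mean_depth_mut = c(0.4, 0.0, 2.1, 0.0, 1.5, 0.5),
    mean_depth_wt = c(24.4, 7.0, 30.0, 30.0, 5.5, 4.9),
    stringsAsFactors = FALSE),
    class = c("coverage_intervals", "data.frame"))
  calls <- call_deletions(iv)
  # published worked row: 349 bp, 0.4x vs 24.4x -> condition 2
  expect_identical(calls$contig, c("c1", "c2"))
  expect_identical(calls$condition, c(2L, 1L))
  # c3 fails mut <= 2; c4 fails length; c5 fails the ratio
  # (5.5 < 4 x 1.5); c6 fails wildtype >= 5
  expect_false(any(c("c3", "c4", "c5", "c6") %in% calls$contig))
})

test_that("boundary values are inclusive where stated", {
  iv <- structure(data.frame(
    contig = c("len", "mut", "ratio"), start = 1L, end = 1L,
    length = c(150L, 200L, 200L),
    mean_depth_mut = c(0, 2.0, 1.25),
    mean_depth_wt = c(5.0, 8.0, 5.0), stringsAsFactors = FALSE),
    class = c("coverage_intervals", "data.frame"))
  calls <- call_deletions(iv)
  # 150 bp, mut exactly 2 and ratio exactly 4 all pass
  expect_identical(calls$contig, c("len", "mut", "ratio"))
  expect_identical(calls$condition, c(1L, 2L, 2L))
})

test_that("calls are monotone in mutant depth and minimum length", {
  set.seed(31)
  for (i in 1:20) {
    iv <- structure(data.frame(
      contig = "c", start = 1L, end = 1L,
      length = sample(100:400, 1),
      mean_depth_mut = stats::runif(1, 0, 3),
      mean_depth_wt = stats::runif(1, 0, 30),
      stringsAsFactors = FALSE),
      class = c("coverage_intervals", "data.frame"))
    base_called <- nrow(call_deletions(iv)) > 0
    iv_lower <- iv
    iv_lower$mean_depth_mut <- iv$mean_depth_mut / 2
    if (base_called) expect_gt(nrow(call_deletions(iv_lower)), 0)
    stricter <- nrow(call_deletions(iv, min_length = iv$length + 1))
    expect_identical(stricter, 0L)
  }
})

test_that("the scan matches the per-base brute-force oracle", {
  set.seed(33)
  for (i in 1:25) {
    d <- random_tracks(1500)
    mine <- call_deletions(covered_intervals(d$mut, d$wt, d$targets),
                           min_length = 20)
    oracle <- brute_force_scan(d$mut, d$wt, d$targets, min_length = 20)
    key <- function(x) x[order(x$contig, x$start), , drop = FALSE]
    a <- key(as.data.frame(mine))
    b <- key(oracle)
    expect_identical(nrow(a), nrow(b))
    expect_equal(a$start, b$start)
    expect_equal(a$end, b$end)
    expect_equal(a$mean_depth_mut, b$mean_depth_mut, tolerance = 1e-12)
    expect_equal(a$mean_depth_wt, b$mean_depth_wt, tolerance = 1e-12)
    expect_identical(a$condition, b$condition)
  }
})
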