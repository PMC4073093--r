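#' Contiguously covered intervals over capture targets
#'
#' Builds maximal runs of consecutive positions with wildtype-pool depth
#' greater than zero, clips them to the capture targets (any overlap of
#' at least 1 bp), and attaches per-pool mean depths computed over every
#' base of the clipped interval (positions absent from a track count as
#' depth zero). Runs are defined on the wildtype track so that a region
#' fully deleted in the mutant pool still yields an interval.
#'
#' @param depth_mut,depth_wt Per-sample depth tracks (`contig`, `pos`,
#'   `depth`), as returned by [read_depth_track()].
#' @param targets Capture targets (`contig`, `start`, `end`, 1-based
#'   inclusive), as returned by [read_targets_bed()].
#' @return Data frame of class `coverage_intervals`: `contig`, `start`,
#'   `end`, `length`, `mean_depth_mut`, `mean_depth_wt`.
#' @export
covered_intervals <- function(depth_mut, depth_wt, targets) {
  out <- list()
  wt_by_ctg <- split(depth_wt[c("pos", "depth")], depth_wt$contig)
  mut_by_ctg <- split(depth_mut[c("pos", "depth")], depth_mut$contig)
  for (ctg in unique(targets$contig)) {
    wt <- wt_by_ctg[[ctg]]
    if (is.null(wt)) next
    covered <- wt$pos[wt$depth > 0L]
    if (!length(covered)) next
    brk <- which(diff(covered) > 1L)
    run_start <- covered[c(1L, brk + 1L)]
    run_end <- covered[c(brk, length(covered))]
    tg <- targets[targets$contig == ctg, , drop = FALSE]
    mut <- mut_by_ctg[[ctg]]
    sum_in <- function(track, a, b) {
      if (is.null(track)) return(0)
      cs <- c(0, cumsum(as.numeric(track$depth)))
      lo <- findInterval(a - 1L, track$pos)
      hi <- findInterval(b, track$pos)
      cs[hi + 1L] - cs[lo + 1L]
    }
    for (i in seq_len(nrow(tg))) {
      os <- pmax(run_start, tg$start[i])
      oe <- pmin(run_end, tg$end[i])
      ok <- which(os <= oe)
      for (j in ok) {
        len <- oe[j] - os[j] + 1L
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, start = os[j], end = oe[j], length = len,
          mean_depth_mut = sum_in(mut, os[j], oe[j]) / len,
          mean_depth_wt = sum_in(wt, os[j], oe[j]) / len,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), start = integer(), end = integer(),
               length = integer(), mean_depth_mut = numeric(),
               mean_depth_wt = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("coverage_intervals", "data.frame")
  res
}

#' Two-condition deletion calls on covered intervals
#'
#' Flags intervals of at least `min_length` bp as putative homozygous
#' (condition 1) or contaminant-tolerant (condition 2) deletions:
#' \describe{
#'   \item{condition 1}{wildtype mean depth of at least `wt_min_c1` and
#'     no read coverage at all in the mutant pool;}
#'   \item{condition 2}{mutant mean depth at most `mut_max`, wildtype
#'     mean depth at least `wt_min_c2`, and wildtype at least
#'     `ratio_min` times the mutant depth. This tolerates the residual
#'     coverage left by a mis-phenotyped heterozygote in the mutant
#'     bulk.}
#' }
#' Condition 1 takes precedence; the ratio is wildtype over mutant so it
#' stays well defined at zero mutant depth.
#'
#' @param intervals A `coverage_intervals` data frame.
#' @param min_length Minimum interval length in bp (default 150,
#'   inclusive).
#' @param wt_min_c1,wt_min_c2 Minimum wildtype mean depth for each
#'   condition (default 5).
#' @param mut_max Maximum mutant mean depth under condition 2
#'   (default 2).
#' @param ratio_min Minimum wildtype/mutant depth ratio under
#'   condition 2 (default 4).
#' @return The calling subset of `intervals` with a `condition` column
#'   (1 or 2), class `deletion_calls`; attribute `scan_counts` records
#'   the filtering cascade.
#' @export
call_deletions <- function(intervals, min_length = 150, wt_min_c1 = 5,
                           wt_min_c2 = 5, mut_max = 2, ratio_min = 4) {
  long <- intervals$length >= min_length
  c1 <- long & intervals$mean_depth_wt >= wt_min_c1 &
    intervals$mean_depth_mut == 0
  c2 <- long & intervals$mean_depth_mut <= mut_max &
    intervals$mean_depth_wt >= wt_min_c2 &
    intervals$mean_depth_wt >= ratio_min * intervals$mean_depth_mut
  called <- c1 | c2
  out <- intervals[called, , drop = FALSE]
  out$condition <- if (nrow(out)) ifelse(c1[called], 1L, 2L) else
    integer(0)
  rownames(out) <- NULL
  attr(out, "scan_counts") <- c(
    intervals = nrow(intervals),
    length_pass = sum(long),
    called = nrow(out))
  class(out) <- c("deletion_calls", "data.frame")
  out
}

#' @export
print.deletion_calls <- function(x, ...) {
  cat(sprintf("Putative deletions: %d interval(s) (%d condition 1, %d condition 2)\n",
              nrow(x), sum(x$condition == 1L), sum(x$condition == 2L)))
  y <- as.data.frame(x)
  y$mean_depth_mut <- round(y$mean_depth_mut, 1)
  y$mean_depth_wt <- round(y$mean_depth_wt, 1)
  print(y, ...)
  invisible(x)
}
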