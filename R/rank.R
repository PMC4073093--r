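#' Place deletion calls on the genetic framework
#'
#' Partitions calls by anchor-table membership; anchored calls inherit
#' their contig's chromosome and centimorgan position.
#'
#' @param calls `deletion_calls` data frame.
#' @param anchors Anchor table (`contig`, `chromosome`, `cm`).
#' @return List with `anchored` (calls plus `chromosome`, `cm`) and
#'   `unanchored` (the rest).
#' @export
anchor_deletions <- function(calls, anchors) {
  idx <- match(calls$contig, anchors$contig)
  anchored <- calls[!is.na(idx), , drop = FALSE]
  anchored$chromosome <- anchors$chromosome[idx[!is.na(idx)]]
  anchored$cm <- anchors$cm[idx[!is.na(idx)]]
  unanchored <- calls[is.na(idx), , drop = FALSE]
  rownames(anchored) <- rownames(unanchored) <- NULL
  list(anchored = as.data.frame(anchored),
       unanchored = as.data.frame(unanchored))
}

#' Restrict anchored calls to a genetic target interval
#'
#' @param anchored Anchored calls ([anchor_deletions()]).
#' @param chromosome Chromosome name, e.g. `"5H"`.
#' @param cm_lo,cm_hi Interval bounds in centimorgan, closed on both
#'   ends.
#' @return The calls inside the interval.
#' @export
select_in_interval <- function(anchored, chromosome, cm_lo, cm_hi) {
  if (cm_lo > cm_hi) stop("'cm_lo' must be <= 'cm_hi'")
  keep <- anchored$chromosome == chromosome &
    anchored$cm >= cm_lo & anchored$cm <= cm_hi
  out <- anchored[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate genes under an allele-frequency peak
#'
#' Joins in-interval deletion calls to gene models (at least 1 bp of
#' overlap between call and gene span on the same contig), aggregates
#' one row per gene, and orders genes by genetic distance to the peak
#' (ascending), then longest deleted interval (descending), then
#' high-confidence first, then gene id. Calls overlapping no annotated
#' gene are reported separately in the `intergenic` attribute rather
#' than dropped.
#'
#' @param in_interval Anchored calls restricted to the target interval
#'   ([select_in_interval()]).
#' @param genes Gene table ([read_gene_table()]).
#' @param peak A `peak_call` (distance is measured to the peak-bin
#'   midpoint) or a single numeric focal position in centimorgan.
#' @return Data frame of class `candidate_ranking`, one row per
#'   candidate gene, ordered best first.
#' @export
rank_candidates <- function(in_interval, genes, peak) {
  peak_cm <- if (inherits(peak, "peak_call")) peak$bin_mid else
    as.numeric(peak)
  hit <- merge(in_interval, genes, by = "contig",
               suffixes = c("", "_gene"))
  hit <- hit[hit$start <= hit$end_gene & hit$end >= hit$start_gene, ,
             drop = FALSE]
  hit_keys <- if (nrow(hit)) paste(hit$contig, hit$start, hit$end) else
    character()
  all_keys <- paste(in_interval$contig, in_interval$start,
                    in_interval$end)
  intergenic <- in_interval[!all_keys %in% hit_keys, , drop = FALSE]
  rownames(intergenic) <- NULL
  if (nrow(hit) == 0L) {
    warning("no deletion call overlaps an annotated gene")
    out <- data.frame(gene_id = character(), contig = character(),
                      confidence = character(), annotation = character(),
                      cm = numeric(), n_deleted_intervals = integer(),
                      total_deleted_bp = integer(),
                      longest_interval_bp = integer(),
                      distance_to_peak = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    by_gene <- split(hit, hit$gene_id)
    out <- do.call(rbind, lapply(by_gene, function(g) {
      data.frame(gene_id = g$gene_id[1L], contig = g$contig[1L],
                 confidence = g$confidence[1L],
                 annotation = g$annotation[1L], cm = g$cm[1L],
                 n_deleted_intervals = nrow(g),
                 total_deleted_bp = sum(g$length),
                 longest_interval_bp = max(g$length),
                 distance_to_peak = abs(g$cm[1L] - peak_cm),
                 stringsAsFactors = FALSE)
    }))
  }
  ord <- order(out$distance_to_peak, -out$longest_interval_bp,
               out$confidence != "high", out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "intergenic") <- intergenic
  attr(out, "peak_cm") <- peak_cm
  class(out) <- c("candidate_ranking", "data.frame")
  out
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat(sprintf("Candidate genes near the %.1f cM peak (%d gene(s)):\n",
              attr(x, "peak_cm"), nrow(x)))
  print(as.data.frame(x), ...)
  ig <- attr(x, "intergenic")
  if (!is.null(ig) && nrow(ig))
    cat(nrow(ig), "in-interval deletion call(s) overlap no annotated gene\n")
  if (nrow(x)) {
    top <- x[1L, ]
    cat(sprintf(
      "Top candidate: %s (%s) on %s at %.1f cM, %.1f cM from the peak; %d deleted interval(s), longest %d bp\n",
      top$gene_id, top$annotation, top$contig, top$cm,
      top$distance_to_peak, top$n_deleted_intervals,
      top$longest_interval_bp))
  }
  invisible(x)
}
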