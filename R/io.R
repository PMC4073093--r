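ALL_COORDINATES_NOTE <- paste(
  "All internal coordinates are 1-based inclusive;",
  "BED input/output is converted at the boundary.")

#' Read a per-base depth track file
#'
#' Parses the tab-separated dialect produced by per-base coverage tools:
#' one row per covered position, columns `contig`, `position` (1-based)
#' and one depth column per sample. Positions absent from the file have
#' depth zero by convention.
#'
#' @param path Path to the depth file.
#' @param sample_count Number of depth columns expected after the
#'   contig and position columns. A file with fewer columns is an error,
#'   never a silent zero-fill.
#' @return A list of `sample_count` data frames, each with columns
#'   `contig`, `pos`, `depth`, positions strictly increasing within each
#'   contig.
#' @seealso [write_depth_track()]
#' @export
read_depth_track <- function(path, sample_count = 2) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  if (file.size(path) == 0 || length(readLines(path, n = 1L)) == 0L) {
    empty <- data.frame(contig = character(), pos = integer(),
                        depth = integer(), stringsAsFactors = FALSE)
    return(rep(list(empty), sample_count))
  }
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "integer",
                                     rep("integer", sample_count)),
                      comment.char = "", quote = ""),
    error = function(e) .locate_bad_depth_row(path, sample_count, e))
  if (ncol(tab) != sample_count + 2L)
    stop("depth file has ", ncol(tab), " columns; expected ",
         sample_count + 2L, " (contig, position, one depth per sample)")
  if (any(tab[[2L]] < 1L))
    stop("depth file contains positions < 1 (positions are 1-based)")
  depths <- tab[-(1:2)]
  if (any(vapply(depths, function(d) any(d < 0L), logical(1))))
    stop("negative depth values in ", path)
  # positions must be strictly increasing within each contig
  by_ctg <- split(tab[[2L]], factor(tab[[1L]], levels = unique(tab[[1L]])))
  bad <- vapply(by_ctg, function(p) any(diff(p) <= 0), logical(1))
  if (any(bad))
    stop("non-monotone positions within contig(s): ",
         paste(names(by_ctg)[bad], collapse = ", "))
  lapply(seq_len(sample_count), function(i) {
    data.frame(contig = tab[[1L]], pos = tab[[2L]], depth = tab[[i + 2L]],
               stringsAsFactors = FALSE)
  })
}

.locate_bad_depth_row <- function(path, sample_count, parent_err) {
  lines <- readLines(path)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf != sample_count + 2L)
  if (length(bad))
    stop("malformed depth row at line ", bad[1L], " of ", path,
         " (expected ", sample_count + 2L, " tab-separated fields)")
  stop("cannot parse depth file ", path, ": ",
       conditionMessage(parent_err))
}

#' Write paired depth tracks
#'
#' Inverse of [read_depth_track()]: the tracks must share an identical
#' `(contig, pos)` skeleton (the simulator guarantees this).
#'
#' @param tracks List of per-sample data frames (`contig`, `pos`,
#'   `depth`).
#' @param path Output path.
#' @export
write_depth_track <- function(tracks, path) {
  base <- tracks[[1L]][c("contig", "pos")]
  for (t in tracks[-1L])
    if (!identical(t$contig, base$contig) || !identical(t$pos, base$pos))
      stop("all tracks must share one (contig, pos) skeleton")
  out <- cbind(base, as.data.frame(lapply(tracks, `[[`, "depth")))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read pooled allelic depths from a two-sample VCF
#'
#' Extracts per-pool reference/alternate read depths (the per-sample
#' `AD` field) at biallelic SNPs for a mutant pool and a wildtype pool.
#' Multiallelic records and indels are skipped and counted. Total site
#' depth is `ref + alt`, not the site `DP`.
#'
#' @param path VCF file (plain or bgzipped).
#' @param mutant_sample,wildtype_sample Sample names of the two pools as
#'   they appear in the VCF header.
#' @return A data frame of class `pool_sites` with columns `contig`,
#'   `pos`, `ref_mut`, `alt_mut`, `ref_wt`, `alt_wt`; attribute
#'   `n_skipped` counts skipped non-biallelic/indel records.
#' @export
read_pool_vcf <- function(path, mutant_sample = "mutant",
                          wildtype_sample = "wildtype") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  missing <- setdiff(c(mutant_sample, wildtype_sample), samples)
  if (length(missing))
    stop("sample(s) not present in VCF: ", paste(missing, collapse = ", "),
         " (found: ", paste(samples, collapse = ", "), ")")
  n <- nrow(vcf@fix)
  if (n == 0L) return(.empty_pool_sites(0L))
  ref <- vcf@fix[, "REF"]
  alt <- vcf@fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message("read_pool_vcf: skipped ", n_skipped,
            " multiallelic/indel record(s)")
  if (!any(keep)) return(.empty_pool_sites(n_skipped))
  vcf <- vcf[keep, ]
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || all(is.na(ad)))
    stop("VCF lacks a per-sample AD (allelic depth) field")
  parse_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    cnt <- vapply(parts, function(p) as.integer(p[1:2]), integer(2))
    cnt[is.na(cnt)] <- 0L
    cnt
  }
  ad_mut <- parse_ad(ad[, mutant_sample])
  ad_wt <- parse_ad(ad[, wildtype_sample])
  out <- data.frame(contig = vcf@fix[, "CHROM"],
                    pos = as.integer(vcf@fix[, "POS"]),
                    ref_mut = ad_mut[1L, ], alt_mut = ad_mut[2L, ],
                    ref_wt = ad_wt[1L, ], alt_wt = ad_wt[2L, ],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("pool_sites", "data.frame")
  out
}

.empty_pool_sites <- function(n_skipped = 0L) {
  out <- data.frame(contig = character(), pos = integer(),
                    ref_mut = integer(), alt_mut = integer(),
                    ref_wt = integer(), alt_wt = integer(),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("pool_sites", "data.frame")
  out
}

#' Write pooled site counts as a minimal two-sample VCF
#'
#' Emits VCF 4.2 with a per-sample `AD` field so that
#' [read_pool_vcf()] round-trips exactly. Placeholder REF/ALT bases are
#' used when the counts carry no sequence context.
#'
#' @param sites `pool_sites` data frame.
#' @param path Output path.
#' @param mutant_sample,wildtype_sample Sample names for the header.
#' @export
write_pool_vcf <- function(sites, path, mutant_sample = "mutant",
                           wildtype_sample = "wildtype") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poolmap",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", mutant_sample, wildtype_sample, sep = "\t"))
  body <- if (nrow(sites)) {
    paste(sites$contig, sites$pos, ".", "A", "T", ".", "PASS", ".", "AD",
          paste0(sites$ref_mut, ",", sites$alt_mut),
          paste0(sites$ref_wt, ",", sites$alt_wt), sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read capture targets from a BED file
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive,
#' so a BED line `ctg 2106 2455` becomes `start = 2107, end = 2455`
#' (length 349).
#'
#' @param path BED file.
#' @return Data frame with columns `contig`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_targets_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write capture targets as BED
#'
#' @param targets Data frame with `contig`, `start`, `end` (1-based
#'   inclusive).
#' @param path Output path.
#' @export
write_targets_bed <- function(targets, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = targets$contig,
    ranges = IRanges::IRanges(start = targets$start, end = targets$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a contig anchoring table
#'
#' Three tab-separated columns without header: contig id, chromosome,
#' centimorgan position on the genetic framework. Contigs absent from
#' the table are treated as unanchored downstream.
#'
#' @param path Anchor TSV.
#' @return Data frame `contig`, `chromosome`, `cm`.
#' @export
read_anchor_table <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(contig = character(), chromosome = character(),
                      cm = numeric(), stringsAsFactors = FALSE))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("contig", "chromosome", "cm"),
                           colClasses = c("character", "character",
                                          "numeric"),
                           comment.char = "", quote = "")
  if (anyDuplicated(tab$contig))
    stop("duplicate contig id(s) in anchor table: ",
         paste(unique(tab$contig[duplicated(tab$contig)]), collapse = ", "))
  if (any(tab$cm < 0)) stop("negative centimorgan position in anchor table")
  tab
}

#' @rdname read_anchor_table
#' @param anchors Data frame `contig`, `chromosome`, `cm`.
#' @export
write_anchor_table <- function(anchors, path) {
  utils::write.table(anchors[c("contig", "chromosome", "cm")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write the gene annotation table
#'
#' Six tab-separated columns with header: `gene_id`, `contig`, `start`,
#' `end` (1-based inclusive), `confidence` (`high`/`low`), `annotation`
#' (free text).
#'
#' @param path Gene table TSV.
#' @return Data frame with the six columns above.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "integer", "integer",
                                          "character", "character"),
                           comment.char = "", quote = "")
  names(tab) <- c("gene_id", "contig", "start", "end", "confidence",
                  "annotation")
  if (!all(tab$confidence %in% c("high", "low")))
    stop("gene confidence class must be 'high' or 'low'")
  if (any(tab$start > tab$end)) stop("gene with start > end")
  tab
}

#' @rdname read_gene_table
#' @param genes Gene data frame.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(
    genes[c("gene_id", "contig", "start", "end", "confidence",
            "annotation")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
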