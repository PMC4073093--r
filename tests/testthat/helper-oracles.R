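# Independent oracles used by unit and property tests. These stay
# deliberately naive (per-chromosome, per-base loops) so they cannot
# share a defect with the vectorised implementation.

# expected pool allele frequency by explicit per-chromosome enumeration:
# every chromosome of the bulk contributes its own carriage probability
enum_bulk_freq <- function(r, n_hom_mutant, n_het, n_hom_wildtype) {
  probs <- c(rep(1 - r, 2 * n_hom_mutant),
             rep(c(1 - r, r), n_het),
             rep(r, 2 * n_hom_wildtype))
  mean(probs)
}

# Pearson goodness-of-fit, written out by hand
pearson_gof <- function(obs, expected_fracs) {
  e <- sum(obs) * expected_fracs
  sum((obs - e)^2 / e)
}

# per-base reference implementation of the coverage-interval scan and
# the two deletion conditions
brute_force_scan <- function(track_mut, track_wt, targets,
                             min_length = 150, wt_min = 5, mut_max = 2,
                             ratio_min = 4) {
  rows <- list()
  for (ctg in unique(targets$contig)) {
    tg <- targets[targets$contig == ctg, , drop = FALSE]
    maxp <- max(c(track_wt$pos[track_wt$contig == ctg], tg$end, 1L))
    wt <- integer(maxp)
    mt <- integer(maxp)
    sel <- track_wt$contig == ctg
    wt[track_wt$pos[sel]] <- track_wt$depth[sel]
    sel <- track_mut$contig == ctg
    mt[track_mut$pos[sel]] <- track_mut$depth[sel]
    runs <- list()
    in_run <- FALSE
    rs <- 0L
    for (p in seq_len(maxp)) {
      if (wt[p] > 0L && !in_run) { in_run <- TRUE; rs <- p }
      if (wt[p] == 0L && in_run) {
        in_run <- FALSE
        runs[[length(runs) + 1L]] <- c(rs, p - 1L)
      }
    }
    if (in_run) runs[[length(runs) + 1L]] <- c(rs, maxp)
    for (t in seq_len(nrow(tg))) for (rn in runs) {
      a <- max(rn[1L], tg$start[t])
      b <- min(rn[2L], tg$end[t])
      if (a <= b)
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, start = a, end = b, length = b - a + 1L,
          mean_depth_mut = mean(mt[a:b]), mean_depth_wt = mean(wt[a:b]),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), length = integer(),
                      mean_depth_mut = numeric(),
                      mean_depth_wt = numeric(), condition = integer(),
                      stringsAsFactors = FALSE))
  iv <- do.call(rbind, rows)
  cond <- integer(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    if (iv$length[i] < min_length) next
    if (iv$mean_depth_wt[i] >= wt_min && iv$mean_depth_mut[i] == 0)
      cond[i] <- 1L
    else if (iv$mean_depth_mut[i] <= mut_max &&
             iv$mean_depth_wt[i] >= wt_min &&
             iv$mean_depth_wt[i] >= ratio_min * iv$mean_depth_mut[i])
      cond[i] <- 2L
  }
  iv$condition <- cond
  iv[cond > 0L, , drop = FALSE]
}

# random sparse depth tracks plus targets on 1-3 short contigs
random_tracks <- function(total_bp = 3000) {
  n_ctg <- sample(1:3, 1)
  len <- floor(total_bp / n_ctg)
  mk <- function() {
    out <- list()
    for (k in seq_len(n_ctg)) {
      lambda <- stats::runif(1, 0.5, 8)
      d <- stats::rpois(len, lambda) *
        stats::rbinom(len, 1, stats::runif(1, 0.5, 0.95))
      pos <- which(d > 0L)
      out[[k]] <- data.frame(contig = paste0("c", k), pos = pos,
                             depth = d[pos], stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  tg <- do.call(rbind, lapply(seq_len(n_ctg), function(k) {
    n_t <- sample(1:4, 1)
    s <- sort(sample(len - 20L, n_t))
    e <- pmin(len, s + sample(10:600, n_t, replace = TRUE))
    # keep targets on one contig disjoint
    for (i in seq_len(n_t - 1L))
      if (i < n_t && e[i] >= s[i + 1L]) e[i] <- s[i + 1L] - 1L
    ok <- s <= e
    data.frame(contig = paste0("c", k), start = s[ok], end = e[ok],
               stringsAsFactors = FALSE)
  }))
  list(mut = mk(), wt = mk(), targets = tg)
}

# hand-built F2 population object for count/depth simulators
make_pop <- function(dosage, cm = NULL, contig = "ctg1",
                     chromosome = "chr1", causal_idx = 1L) {
  m <- ncol(dosage)
  if (is.null(cm)) cm <- seq_len(m)
  markers <- data.frame(chromosome = chromosome, cm = cm,
                        contig = contig,
                        pos = seq(100L, by = 100L, length.out = m),
                        stringsAsFactors = FALSE)
  structure(list(
    markers = markers,
    contigs = data.frame(contig = unique(contig),
                         chromosome = chromosome,
                         cm = cm[match(unique(contig), contig)],
                         stringsAsFactors = FALSE),
    dosage = dosage,
    phenotype = ifelse(dosage[, causal_idx] == 2L, "mutant", "wildtype"),
    causal_idx = causal_idx), class = "f2_population")
}

# bulk pair over explicit individual indices
make_bulks <- function(pop, mut_idx, wt_idx) {
  comp <- function(idx) {
    d <- pop$dosage[idx, pop$causal_idx]
    bulk_composition(sum(d == 2L), sum(d == 1L), sum(d == 0L))
  }
  structure(list(mutant = list(indices = mut_idx,
                               composition = comp(mut_idx)),
                 wildtype = list(indices = wt_idx,
                                 composition = comp(wt_idx))),
            class = "bulk_pair")
}

# the eight published deleted target intervals of the worked example:
# coordinates, per-pool coverages, genes and framework-map anchors
table1_intervals <- function() {
  data.frame(
    contig = c("contig_49382", "contig_49382", "contig_159829",
               "contig_159829", "contig_1558349", "contig_45126",
               "contig_2547452", "contig_58347"),
    start = c(2107L, 3871L, 785L, 4501L, 1236L, 14800L, 4712L, 7926L),
    end = c(2455L, 4101L, 996L, 4709L, 1477L, 14961L, 4913L, 8186L),
    mean_depth_mut = c(0.4, 1.1, 0.9, 0.4, 1.5, 0.8, 0.1, 1.0),
    mean_depth_wt = c(24.4, 8.8, 8.2, 12.4, 11.5, 7.3, 10.5, 14.5),
    stringsAsFactors = FALSE)
}

table1_genes <- function() {
  iv <- table1_intervals()
  ids <- c("MLOC_64838.2", "MLOC_64838.2", "MLOC_21734.1",
           "MLOC_21734.1", "MLOC_10070.1", "AK365660", "AK357178",
           "MLOC_70680.1")
  ann <- c("Cytochrome P450", "Cytochrome P450", "CC-NBS-LRR",
           "CC-NBS-LRR", "MATE efflux family",
           "Tumor susceptibility 101 protein",
           "3'-5' exoribonuclease CSL4", "DNA repair protein-like")
  # gene spans cover that gene's intervals on its contig
  agg <- do.call(rbind, lapply(split(seq_along(ids), ids), function(ii) {
    data.frame(gene_id = ids[ii[1]], contig = iv$contig[ii[1]],
               start = min(iv$start[ii]), end = max(iv$end[ii]),
               confidence = "high", annotation = ann[ii[1]],
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

table1_anchors <- function() {
  data.frame(
    contig = c("contig_49382", "contig_159829", "contig_1558349",
               "contig_45126", "contig_2547452", "contig_58347"),
    chromosome = "5H",
    cm = c(96.6, 99.9, 99.9, 107.1, 108.1, 109.4),
    stringsAsFactors = FALSE)
}

table1_calls <- function() {
  iv <- table1_intervals()
  iv$length <- iv$end - iv$start + 1L
  call_deletions(structure(iv, class = c("coverage_intervals",
                                         "data.frame")))
}
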