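#' Configuration of a simulated genetic map
#'
#' Describes the marker/contig scaffold the simulator places an F2
#' population on: chromosomes with lengths in centimorgan, a uniform
#' marker density, and a partition of each chromosome into equally
#' sized contigs anchored at their midpoint (emulating a fragmented
#' assembly anchored by a population-sequencing map). A fraction of
#' contigs is withheld from the anchor table to emulate unplaced
#' contigs.
#'
#' @param chromosomes Data frame with columns `name`, `length_cm`.
#' @param markers_per_cm Marker density (markers per centimorgan). The
#'   default (35) leaves 1-cM bins comfortably above the 30-SNP
#'   retention rule after site filtering.
#' @param contigs_per_chromosome Contigs each chromosome is split into.
#' @param unanchored_fraction Fraction of contigs absent from the
#'   anchor table, in `[0, 1)`.
#' @param contig_length_bp Nominal physical length of each contig.
#' @param marker_positions Optional named list mapping a chromosome
#'   name to an explicit vector of marker positions in centimorgan
#'   (overrides the uniform `markers_per_cm` spacing there; ties are
#'   allowed and give completely linked markers).
#' @return A list of class `genetic_map_config`.
#' @export
genetic_map_config <- function(chromosomes = data.frame(
                                 name = c("chr1", "chr2"),
                                 length_cm = c(150, 150),
                                 stringsAsFactors = FALSE),
                               markers_per_cm = 35,
                               contigs_per_chromosome = 300,
                               unanchored_fraction = 0.05,
                               contig_length_bp = 10000L,
                               marker_positions = NULL) {
  stopifnot(all(chromosomes$length_cm > 0), markers_per_cm > 0,
            contigs_per_chromosome >= 1,
            unanchored_fraction >= 0, unanchored_fraction < 1)
  structure(list(chromosomes = chromosomes,
                 markers_per_cm = markers_per_cm,
                 contigs_per_chromosome = contigs_per_chromosome,
                 unanchored_fraction = unanchored_fraction,
                 contig_length_bp = contig_length_bp,
                 marker_positions = marker_positions),
            class = "genetic_map_config")
}

#' Sequencing depth model for pooled reads
#'
#' Per-site (or per-base) depth is negative binomial with mean
#' `mean_depth` and size `dispersion`; `dispersion = Inf` collapses to
#' Poisson. Reads support the wrong allele with probability
#' `error_rate`.
#'
#' @param mean_depth Mean depth (reads).
#' @param dispersion Negative-binomial size parameter; `Inf` for
#'   Poisson.
#' @param error_rate Per-read allele error rate, in `[0, 0.01]`.
#' @return A list of class `depth_model`.
#' @export
depth_model <- function(mean_depth = 30, dispersion = 10,
                        error_rate = 0.002) {
  stopifnot(mean_depth > 0, dispersion > 0,
            error_rate >= 0, error_rate <= 0.01)
  structure(list(mean_depth = mean_depth, dispersion = dispersion,
                 error_rate = error_rate), class = "depth_model")
}

.draw_depth <- function(n, model, mean = model$mean_depth) {
  if (is.infinite(model$dispersion)) stats::rpois(n, mean)
  else stats::rnbinom(n, size = model$dispersion, mu = mean)
}

# Marker/contig scaffold: one row per marker with its contig assignment
# and physical position, plus the contig -> (chromosome, cM) table.
.build_map <- function(config, causal_chromosome, causal_cm) {
  chroms <- config$chromosomes
  if (!causal_chromosome %in% chroms$name)
    stop("causal chromosome '", causal_chromosome,
         "' is not on the configured map")
  len <- chroms$length_cm[match(causal_chromosome, chroms$name)]
  if (causal_cm < 0 || causal_cm > len)
    stop("causal position ", causal_cm, " cM lies off chromosome ",
         causal_chromosome, " (length ", len, " cM)")
  marker_list <- list()
  contig_list <- list()
  for (k in seq_len(nrow(chroms))) {
    L <- chroms$length_cm[k]
    cm <- config$marker_positions[[chroms$name[k]]]
    if (is.null(cm)) {
      m <- max(1L, round(L * config$markers_per_cm))
      cm <- (seq_len(m) - 0.5) / config$markers_per_cm
      cm <- cm[cm <= L]
    } else {
      if (any(cm < 0 | cm > L))
        stop("explicit marker positions off chromosome ", chroms$name[k])
      cm <- sort(cm)
    }
    C <- config$contigs_per_chromosome
    span <- L / C
    ctg_idx <- pmin(C, floor(cm / span) + 1L)
    ctg_id <- sprintf("ctg_%s_%04d", chroms$name[k], ctg_idx)
    pos <- unlist(lapply(split(seq_along(cm), ctg_idx), function(ii) {
      round(seq(1, config$contig_length_bp - 1000,
                length.out = length(ii) + 2))[-c(1, length(ii) + 2)]
    }), use.names = FALSE)
    ord <- order(ctg_idx, cm) # already ordered; keep explicit
    marker_list[[k]] <- data.frame(
      chromosome = chroms$name[k], cm = cm[ord], contig = ctg_id[ord],
      pos = as.integer(pos), stringsAsFactors = FALSE)
    contig_list[[k]] <- data.frame(
      contig = sprintf("ctg_%s_%04d", chroms$name[k], seq_len(C)),
      chromosome = chroms$name[k],
      cm = (seq_len(C) - 0.5) * span, stringsAsFactors = FALSE)
  }
  markers <- do.call(rbind, marker_list)
  # snap the causal locus to the nearest configured marker
  on_chr <- which(markers$chromosome == causal_chromosome)
  causal_idx <- on_chr[which.min(abs(markers$cm[on_chr] - causal_cm))]
  list(markers = markers, contigs = do.call(rbind, contig_list),
       causal_idx = causal_idx)
}

#' Simulate an F2 population from a mutant x wildtype cross
#'
#' Each individual is the union of two gametes drawn independently from
#' a heterozygous F1. Gametes are generated marker to marker along each
#' chromosome with recombination probabilities from Haldane's map
#' function applied to inter-marker distances (Poisson crossovers, no
#' interference). Phenotype is recessive on the causal-locus dosage.
#'
#' @param config A [genetic_map_config()].
#' @param n_individuals Population size.
#' @param causal Causal locus as `list(chromosome =, cm =)`; snapped to
#'   the nearest configured marker.
#' @param seed Optional integer seed.
#' @return A list of class `f2_population`: `markers` (map with the
#'   causal row flagged), `contigs` (full contig table), `dosage`
#'   (individuals x markers mutant-allele dosage matrix), `phenotype`
#'   (`"mutant"`/`"wildtype"`), `causal_idx`.
#' @export
simulate_f2 <- function(config, n_individuals,
                        causal = list(chromosome = "chr1", cm = 97),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- .build_map(config, causal$chromosome, causal$cm)
  markers <- map$markers
  n_gam <- 2L * n_individuals
  gam <- matrix(0L, nrow = n_gam, ncol = nrow(markers))
  for (ch in unique(markers$chromosome)) {
    cols <- which(markers$chromosome == ch)
    m <- length(cols)
    first <- stats::rbinom(n_gam, 1L, 0.5)
    if (m == 1L) {
      gam[, cols] <- first
      next
    }
    r <- map_cm_to_r(diff(markers$cm[cols]), "haldane")
    sw <- matrix(stats::rbinom(n_gam * (m - 1L), 1L,
                               rep(r, each = n_gam)), nrow = n_gam)
    cs <- apply(sw, 1L, cumsum) # (m-1) x n_gam, or a vector when m = 2
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
    cum <- cbind(0L, t(cs))
    gam[, cols] <- (first + cum) %% 2L
  }
  odd <- seq(1L, n_gam, by = 2L)
  dosage <- gam[odd, , drop = FALSE] + gam[odd + 1L, , drop = FALSE]
  phenotype <- ifelse(dosage[, map$causal_idx] == 2L, "mutant",
                      "wildtype")
  structure(list(markers = markers, contigs = map$contigs,
                 dosage = dosage, phenotype = phenotype,
                 causal_idx = map$causal_idx),
            class = "f2_population")
}

#' @export
print.f2_population <- function(x, ...) {
  cat(sprintf(
    "F2 population: %d individuals, %d markers on %d chromosome(s); %d phenotypic mutant(s)\n",
    nrow(x$dosage), ncol(x$dosage), length(unique(x$markers$chromosome)),
    sum(x$phenotype == "mutant")))
  cat(sprintf("  causal locus: %s at %.3f cM (marker %d on %s)\n",
              x$markers$chromosome[x$causal_idx],
              x$markers$cm[x$causal_idx], x$causal_idx,
              x$markers$contig[x$causal_idx]))
  invisible(x)
}

#' Compose the sequenced phenotypic bulks
#'
#' The mutant bulk holds `mutant_bulk_size - n_misphenotyped_het`
#' phenotypic mutants plus `n_misphenotyped_het` heterozygotes scored as
#' mutant by mistake; the wildtype bulk is drawn uniformly without
#' replacement from the remaining phenotypic wildtypes.
#'
#' @param pop An `f2_population`.
#' @param mutant_bulk_size,wildtype_bulk_size Bulk sizes (defaults 18
#'   and 30).
#' @param n_misphenotyped_het Heterozygotes mis-scored into the mutant
#'   bulk (default 1).
#' @param seed Optional integer seed.
#' @return List of class `bulk_pair`: `mutant` and `wildtype`, each
#'   with member `indices` and the causal-locus [bulk_composition()].
#' @export
compose_bulks <- function(pop, mutant_bulk_size = 18,
                          wildtype_bulk_size = 30,
                          n_misphenotyped_het = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  causal_dosage <- pop$dosage[, pop$causal_idx]
  mutants <- which(pop$phenotype == "mutant")
  hets <- which(causal_dosage == 1L)
  n_true <- mutant_bulk_size - n_misphenotyped_het
  if (length(mutants) < n_true)
    stop("insufficient phenotypic mutants: need ", n_true, ", have ",
         length(mutants))
  if (length(hets) < n_misphenotyped_het)
    stop("insufficient heterozygotes: need ", n_misphenotyped_het,
         ", have ", length(hets))
  mut_idx <- c(sample(mutants, n_true),
               if (n_misphenotyped_het > 0)
                 sample(hets, n_misphenotyped_het))
  wt_pool <- setdiff(which(pop$phenotype == "wildtype"), mut_idx)
  if (length(wt_pool) < wildtype_bulk_size)
    stop("insufficient phenotypic wildtypes: need ", wildtype_bulk_size,
         ", have ", length(wt_pool))
  wt_idx <- sample(wt_pool, wildtype_bulk_size)
  comp <- function(idx) {
    d <- causal_dosage[idx]
    bulk_composition(sum(d == 2L), sum(d == 1L), sum(d == 0L))
  }
  structure(list(
    mutant = list(indices = mut_idx, composition = comp(mut_idx)),
    wildtype = list(indices = wt_idx, composition = comp(wt_idx))),
    class = "bulk_pair")
}

#' Simulate pooled allelic read counts at every marker
#'
#' Per marker and pool, the true mutant-allele frequency is the dosage
#' fraction over the bulk's chromosomes; site depth is drawn from the
#' depth model and the alternate-read count is binomial with success
#' probability `f (1 - e) + (1 - f) e`.
#'
#' @param pop An `f2_population`.
#' @param bulks A `bulk_pair` ([compose_bulks()]).
#' @param model A [depth_model()].
#' @param seed Optional integer seed.
#' @return A `pool_sites` data frame (one row per marker with depth in
#'   at least one pool).
#' @export
simulate_pool_counts <- function(pop, bulks, model = depth_model(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_mk <- ncol(pop$dosage)
  e <- model$error_rate
  one_pool <- function(idx) {
    f <- colSums(pop$dosage[idx, , drop = FALSE]) / (2 * length(idx))
    depth <- .draw_depth(n_mk, model)
    alt <- stats::rbinom(n_mk, depth, f * (1 - e) + (1 - f) * e)
    cbind(ref = depth - alt, alt = alt)
  }
  mut <- one_pool(bulks$mutant$indices)
  wt <- one_pool(bulks$wildtype$indices)
  out <- data.frame(contig = pop$markers$contig, pos = pop$markers$pos,
                    ref_mut = mut[, "ref"], alt_mut = mut[, "alt"],
                    ref_wt = wt[, "ref"], alt_wt = wt[, "alt"],
                    stringsAsFactors = FALSE)
  keep <- (out$ref_mut + out$alt_mut + out$ref_wt + out$alt_wt) > 0L
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pool_sites", "data.frame")
  out
}

#' Simulate paired per-base depth tracks over capture targets
#'
#' Off-target depth is zero. Expected depth at a base is the model mean
#' times a per-target multiplicative lognormal capture-efficiency
#' factor (shared between pools, sd `target_sigma` on the log scale)
#' and, within the deleted exons, the fraction of non-deleted
#' chromosomes in the bulk. A mutant bulk of 17 homozygous-deletion
#' plants and 1 heterozygote keeps 1/36 of its chromosomes intact, so
#' at a 30x model mean the deleted exons retain about 0.83x residual
#' coverage.
#'
#' @param pop An `f2_population`.
#' @param bulks A `bulk_pair`.
#' @param targets Capture targets (`contig`, `start`, `end`).
#' @param deletion `NULL`, or `list(contig =, exons = data.frame(start,
#'   end))`; deletion zygosity per plant is its causal-locus dosage
#'   (the causal mutation is the deletion).
#' @param model A [depth_model()].
#' @param target_sigma Log-scale sd of the per-target capture factor
#'   (default 0.5; factors have mean 1).
#' @param seed Optional integer seed.
#' @return List of two depth tracks (`mutant`, `wildtype`), each
#'   `contig`/`pos`/`depth`, rows with zero depth in both pools
#'   omitted.
#' @export
simulate_depth_tracks <- function(pop, bulks, targets, deletion = NULL,
                                  model = depth_model(),
                                  target_sigma = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(deletion)) {
    ok <- vapply(seq_len(nrow(deletion$exons)), function(i) {
      any(targets$contig == deletion$contig &
            targets$start <= deletion$exons$start[i] &
            targets$end >= deletion$exons$end[i])
    }, logical(1))
    if (!all(ok))
      stop("deletion exon(s) outside all capture targets: ",
           paste(which(!ok), collapse = ", "))
  }
  intact <- function(bulk) {
    d <- pop$dosage[bulk$indices, pop$causal_idx]
    1 - sum(d) / (2 * length(d))
  }
  frac <- c(mutant = if (is.null(deletion)) 1 else intact(bulks$mutant),
            wildtype = if (is.null(deletion)) 1 else
              intact(bulks$wildtype))
  n_t <- nrow(targets)
  factor_t <- stats::rlnorm(n_t, meanlog = -target_sigma^2 / 2,
                            sdlog = target_sigma)
  pos_list <- lapply(seq_len(n_t), function(i)
    seq.int(targets$start[i], targets$end[i]))
  lens <- lengths(pos_list)
  contig <- rep(targets$contig, lens)
  pos <- unlist(pos_list, use.names = FALSE)
  base_mean <- rep(factor_t, lens) * model$mean_depth
  deleted <- if (is.null(deletion)) rep(FALSE, length(pos)) else
    contig == deletion$contig &
      Reduce(`|`, lapply(seq_len(nrow(deletion$exons)), function(i)
        pos >= deletion$exons$start[i] & pos <= deletion$exons$end[i]))
  draw <- function(which_pool) {
    mean_b <- base_mean * ifelse(deleted, frac[[which_pool]], 1)
    .draw_depth(length(pos), model, mean = mean_b)
  }
  d_mut <- draw("mutant")
  d_wt <- draw("wildtype")
  ord <- order(contig, pos)
  keep <- (d_mut + d_wt > 0L)[ord]
  list(mutant = data.frame(contig = contig[ord], pos = pos[ord],
                           depth = d_mut[ord],
                           stringsAsFactors = FALSE)[keep, ],
       wildtype = data.frame(contig = contig[ord], pos = pos[ord],
                             depth = d_wt[ord],
                             stringsAsFactors = FALSE)[keep, ])
}

#' The default simulated mapping-by-sequencing scenario
#'
#' One hundred F2 plants from a homozygous-mutant x wildtype cross on a
#' two-chromosome, 150-cM-each map at 35 markers/cM; the causal locus
#' (simultaneously a SNP marker and a two-exon homozygous deletion)
#' sits at 97 cM on chromosome 1. Bulks of 18 (including one
#' mis-phenotyped heterozygote) and 30 plants; SNP-site depth
#' NB(mean 60, size 20) so marker sites clear the 30x site filter;
#' per-base exome depth NB(mean 30, size 10), the scale of typical
#' capture coverage at targets.
#'
#' @return A list of scenario parameters accepted by
#'   [simulate_dataset()].
#' @export
default_scenario <- function() {
  list(config = genetic_map_config(),
       n_individuals = 100L,
       causal = list(chromosome = "chr1", cm = 97),
       mutant_bulk_size = 18L, wildtype_bulk_size = 30L,
       n_misphenotyped_het = 1L,
       snp_depth = depth_model(mean_depth = 60, dispersion = 20,
                               error_rate = 0.002),
       track_depth = depth_model(mean_depth = 30, dispersion = 10,
                                 error_rate = 0.002),
       gene_fraction = 0.25, high_conf_fraction = 0.8,
       target_sigma = 0.5)
}

#' Simulate a complete mapping-by-sequencing dataset
#'
#' Runs the whole generative chain — F2 genotypes, phenotypic bulks,
#' pooled allelic counts, capture targets, gene models, the causal
#' deletion, per-base depth tracks and the (partially incomplete)
#' anchor table — and optionally writes every pipeline input format
#' plus a ground-truth JSON. If a drawn population cannot fill the
#' bulks (too few phenotypic mutants), the population is redrawn, as an
#' experiment would only proceed with a population that can be bulked.
#'
#' @param scenario Parameter list, see [default_scenario()].
#' @param seed Integer seed governing every random draw.
#' @param dir Optional output directory; created if missing. Files:
#'   `pools.vcf`, `depth.tsv`, `targets.bed`, `anchors.tsv`,
#'   `genes.tsv`, `truth.json`.
#' @param max_tries Population redraws allowed (default 25).
#' @return Invisibly, a list of class `poolmap_sim` holding all
#'   simulated objects and `truth`.
#' @export
simulate_dataset <- function(scenario = default_scenario(), seed = 1,
                             dir = NULL, max_tries = 25) {
  set.seed(seed)
  pop <- NULL
  bulks <- NULL
  for (i in seq_len(max_tries)) {
    cand <- simulate_f2(scenario$config, scenario$n_individuals,
                        scenario$causal)
    b <- tryCatch(
      compose_bulks(cand, scenario$mutant_bulk_size,
                    scenario$wildtype_bulk_size,
                    scenario$n_misphenotyped_het),
      error = function(e) NULL)
    if (!is.null(b)) {
      pop <- cand
      bulks <- b
      break
    }
  }
  if (is.null(pop))
    stop("could not draw a population filling the bulks in ",
         max_tries, " tries")
  causal_contig <- pop$markers$contig[pop$causal_idx]
  genes_targets <- .build_annotation(pop, scenario, causal_contig)
  genes <- genes_targets$genes
  targets <- genes_targets$targets
  deletion <- list(contig = causal_contig,
                   exons = genes_targets$causal_exons)
  sites <- simulate_pool_counts(pop, bulks, scenario$snp_depth)
  tracks <- simulate_depth_tracks(pop, bulks, targets, deletion,
                                  scenario$track_depth,
                                  scenario$target_sigma)
  anchors <- .thin_anchors(pop$contigs,
                           scenario$config$unanchored_fraction)
  truth <- list(
    causal_chromosome = scenario$causal$chromosome,
    causal_cm = pop$markers$cm[pop$causal_idx],
    causal_contig = causal_contig,
    causal_gene = genes_targets$causal_gene,
    deletion_exons = genes_targets$causal_exons,
    mutant_bulk = unclass(bulks$mutant$composition),
    wildtype_bulk = unclass(bulks$wildtype$composition),
    seed = seed)
  out <- structure(list(pop = pop, bulks = bulks, sites = sites,
                        tracks = tracks, targets = targets,
                        genes = genes, anchors = anchors,
                        deletion = deletion, truth = truth),
                   class = "poolmap_sim")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_pool_vcf(sites, file.path(dir, "pools.vcf"))
    write_depth_track(list(tracks$mutant, tracks$wildtype),
                      file.path(dir, "depth.tsv"))
    write_targets_bed(targets, file.path(dir, "targets.bed"))
    write_anchor_table(anchors, file.path(dir, "anchors.tsv"))
    write_gene_table(genes, file.path(dir, "genes.tsv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

# Gene models and capture targets on the contig scaffold. The causal
# contig always carries one high-confidence two-exon gene whose exons
# are the deleted (and captured) intervals; a seeded fraction of other
# contigs carries one decoy gene each, and a few gene-less targets are
# sprinkled in.
.build_annotation <- function(pop, scenario, causal_contig) {
  contigs <- pop$contigs$contig
  exon1 <- c(2001L, 2400L)
  exon2 <- c(3601L, 3900L)
  vocab <- c("protein kinase", "NB-LRR disease resistance",
             "MATE efflux family", "zinc finger", "F-box protein",
             "glycosyl transferase", "unknown function")
  others <- setdiff(contigs, causal_contig)
  with_gene <- sample(others, round(scenario$gene_fraction *
                                      length(others)))
  conf <- ifelse(stats::runif(length(with_gene)) <
                   scenario$high_conf_fraction, "high", "low")
  ann <- sample(vocab, length(with_gene), replace = TRUE)
  causal_gene <- "gene_causal_P450"
  genes <- rbind(
    data.frame(gene_id = causal_gene, contig = causal_contig,
               start = exon1[1L], end = exon2[2L], confidence = "high",
               annotation = "cytochrome P450", stringsAsFactors = FALSE),
    data.frame(gene_id = paste0("gene_", with_gene),
               contig = with_gene, start = exon1[1L], end = exon2[2L],
               confidence = conf, annotation = ann,
               stringsAsFactors = FALSE))
  gene_targets <- data.frame(
    contig = rep(genes$contig, each = 2L),
    start = rep(c(exon1[1L], exon2[1L]), nrow(genes)),
    end = rep(c(exon1[2L], exon2[2L]), nrow(genes)),
    stringsAsFactors = FALSE)
  bare <- sample(setdiff(others, with_gene),
                 round(0.05 * length(others)))
  bare_targets <- data.frame(contig = bare, start = 5001L, end = 5400L,
                             stringsAsFactors = FALSE)
  targets <- rbind(gene_targets, bare_targets)
  targets <- targets[order(targets$contig, targets$start), ]
  rownames(targets) <- NULL
  list(genes = genes, targets = targets,
       causal_exons = data.frame(start = c(exon1[1L], exon2[1L]),
                                 end = c(exon1[2L], exon2[2L])),
       causal_gene = causal_gene)
}

.thin_anchors <- function(contigs, unanchored_fraction) {
  if (unanchored_fraction <= 0) return(contigs)
  drop <- sample(nrow(contigs),
                 floor(unanchored_fraction * nrow(contigs)))
  out <- contigs[-drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.poolmap_sim <- function(x, ...) {
  cat("Simulated mapping-by-sequencing dataset\n")
  print(x$pop)
  cat(sprintf("  %d pooled SNP sites, %d capture targets, %d genes, %d anchored contigs\n",
              nrow(x$sites), nrow(x$targets), nrow(x$genes),
              nrow(x$anchors)))
  cat(sprintf("  causal gene %s on %s; deletion exons %s\n",
              x$truth$causal_gene, x$truth$causal_contig,
              paste(sprintf("%d-%d", x$deletion$exons$start,
                            x$deletion$exons$end), collapse = ", ")))
  invisible(x)
}
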