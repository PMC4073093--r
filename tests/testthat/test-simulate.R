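tiny_config <- function(...) {
  genetic_map_config(
    chromosomes = data.frame(name = "chr1", length_cm = 10,
                             stringsAsFactors = FALSE),
    markers_per_cm = 1, contigs_per_chromosome = 2,
    unanchored_fraction = 0, ...)
}

test_that("F2 dosage at the causal locus is Mendelian 1:2:1", {
  pop <- simulate_f2(tiny_config(), 10000,
                     causal = list(chromosome = "chr1", cm = 5),
                     seed = 11)
  d <- pop$dosage[, pop$causal_idx]
  n <- length(d)
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(d == 0) - 0.25), 3 * se(0.25))
  expect_lt(abs(mean(d == 1) - 0.50), 3 * se(0.50))
  expect_lt(abs(mean(d == 2) - 0.25), 3 * se(0.25))
  expect_identical(sum(pop$phenotype == "mutant"), sum(d == 2L))
})

test_that("completely linked markers have identical dosage columns", {
  cfg <- tiny_config(marker_positions = list(chr1 = c(5, 5)))
  pop <- simulate_f2(cfg, 500, causal = list(chromosome = "chr1", cm = 5),
                     seed = 2)
  expect_identical(pop$dosage[, 1], pop$dosage[, 2])
})

test_that("gamete recombination fractions follow Haldane's map function", {
  cfg <- tiny_config(marker_positions = list(chr1 = c(0, 10)))
  pop <- simulate_f2(cfg, 40000,
                     causal = list(chromosome = "chr1", cm = 0), seed = 5)
  # condition on dosage 0 at the first locus: both of that plant's
  # gametes carry the non-mutant allele there, so each second-locus
  # allele marks a recombinant gamete independently with probability r
  r_true <- map_cm_to_r(10)
  d1 <- pop$dosage[, 1]
  d2 <- pop$dosage[, 2]
  n_gam <- 2 * sum(d1 == 0)
  expect_gte(n_gam, 10000)
  r_hat <- sum(d2[d1 == 0]) / n_gam
  se <- sqrt(r_true * (1 - r_true) / n_gam)
  expect_lt(abs(r_hat - r_true), 3 * se)
})

test_that("bulk composition follows the mis-phenotyping contract", {
  sc <- default_scenario()
  set.seed(1)
  pop <- simulate_f2(sc$config, 100, sc$causal)
  bulks <- compose_bulks(pop, 18, 30, 1)
  comp <- bulks$mutant$composition
  expect_identical(comp$n_hom_mutant, 17L)
  expect_identical(comp$n_het, 1L)
  expect_identical(comp$n_hom_wildtype, 0L)
  expect_length(bulks$wildtype$indices, 30)
  expect_identical(bulks$wildtype$composition$n_hom_mutant, 0L)
  # no double membership
  expect_length(intersect(bulks$mutant$indices,
                          bulks$wildtype$indices), 0)

  clean <- compose_bulks(pop, 18, 30, 0)
  expect_identical(clean$mutant$composition$n_het, 0L)
  expect_identical(clean$mutant$composition$n_hom_mutant, 18L)

  expect_error(compose_bulks(pop, 95, 2, 0), "insufficient")
})

test_that("the wildtype bulk is close to the 2:1 het:hom expectation", {
  sc <- default_scenario()
  pop <- simulate_f2(sc$config, 2000, sc$causal, seed = 9)
  bulks <- compose_bulks(pop, 18, 600, 1)
  comp <- bulks$wildtype$composition
  p_het <- comp$n_het / (comp$n_het + comp$n_hom_wildtype)
  expect_lt(abs(p_het - 2 / 3), 3 * sqrt(2 / 9 / 600))
})

test_that("pooled counts follow the binomial read-sampling model", {
  # degenerate: fixed bulk frequency 1, no error -> all reads alternate
  pop <- make_pop(matrix(2L, nrow = 4, ncol = 50))
  bulks <- make_bulks(pop, 1:2, 3:4)
  sites <- simulate_pool_counts(pop, bulks,
                                depth_model(40, Inf, 0), seed = 1)
  expect_true(all(sites$ref_mut == 0L))
  expect_true(all(sites$alt_mut > 0L))

  # the 35/36 mutant bulk converges on the 97.2% expectation
  dos <- matrix(2L, nrow = 18, ncol = 2000)
  dos[18, ] <- 1L
  pop <- make_pop(dos)
  bulks <- make_bulks(pop, 1:18, 1:18)
  sites <- simulate_pool_counts(pop, bulks, depth_model(30, Inf, 0),
                                seed = 3)
  f <- mean(site_frequency(sites, "mutant"))
  se <- sqrt((35 / 36) * (1 / 36) / 30 / nrow(sites))
  expect_lt(abs(f - 35 / 36), 3 * se)

  # error floor: a dosage-0 bulk still shows ~error_rate alt reads
  pop <- make_pop(matrix(0L, nrow = 4, ncol = 5000))
  bulks <- make_bulks(pop, 1:2, 3:4)
  sites <- simulate_pool_counts(pop, bulks, depth_model(30, Inf, 0.002),
                                seed = 4)
  rate <- sum(sites$alt_mut) / sum(sites$alt_mut + sites$ref_mut)
  expect_lt(abs(rate - 0.002), 3 * sqrt(0.002 / sum(sites$alt_mut +
                                                      sites$ref_mut)))
})

test_that("depth tracks scale with the non-deleted chromosome fraction", {
  dos <- matrix(2L, nrow = 18, ncol = 1)
  dos[18, 1] <- 1L
  pop <- make_pop(dos)
  bulks <- make_bulks(pop, 1:18, 1:18)
  targets <- data.frame(contig = "ctg1", start = 1L, end = 4000L,
                        stringsAsFactors = FALSE)
  deletion <- list(contig = "ctg1",
                   exons = data.frame(start = 1L, end = 4000L))
  tr <- simulate_depth_tracks(pop, bulks, targets, deletion,
                              depth_model(30, 10, 0), target_sigma = 0,
                              seed = 6)
  mu <- 30 / 36
  m <- sum(tr$mutant$depth) / 4000
  expect_lt(abs(m - mu), 3 * sqrt((mu + mu^2 / 10) / 4000))

  # all-hom-deleted bulk: exactly zero mutant depth
  dos[18, 1] <- 2L
  pop <- make_pop(dos)
  bulks <- make_bulks(pop, 1:18, 1:18)
  tr <- simulate_depth_tracks(pop, bulks, targets, deletion,
                              depth_model(30, 10, 0), target_sigma = 0,
                              seed = 6)
  expect_identical(sum(tr$mutant$depth), 0)

  # a bulk carrying no deletion sees the full model mean
  dos0 <- matrix(0L, nrow = 18, ncol = 1)
  pop0 <- make_pop(dos0)
  bulks0 <- make_bulks(pop0, 1:9, 10:18)
  tr0 <- simulate_depth_tracks(pop0, bulks0, targets, deletion,
                               depth_model(30, 10, 0), target_sigma = 0,
                               seed = 7)
  m0 <- sum(tr0$wildtype$depth) / 4000
  expect_lt(abs(m0 - 30), 3 * sqrt((30 + 90) / 4000))

  # a deletion outside every capture target is a configuration error
  bad <- list(contig = "ctg1", exons = data.frame(start = 9000L,
                                                  end = 9100L))
  expect_error(simulate_depth_tracks(pop, bulks, targets, bad,
                                     depth_model(30, 10, 0)),
               "outside all capture targets")
})

test_that("off-map causal positions are configuration errors", {
  expect_error(simulate_f2(tiny_config(), 10,
                           causal = list(chromosome = "chr9", cm = 5)),
               "not on the configured map")
  expect_error(simulate_f2(tiny_config(), 10,
                           causal = list(chromosome = "chr1", cm = 99)),
               "off chromosome")
})

test_that("simulated datasets are seed-deterministic", {
  a <- simulate_dataset(seed = 12)
  b <- simulate_dataset(seed = 12)
  c <- simulate_dataset(seed = 13)
  expect_identical(a$pop$dosage, b$pop$dosage)
  expect_identical(a$sites, b$sites)
  expect_identical(a$tracks, b$tracks)
  expect_false(identical(a$pop$dosage, c$pop$dosage))
})
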