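test_that("AIM discovery applies the all-zea / at-most-one-armigera rule", {
  # 7 zea + 3 armigera genomes, 3 candidate sites
  zea_ids <- sprintf("z%d", 1:7)
  arm_ids <- sprintf("a%d", 1:3)
  geno <- rbind(
    c(rep(2, 7), 0, 0, 0),   # alt in all zea, 0 armigera -> AIM
    c(rep(2, 7), 1, 1, 0),   # alt in all zea, 2 armigera -> rejected
    c(rep(2, 6), 0, 0, 0, 0) # one zea is 0/0 -> rejected
  )
  tab <- make_table(geno, samples = c(zea_ids, arm_ids))
  aims <- discover_aims(tab, zea_ids, arm_ids)
  expect_equal(aims$site, 1)
  expect_equal(aims$n_zea_carriers, 7)
  expect_equal(aims$n_armigera_carriers, 0)

  # one armigera carrier is tolerated by default, not two
  geno2 <- rbind(c(rep(2, 7), 1, 0, 0))
  aims2 <- discover_aims(make_table(geno2, samples = c(zea_ids, arm_ids)),
                         zea_ids, arm_ids)
  expect_equal(aims2$n_armigera_carriers, 1)
  strict <- discover_aims(make_table(geno2, samples = c(zea_ids, arm_ids)),
                          zea_ids, arm_ids, max_armigera_carriers = 0)
  expect_equal(nrow(strict), 0)

  # a missing genotype in a zea reference genome disqualifies the site
  geno3 <- rbind(c(rep(2, 6), NA, 0, 0, 0))
  expect_equal(nrow(discover_aims(make_table(geno3,
                                             samples = c(zea_ids, arm_ids)),
                                  zea_ids, arm_ids)), 0)

  # empty site table and empty panels
  empty <- make_table(matrix(integer(0), 0, 10),
                      samples = c(zea_ids, arm_ids))
  expect_equal(nrow(discover_aims(empty, zea_ids, arm_ids)), 0)
  expect_error(discover_aims(tab, character(0), arm_ids), "zea")
})

test_that("noiseless AIM discovery matches an enumeration oracle over the truth", {
  sim <- simulate_dataset(sim_config(
    n_sites = 2000, n_chromosomes = 4, fst = 0.3,
    n_pure_armigera = 12, n_pure_zea = 7, hybrid_spec = hybrid_panel(),
    mean_depth = 30, fixed_diff_frac = 0.1, seed = 81
  ))
  tab <- truth_table(sim)   # true genotypes exposed as calls
  zea <- sim$panel$sample_id[sim$panel$class == "pure_zea"]
  arm <- sim$panel$sample_id[sim$panel$class == "pure_armigera"]
  aims <- discover_aims(tab, zea, arm)

  # oracle: site-by-site loop over the truth genotypes
  gt <- sim$truth$genotype_true
  zc <- match(zea, sim$panel$sample_id)
  ac <- match(arm, sim$panel$sample_id)
  oracle <- integer(0)
  for (j in seq_len(nrow(gt))) {
    if (all(gt[j, zc] >= 1) && sum(gt[j, ac] >= 1) <= 1)
      oracle <- c(oracle, j)
  }
  expect_identical(aims$site, oracle)
  # every forced fixed difference is recovered
  expect_true(all(sim$truth$fixed_diff_sites %in% aims$site))
})

test_that("AIM ancestry proportions follow the dosage and presence codings", {
  zea_ids <- sprintf("z%d", 1:7)
  samples <- c(zea_ids, "a1", "query")
  J <- 50
  geno <- cbind(matrix(2L, J, 7), matrix(0L, J, 1), matrix(2L, J, 1))
  tab <- make_table(geno, samples = samples)
  aims <- discover_aims(tab, zea_ids, "a1")
  expect_equal(nrow(aims), J)

  # pure zea: 100% under both codings; pure armigera: 0%
  expect_equal(aim_ancestry_proportion(tab, "query", aims,
                                       "dosage")$percent, 100)
  expect_equal(aim_ancestry_proportion(tab, "query", aims,
                                       "presence")$percent, 100)
  expect_equal(aim_ancestry_proportion(tab, "a1", aims, "dosage")$percent, 0)

  # ideal F1 (dosage 1 everywhere): 50% dosage-coded, 100% presence-coded
  tab$geno[, "query"] <- 1L
  expect_equal(aim_ancestry_proportion(tab, "query", aims,
                                       "dosage")$percent, 50)
  expect_equal(aim_ancestry_proportion(tab, "query", aims,
                                       "presence")$percent, 100)

  # pure zea with 20% of AIMs force-called 0/0 by zero coverage
  tab$geno[, "query"] <- 2L
  hit <- seq_len(0.2 * J)
  tab$geno[hit, "query"] <- 0L
  tab$depth[hit, "query"] <- 0L
  expect_equal(aim_ancestry_proportion(tab, "query", aims,
                                       "dosage")$percent, 80)
  masked <- aim_ancestry_proportion(tab, "query", aims, "dosage",
                                    mask_below_dp = 5)
  expect_equal(masked$percent, 100)
  expect_equal(masked$n_scored, 40L)

  # masking everything is reported as missing, with a warning
  tab$depth[, "query"] <- 0L
  expect_warning(
    all_masked <- aim_ancestry_proportion(tab, "query", aims, "dosage",
                                          mask_below_dp = 5),
    "masked")
  expect_true(is.na(all_masked$percent))
})

test_that("depth diagnostics count zero- and low-coverage AIM positions", {
  zea_ids <- sprintf("z%d", 1:3)
  samples <- c(zea_ids, "a1", "q")
  geno <- cbind(matrix(2L, 5, 3), matrix(0L, 5, 1), matrix(2L, 5, 1))
  depth <- matrix(10L, 5, 5, dimnames = list(NULL, samples))
  tab <- make_table(geno, depth = depth, samples = samples)
  aims <- discover_aims(tab, zea_ids, "a1")

  d <- depth_diagnostics(tab, "q", aims)
  expect_equal(d$n_dp0, 0)
  expect_equal(d$n_below_threshold, 0)

  tab$depth[, "q"] <- c(0L, 0L, 3L, 7L, 9L)
  d <- depth_diagnostics(tab, "q", aims, dp_threshold = 5)
  expect_equal(d$n_dp0, 2)
  expect_equal(d$n_below_threshold, 3)
  expect_equal(d$flagged$pos, tab$sites$pos[1:3])
  # invariant: n_dp0 <= n_below_threshold <= number of AIMs
  expect_lte(d$n_dp0, d$n_below_threshold)
  expect_lte(d$n_below_threshold, nrow(aims))
})

test_that("zero-coverage AIM counts follow the Poisson zero class at low depth", {
  sim <- simulate_dataset(sim_config(
    n_sites = 3000, n_chromosomes = 3, fst = 0.3,
    n_pure_armigera = 8, n_pure_zea = 7, hybrid_spec = hybrid_panel(),
    mean_depth = 2, fixed_diff_frac = 0.3, seed = 82
  ))
  # score depth on an AIM set defined from the truth (calls at depth 2 are
  # too corrupted for discovery itself, which is not under test here)
  fd <- sim$truth$fixed_diff_sites
  aims <- structure(
    data.frame(site = fd, chrom = sim$table$sites$chrom[fd],
               pos = sim$table$sites$pos[fd],
               diagnostic_allele = sim$table$sites$alt[fd],
               n_zea_carriers = 7L, n_armigera_carriers = 0L),
    class = c("aim_set", "data.frame"))
  d <- depth_diagnostics(sim$table, sim$panel$sample_id[1], aims)
  expect_lt(abs(d$n_dp0 / nrow(aims) - exp(-2)), 0.03)
})

test_that("masking recovers dosage-coded ancestry corrupted by reference bias", {
  sim <- small_sim(seed = 83, n_sites = 1000, f1 = 0, mean_depth = 30,
                   fixed_diff_frac = 0.1)
  tab <- truth_table(sim)
  zea <- sim$panel$sample_id[sim$panel$class == "pure_zea"]
  arm <- sim$panel$sample_id[sim$panel$class == "pure_armigera"]
  aims <- discover_aims(tab, zea, arm)
  q <- zea[1]
  # corrupt only by zero-depth reference calls
  hit <- aims$site[seq_len(floor(0.25 * nrow(aims)))]
  tab$geno[hit, q] <- 0L
  tab$depth[hit, q] <- 0L
  plain <- aim_ancestry_proportion(tab, q, aims, "dosage")$percent
  masked <- aim_ancestry_proportion(tab, q, aims, "dosage",
                                    mask_below_dp = 5)$percent
  expect_gte(masked, plain)
})
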