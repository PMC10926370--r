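test_that("admixture log-likelihood matches closed forms and a brute-force oracle", {
  # K = 1, f = 0.5 everywhere: every allele contributes log(0.5)
  J <- 7
  G <- matrix(c(0, 1, 2, 1, 0, 2, 1), 1, J)
  Q1 <- matrix(1, 1, 1)
  F1 <- matrix(0.5, 1, J)
  expect_equal(admixture_loglik(G, Q1, F1), 2 * J * log(0.5))

  # q = (1, 0) degenerates to the K = 1 likelihood under F's first row
  f <- c(0.2, 0.7, 0.4, 0.9, 0.1, 0.5, 0.3)
  F2 <- rbind(f, runif(J))
  expect_equal(admixture_loglik(G, matrix(c(1, 0), 1, 2), F2),
               admixture_loglik(G, Q1, matrix(f, 1, J)))

  # small instance against the independent triple-loop oracle
  set.seed(71)
  G3 <- matrix(sample(c(0:2, NA), 6, replace = TRUE), 2, 3)
  Q3 <- matrix(c(0.3, 0.8, 0.7, 0.2), 2, 2)
  F3 <- matrix(runif(6, 0.1, 0.9), 2, 3)
  expect_equal(admixture_loglik(G3, Q3, F3), brute_loglik(G3, Q3, F3),
               tolerance = 1e-10)
  expect_error(admixture_loglik(G3, Q3, F3[, 1:2]), "dimension")
})

test_that("the EM step is monotone in likelihood and preserves the simplex", {
  set.seed(72)
  for (rep in 1:100) {
    N <- sample(2:6, 1); J <- sample(3:12, 1)
    G <- matrix(sample(c(0:2, NA), N * J, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), N, J)
    G[rowSums(!is.na(G)) == 0, 1] <- 1L
    Q <- matrix(rgamma(N * 2, 1), N, 2); Q <- Q / rowSums(Q)
    F <- matrix(runif(2 * J, 0.05, 0.95), 2, J)
    st <- em_step(G, Q, F)
    expect_gte(admixture_loglik(G, st$Q, st$F) + 1e-9,
               admixture_loglik(G, Q, F))
    expect_equal(rowSums(st$Q), rep(1, N), tolerance = 1e-9)
    expect_true(all(st$F > 0 & st$F < 1))
  }
})

test_that("EM is stationary at an exact solution and under pop symmetry", {
  # pure individuals with F at the empirical frequencies: a fixed point
  set.seed(73)
  J <- 40
  f1 <- runif(J, 0.2, 0.8); f2 <- runif(J, 0.2, 0.8)
  G <- rbind(rbinom(J, 2, f1), rbinom(J, 2, f1),
             rbinom(J, 2, f2), rbinom(J, 2, f2))
  emp1 <- colMeans(G[1:2, ]) / 2
  emp2 <- colMeans(G[3:4, ]) / 2
  eps <- 1e-6
  F <- rbind(pmin(pmax(emp1, eps), 1 - eps), pmin(pmax(emp2, eps), 1 - eps))
  Q <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  st <- em_step(G, Q, F)
  expect_lt(max(abs(st$Q - Q)), 1e-8)

  # indistinguishable populations leave q untouched
  Fsym <- rbind(f1, f1)
  Qsym <- matrix(0.5, 1, 2)
  st <- em_step(matrix(rbinom(J, 2, f1), 1, J), Qsym, Fsym)
  expect_equal(st$Q, Qsym, tolerance = 1e-12)
})

test_that("unsupervised K=2 fitting recovers simulated ancestry", {
  sim <- simulate_dataset(sim_config(
    n_sites = 500, n_chromosomes = 2, fst = 0.3,
    n_pure_armigera = 20, n_pure_zea = 20,
    hybrid_spec = hybrid_panel(f1 = 1), mean_depth = 60,
    fixed_diff_frac = 0.05, seed = 74
  ))
  est <- fit_admixture(sim$table, K = 2, seed = 75,
                       labels = sim$panel$species_label)
  expect_true(all(diff(est$loglik_trace) > -1e-8))
  expect_equal(unname(rowSums(est$Q)), rep(1, 41), tolerance = 1e-9)
  expect_identical(colnames(est$Q), c("armigera", "zea"))

  pure <- sim$panel$class != "F1"
  expect_lt(max(abs(est$Q[pure, "armigera"] - sim$panel$q_armigera[pure])),
            0.02)
  expect_lt(abs(est$Q[!pure, "armigera"] - 0.5), 0.05)

  # supervised projection against the pure panels agrees with the
  # unsupervised fit when pure genomes dominate the sample
  arm <- sim$panel$sample_id[sim$panel$class == "pure_armigera"]
  zea <- sim$panel$sample_id[sim$panel$class == "pure_zea"]
  F_ref <- reference_frequencies(sim$table, arm, zea)
  Qs <- fit_supervised(sim$table, F_ref)
  expect_lt(max(abs(Qs[, "armigera"] - est$Q[, "armigera"])), 0.02)

  # seeded determinism, to the last bit
  est2 <- fit_admixture(sim$table, K = 2, seed = 75,
                        labels = sim$panel$species_label)
  expect_identical(est$Q, est2$Q)

  # swapping the species labels everywhere swaps the Q columns exactly
  swapped <- ifelse(sim$panel$species_label == "armigera", "zea", "armigera")
  est3 <- fit_admixture(sim$table, K = 2, seed = 75, labels = swapped)
  expect_identical(unname(est$Q), unname(est3$Q[, c("zea", "armigera")]))

  expect_warning(fit_admixture(sim$table, K = 2, seed = 75), "labels")
})

test_that("supervised projection maximizes the fixed-frequency likelihood", {
  eps <- 1e-6
  # diagnostic sites, heterozygous everywhere: analytic maximum at 0.5
  J <- 30
  F_ref <- rbind(armigera = rep(eps, J), zea = rep(1 - eps, J))
  q <- fit_supervised(matrix(1L, 1, J), F_ref)
  expect_equal(unname(q[1, ]), c(0.5, 0.5), tolerance = 1e-6)

  # a pure-zea-like query hits the boundary
  sim <- small_sim(seed = 76, n_sites = 400, f1 = 0)
  tab <- sim$table
  arm <- sim$panel$sample_id[sim$panel$class == "pure_armigera"]
  zea <- sim$panel$sample_id[sim$panel$class == "pure_zea"]
  F_ref <- reference_frequencies(tab, arm, zea)
  qz <- fit_supervised(t(tab$geno[, zea[1], drop = FALSE]), F_ref)
  expect_gte(qz[1, "zea"], 0.99)

  # EM solution matches the grid-search oracle on random small instances
  set.seed(77)
  for (rep in 1:20) {
    J <- 20
    fa <- runif(J, 0.05, 0.95); fz <- runif(J, 0.05, 0.95)
    qtrue <- runif(1)
    g <- rbinom(J, 2, qtrue * fa + (1 - qtrue) * fz)
    Fr <- rbind(armigera = fa, zea = fz)
    qem <- fit_supervised(matrix(g, 1, J), Fr)[1, "armigera"]
    qgrid <- grid_supervised_q(g, fa, fz)
    expect_lt(abs(qem - qgrid), 1e-3)
  }

  # an individual with no called genotypes is reported missing
  G <- rbind(a = rep(NA_integer_, J), b = rep(1L, J))
  expect_warning(qm <- fit_supervised(G, Fr), "no called genotypes")
  expect_true(all(is.na(qm["a", ])))
  expect_false(anyNA(qm["b", ]))
})

test_that("purity classification separates pure genomes from hybrids", {
  Q <- rbind(c(1, 0), c(0.5, 0.5), c(0.995, 0.005), c(0.005, 0.995))
  colnames(Q) <- c("armigera", "zea")
  rownames(Q) <- c("a", "b", "c", "d")
  cls <- classify_purity(Q, threshold = 0.99)
  expect_identical(cls$pure_armigera, c("a", "c"))
  expect_identical(cls$pure_zea, "d")
  expect_identical(cls$hybrid, "b")
})

test_that("zero-coverage reference calls inflate armigera ancestry monotonically", {
  sim <- small_sim(seed = 78, n_sites = 600, f1 = 0)
  tab <- sim$table
  arm <- sim$panel$sample_id[sim$panel$class == "pure_armigera"]
  zea <- sim$panel$sample_id[sim$panel$class == "pure_zea"]
  F_ref <- reference_frequencies(tab, arm, zea)
  diag_sites <- which(abs(F_ref["armigera", ] - F_ref["zea", ]) > 0.8)
  g <- tab$geno[, zea[1]]
  qs <- vapply(c(0, 0.2, 0.4, 0.6), function(m) {
    gm <- g
    hit <- diag_sites[seq_len(floor(m * length(diag_sites)))]
    gm[hit] <- 0L   # DP = 0 at these sites: caller emits reference calls
    fit_supervised(matrix(gm, 1), F_ref)[1, "armigera"]
  }, 0)
  expect_true(all(diff(qs) > 0))
})
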