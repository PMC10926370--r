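# Shared fixtures and independent oracles for the test suite.

# Build a variant_table directly from matrices (sites x samples).
make_table <- function(geno, depth = NULL, qual = NULL, chrom = NULL,
                       pos = NULL, samples = NULL) {
  geno <- as.matrix(geno)
  J <- nrow(geno); N <- ncol(geno)
  if (is.null(depth)) depth <- matrix(30L, J, N)
  if (is.null(qual)) qual <- rep(60, J)
  if (is.null(chrom)) chrom <- rep("chr2", J)
  if (is.null(pos)) pos <- seq_len(J) * 100L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(N))
  storage.mode(geno) <- "integer"
  depth <- as.matrix(depth); storage.mode(depth) <- "integer"
  variant_table(
    data.frame(chrom = chrom, pos = pos,
               ref = rep("A", J), alt = rep("T", J), qual = qual),
    geno, depth, samples
  )
}

# Hudson-type FST from the two pure panels' genotypes: ratio of averages
# with the finite-sample correction on each panel's allele frequency.
hudson_fst <- function(g_pop1, g_pop2) {
  n1 <- 2 * ncol(g_pop1); n2 <- 2 * ncol(g_pop2)
  p1 <- rowMeans(g_pop1) / 2
  p2 <- rowMeans(g_pop2) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Brute-force admixture log-likelihood: triple loop, no shared code with
# the vectorized implementation.
brute_loglik <- function(G, Q, F) {
  ll <- 0
  for (i in seq_len(nrow(G))) for (j in seq_len(ncol(G))) {
    g <- G[i, j]
    if (is.na(g)) next
    p <- 0
    for (k in seq_len(ncol(Q))) p <- p + Q[i, k] * F[k, j]
    ll <- ll + g * log(p) + (2 - g) * log(1 - p)
  }
  ll
}

# Grid-search oracle for the supervised K=2 projection: maximize the
# per-individual likelihood over q_armigera on a regular grid.
grid_supervised_q <- function(g, f_arm, f_zea, step = 1e-4) {
  qs <- seq(0, 1, by = step)
  ok <- !is.na(g)
  g <- g[ok]; f_arm <- f_arm[ok]; f_zea <- f_zea[ok]
  ll <- vapply(qs, function(q) {
    p <- q * f_arm + (1 - q) * f_zea
    sum(g * log(p) + (2 - g) * log(1 - p))
  }, 0)
  qs[which.max(ll)]
}

# Small fully simulated dataset reused across tests.
small_sim <- function(seed = 11, n_sites = 800, f1 = 2,
                      n_arm = 12, n_zea = 12, mean_depth = 30, fst = 0.3,
                      fixed_diff_frac = 0.05) {
  simulate_dataset(sim_config(
    n_sites = n_sites, n_chromosomes = 4, fst = fst,
    n_pure_armigera = n_arm, n_pure_zea = n_zea,
    hybrid_spec = hybrid_panel(f1 = f1),
    mean_depth = mean_depth, fixed_diff_frac = fixed_diff_frac,
    low_qual_frac = 0.05, seed = seed
  ))
}

# A noiseless table: true genotypes exposed as calls at uniform depth.
truth_table <- function(sim, depth = 30L) {
  make_table(sim$truth$genotype_true,
             depth = matrix(depth, nrow(sim$truth$genotype_true),
                            ncol(sim$truth$genotype_true)),
             chrom = sim$table$sites$chrom, pos = sim$table$sites$pos,
             samples = sim$panel$sample_id)
}
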