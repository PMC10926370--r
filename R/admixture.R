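#' Log-likelihood of the binomial admixture model
#'
#' For individual i with ancestry fractions q_i (row of Q on the simplex)
#' and population alt-allele frequencies F (K x J, clipped away from 0 and
#' 1), each allele copy at site j is alt with probability
#' p_ij = sum_k q_ik f_kj. The log-likelihood over called genotypes is
#' sum over (i, j) of g_ij log p_ij + (2 - g_ij) log(1 - p_ij); missing
#' genotypes contribute nothing. (The binomial coefficient is constant in
#' the parameters and omitted.)
#'
#' @param G dosage matrix, individuals x sites, entries 0/1/2 or NA.
#' @param Q ancestry matrix, individuals x K, rows on the simplex.
#' @param F allele-frequency matrix, K x sites, entries in (0, 1).
#' @return scalar log-likelihood.
#' @export
admixture_loglik <- function(G, Q, F) {
  check_qf(G, Q, F)
  P <- Q %*% F
  sum(G * log(P) + (2 - G) * log1p(-P), na.rm = TRUE)
}

check_qf <- function(G, Q, F) {
  if (nrow(Q) != nrow(G) || ncol(F) != ncol(G) || ncol(Q) != nrow(F))
    stop("dimension mismatch between G, Q and F")
  invisible(TRUE)
}

#' One EM step for the admixture model
#'
#' Standard EM updates of the binomial admixture likelihood: the expected
#' number of alt (and ref) allele copies attributed to population k is
#' computed per individual and site, giving
#' q'_ik = (1 / 2J_i) sum_j (a_ijk + b_ijk) and
#' f'_kj = sum_i a_ijk / sum_i (a_ijk + b_ijk), with
#' a_ijk = g_ij q_ik f_kj / p_ij and b_ijk = (2 - g_ij) q_ik (1 - f_kj) /
#' (1 - p_ij), and J_i the number of called sites of individual i.
#' The step never decreases the log-likelihood (EM ascent); F is clipped
#' to [eps, 1 - eps] afterwards.
#'
#' @inheritParams admixture_loglik
#' @param update_f if `FALSE`, F is held fixed (supervised projection).
#' @param eps clipping bound for F.
#' @return list with updated `Q` and `F`.
#' @export
em_step <- function(G, Q, F, update_f = TRUE, eps = 1e-6) {
  check_qf(G, Q, F)
  K <- ncol(Q)
  called <- !is.na(G)
  G0 <- ifelse(called, G, 0)
  G2 <- ifelse(called, 2 - G, 0)
  P <- Q %*% F
  R1 <- G0 / P
  R0 <- G2 / (1 - P)
  Ji <- rowSums(called)
  Qn <- matrix(0, nrow(Q), K, dimnames = dimnames(Q))
  Fn <- F
  for (k in seq_len(K)) {
    Ak <- R1 * (Q[, k] %o% F[k, ])
    Bk <- R0 * (Q[, k] %o% (1 - F[k, ]))
    Qn[, k] <- rowSums(Ak + Bk) / (2 * Ji)
    if (update_f) {
      a <- colSums(Ak); d <- a + colSums(Bk)
      Fn[k, ] <- ifelse(d > 0, a / d, F[k, ])
    }
  }
  Qn <- Qn / rowSums(Qn)
  if (update_f) Fn <- pmin(pmax(Fn, eps), 1 - eps)
  list(Q = Qn, F = Fn)
}

#' Unsupervised K-population ancestry estimation (EM)
#'
#' Maximum-likelihood fit of the admixture model by EM from a seeded
#' random start: Q is initialized from a symmetric Dirichlet, F from the
#' empirical alt-allele frequencies perturbed per population. Iterates
#' until the log-likelihood improves by less than `tol` or `max_iter` is
#' reached. If putative species labels are supplied, the fitted F rows are
#' matched to species by correlation with the empirical frequencies of the
#' labeled samples, resolving the label-switching ambiguity; otherwise the
#' columns are named `pop1`/`pop2` (with a warning) in a deterministic
#' order (descending first-sample q).
#'
#' @param x a [variant_table()] or a dosage matrix (individuals x sites).
#' @param K number of ancestral populations (2 for a two-species
#'   hybridization scan).
#' @param seed integer seed for the random initialization (required for
#'   reproducible fits).
#' @param tol convergence tolerance on the log-likelihood increment.
#' @param max_iter iteration cap.
#' @param labels optional character vector of putative species labels
#'   (`"armigera"`/`"zea"`/`NA`), one per individual, used only to anchor
#'   column names.
#' @param eps clipping bound for F.
#' @return object of class `ancestry_estimate`: list with `Q` (individuals
#'   x K, rows summing to 1, columns named by species), `F`,
#'   `loglik_trace` (non-decreasing), `n_iter`, `converged`, `labels`
#'   (column names) and `samples`.
#' @export
fit_admixture <- function(x, K = 2, seed = 1L, tol = 1e-6, max_iter = 2000,
                          labels = NULL, eps = 1e-6) {
  G <- as_dosage_matrix(x)
  N <- nrow(G); J <- ncol(G)
  if (N < K) stop("need at least K individuals")
  if (any(rowSums(!is.na(G)) == 0))
    stop("every individual needs at least one called genotype")
  init <- with_seed(seed, {
    Q <- matrix(stats::rgamma(N * K, 1), N, K)
    Q <- Q / rowSums(Q)
    pbar <- colMeans(G, na.rm = TRUE) / 2
    F <- matrix(rep(pbar, each = K), K, J) +
      matrix(stats::runif(K * J, -0.1, 0.1), K, J)
    list(Q = Q, F = pmin(pmax(F, eps), 1 - eps))
  })
  Q <- init$Q; F <- init$F
  rownames(Q) <- rownames(G)
  trace <- admixture_loglik(G, Q, F)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    st <- em_step(G, Q, F, eps = eps)
    Q <- st$Q; F <- st$F
    ll <- admixture_loglik(G, Q, F)
    delta <- ll - trace[length(trace)]
    trace <- c(trace, ll)
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  est <- structure(
    list(Q = Q, F = F, loglik_trace = trace, n_iter = iter,
         converged = converged, labels = paste0("pop", seq_len(K)),
         samples = rownames(G)),
    class = "ancestry_estimate"
  )
  align_ancestry_labels(est, G, labels)
}

as_dosage_matrix <- function(x) {
  if (inherits(x, "variant_table")) {
    G <- t(x$geno)
    rownames(G) <- x$samples
    G
  } else if (is.matrix(x)) x
  else stop("x must be a variant_table or a dosage matrix")
}

# Resolve label switching: match each F row to the species whose labeled
# samples' empirical frequencies it correlates with best.
align_ancestry_labels <- function(est, G, labels) {
  K <- ncol(est$Q)
  if (is.null(labels) || all(is.na(labels)) || K != 2) {
    if (K == 2)
      warning("no species labels supplied; columns named pop1/pop2")
    ord <- order(est$Q[1, ], decreasing = TRUE)
    est$Q <- est$Q[, ord, drop = FALSE]
    est$F <- est$F[ord, , drop = FALSE]
    est$labels <- paste0("pop", seq_len(K))
  } else {
    stopifnot(length(labels) == nrow(G))
    species <- c("armigera", "zea")
    anchor <- vapply(species, function(s) {
      ids <- which(labels %in% s)
      if (!length(ids)) return(rep(NA_real_, ncol(G)))
      colMeans(G[ids, , drop = FALSE], na.rm = TRUE) / 2
    }, numeric(ncol(G)))
    use <- species[colSums(!is.na(anchor)) > 0]
    if (!length(use)) {
      warning("no usable anchor samples; columns named pop1/pop2")
      est$labels <- paste0("pop", 1:2)
    } else {
      ref <- anchor[, use[1]]
      r <- vapply(1:2, function(k)
        suppressWarnings(stats::cor(est$F[k, ], ref,
                                    use = "complete.obs")), 0)
      first <- which.max(r)
      ord <- c(first, setdiff(1:2, first))
      lab <- c(use[1], setdiff(species, use[1]))
      est$Q <- est$Q[, ord, drop = FALSE]
      est$F <- est$F[ord, , drop = FALSE]
      est$labels <- lab
    }
  }
  colnames(est$Q) <- est$labels
  rownames(est$F) <- est$labels
  est
}

#' @export
print.ancestry_estimate <- function(x, ...) {
  cat(sprintf(
    "<ancestry_estimate> %d individuals, K=%d (%s); %d EM iterations, %s\n",
    nrow(x$Q), ncol(x$Q), paste(x$labels, collapse = "/"),
    x$n_iter, if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Empirical reference allele frequencies from classified pure panels
#'
#' Builds the fixed K=2 frequency matrix used by supervised projection:
#' per-site empirical alt frequencies among the unhybridized armigera and
#' zea genomes, clipped to [eps, 1 - eps]. Sites with no called genotype
#' in a panel get the uninformative value 0.5.
#'
#' @param table a [variant_table()].
#' @param armigera_ids,zea_ids sample ids of the pure reference panels.
#' @param eps clipping bound.
#' @return 2 x J matrix with rows `armigera`, `zea`.
#' @export
reference_frequencies <- function(table, armigera_ids, zea_ids, eps = 1e-6) {
  stopifnot(inherits(table, "variant_table"))
  if (!length(armigera_ids) || !length(zea_ids))
    stop("both reference panels must be non-empty")
  freq_of <- function(ids) {
    g <- table$geno[, match(ids, table$samples), drop = FALSE]
    f <- rowMeans(g, na.rm = TRUE) / 2
    f[!is.finite(f)] <- 0.5
    f
  }
  F <- rbind(armigera = freq_of(armigera_ids), zea = freq_of(zea_ids))
  pmin(pmax(F, eps), 1 - eps)
}

#' Supervised ancestry projection against fixed reference frequencies
#'
#' Maximizes the admixture likelihood over each query individual's
#' ancestry fraction with the population frequencies held fixed (EM on q
#' only — for K=2 a one-dimensional concave problem). Individuals with no
#' called genotype get `NA` with a warning.
#'
#' @param x a [variant_table()] or dosage matrix (individuals x sites) of
#'   the query samples.
#' @param F_ref fixed K x J frequency matrix (rows named by species), as
#'   from [reference_frequencies()].
#' @param tol convergence tolerance on the largest change in q.
#' @param max_iter iteration cap.
#' @return matrix of ancestry fractions, individuals x K, columns named
#'   after the rows of `F_ref`; rows sum to 1.
#' @export
fit_supervised <- function(x, F_ref, tol = 1e-8, max_iter = 10000) {
  G <- as_dosage_matrix(x)
  if (ncol(G) != ncol(F_ref)) stop("site dimension mismatch with F_ref")
  K <- nrow(F_ref)
  N <- nrow(G)
  empty <- rowSums(!is.na(G)) == 0
  if (any(empty))
    warning(sum(empty), " individual(s) with no called genotypes: q = NA")
  Q <- matrix(1 / K, N, K)
  Gf <- G[!empty, , drop = FALSE]
  Qf <- Q[!empty, , drop = FALSE]
  for (it in seq_len(max_iter)) {
    Qn <- em_step(Gf, Qf, F_ref, update_f = FALSE)$Q
    done <- max(abs(Qn - Qf)) < tol
    Qf <- Qn
    if (done) break
  }
  Q[!empty, ] <- Qf
  Q[empty, ] <- NA_real_
  colnames(Q) <- rownames(F_ref)
  rownames(Q) <- rownames(G)
  Q
}

#' Classify samples as pure or hybrid from ancestry fractions
#'
#' A sample is called pure for a species when its ancestry fraction for
#' that species reaches the purity threshold; everything else is treated
#' as hybrid/admixed. This is the unsupervised route to identifying the
#' unhybridized reference genomes that anchor AIM discovery.
#'
#' @param estimate an `ancestry_estimate` (or a Q matrix with species
#'   column names).
#' @param threshold purity threshold on q, default 0.99.
#' @return list with character vectors `pure_armigera`, `pure_zea`,
#'   `hybrid`.
#' @export
classify_purity <- function(estimate, threshold = 0.99) {
  Q <- if (inherits(estimate, "ancestry_estimate")) estimate$Q else estimate
  if (!all(c("armigera", "zea") %in% colnames(Q)))
    stop("Q columns must be labeled 'armigera' and 'zea'")
  ids <- rownames(Q)
  if (is.null(ids)) ids <- sprintf("sample%d", seq_len(nrow(Q)))
  pa <- Q[, "armigera"] >= threshold
  pz <- Q[, "zea"] >= threshold
  list(pure_armigera = ids[pa],
       pure_zea = ids[pz],
       hybrid = ids[!pa & !pz])
}
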