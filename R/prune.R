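#' Linkage-disequilibrium pruning parameters
#'
#' Pairwise genotype-correlation pruning in sliding windows, in the style
#' of plink's pairwise prune. The r-squared threshold of 0.95 is the one
#' meaningful parameter for downstream ancestry estimation (which assumes
#' independent loci); window and step sizes are conventional defaults.
#'
#' @param r2_max maximum allowed squared dosage correlation between any
#'   retained pair within a window, in (0, 1].
#' @param window_size window length in SNPs.
#' @param window_step step between window starts in SNPs; must not exceed
#'   `window_size` (windows must tile the chromosome).
#' @return object of class `prune_spec`.
#' @export
prune_spec <- function(r2_max = 0.95, window_size = 50, window_step = 5) {
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must lie in (0, 1]")
  if (window_step > window_size) stop("window_step must be <= window_size")
  if (window_size < 2 || window_step < 1) stop("invalid window geometry")
  structure(list(r2_max = r2_max,
                 window_size = as.integer(window_size),
                 window_step = as.integer(window_step)),
            class = "prune_spec")
}

#' Squared genotype correlation between two sites
#'
#' Squared Pearson correlation of alt-allele dosages over jointly called
#' samples (unphased data, so this is allele-count LD, not haplotype LD).
#' Defined as 0 when either vector is constant over the jointly called
#' samples or fewer than two samples are jointly called.
#'
#' @param a,b equal-length dosage vectors (NA = missing).
#' @return squared correlation in [0, 1].
#' @export
genotype_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("dosage vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(0)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(0)
  stats::cor(a, b)^2
}

#' Prune sites in linkage disequilibrium
#'
#' Slides windows of `window_size` SNPs (stepping by `window_step`) along
#' each chromosome; within a window, while any retained pair has
#' r-squared above `r2_max`, the member of the currently worst pair with
#' the lower MAF is removed (ties broken toward the larger position
#' index). Windows are defined over the sequence of currently retained
#' sites and never span chromosomes; passes are repeated until no further
#' site is removed, so removals that pull distant sites into a common
#' window are resolved too. The result is an order-preserving subset in
#' which no retained pair within any window of the pruned sequence
#' exceeds the threshold; pruning an already-pruned table removes
#' nothing.
#'
#' @param table a [variant_table()] with sites sorted by (chrom, pos).
#' @param spec a [prune_spec()].
#' @return integer vector of retained site indices (ascending).
#' @export
prune_ld <- function(table, spec = prune_spec()) {
  stopifnot(inherits(table, "variant_table"), inherits(spec, "prune_spec"))
  maf <- compute_maf(table)
  maf[is.na(maf)] <- -1  # all-missing sites lose every tie
  retained_all <- integer(0)
  for (chr in unique(table$sites$chrom)) {
    idx <- which(table$sites$chrom == chr)
    retained_all <- c(retained_all,
                      idx[prune_chromosome(table$geno[idx, , drop = FALSE],
                                           maf[idx], spec)])
  }
  sort(retained_all)
}

prune_chromosome <- function(G, maf, spec) {
  n <- nrow(G)
  if (n < 2) return(seq_len(n))
  keep <- rep(TRUE, n)
  repeat {
    cur <- which(keep)
    m <- length(cur)
    if (m < 2) break
    removed <- FALSE
    for (ws in seq(1L, max(1L, m - 1L), by = spec$window_step)) {
      win <- cur[ws:min(ws + spec$window_size - 1L, m)]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- suppressWarnings(stats::cor(t(G[win, , drop = FALSE]),
                                        use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      while (TRUE) {
        worst <- which.max(r2)
        if (r2[worst] <= spec$r2_max) break
        ij <- arrayInd(worst, dim(r2))
        i <- win[ij[1]]; j <- win[ij[2]]
        # drop lower MAF; tie -> larger position index
        drop <- if (maf[i] < maf[j]) i
                else if (maf[j] < maf[i]) j
                else max(i, j)
        keep[drop] <- FALSE
        removed <- TRUE
        w <- which(win == drop)
        r2[w, ] <- 0
        r2[, w] <- 0
      }
    }
    if (!removed) break
  }
  which(keep)
}
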