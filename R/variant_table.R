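#' Construct a variant table
#'
#' The central container of the pipeline: per-site metadata together with a
#' per-sample alt-allele dosage matrix and a per-sample read-depth matrix, as
#' obtained from a jointly called multi-sample VCF. Dosage is the number of
#' alternate-allele copies (0, 1, 2) with `NA` for missing genotypes
#' (`./.`); depth is the per-sample `DP` field with absent values recorded
#' as 0.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `qual` (phred-scaled site quality); one row per biallelic SNP,
#'   unique by (chrom, pos), sorted by (chrom, pos).
#' @param geno integer matrix, sites x samples, entries in {0, 1, 2, NA}.
#' @param depth integer matrix, sites x samples, non-negative.
#' @param samples character vector of sample identifiers (column names).
#'
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, geno, depth, samples) {
  sites <- as.data.frame(sites)
  stopifnot(
    all(c("chrom", "pos", "ref", "alt", "qual") %in% names(sites)),
    is.matrix(geno), is.matrix(depth),
    nrow(geno) == nrow(sites), nrow(depth) == nrow(sites),
    ncol(geno) == length(samples), ncol(depth) == length(samples)
  )
  if (anyDuplicated(sites[c("chrom", "pos")]))
    stop("sites must be unique by (chrom, pos)")
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  if (anyNA(depth) || any(depth < 0))
    stop("depths must be non-negative and non-missing")
  colnames(geno) <- samples
  colnames(depth) <- samples
  rownames(sites) <- NULL
  structure(
    list(sites = sites, geno = geno, depth = depth, samples = samples),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf(
    "<variant_table> %d sites x %d samples (%s)\n",
    n_sites(x), length(x$samples),
    paste(unique(x$sites$chrom), collapse = ", ")
  ))
  invisible(x)
}

#' Number of sites in a variant table
#' @param table a `variant_table`
#' @return integer count of sites (rows)
#' @export
n_sites <- function(table) nrow(table$sites)

#' Subset a variant table by site index
#'
#' @param table a `variant_table`
#' @param idx integer or logical index over sites
#' @return a `variant_table` with the selected sites, order preserved
#' @export
subset_sites <- function(table, idx) {
  variant_table(
    sites = table$sites[idx, , drop = FALSE],
    geno = table$geno[idx, , drop = FALSE],
    depth = table$depth[idx, , drop = FALSE],
    samples = table$samples
  )
}

# Seed-scoped RNG: run expr under set.seed(seed) without clobbering the
# caller's stream; seed = NULL uses the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-separated child seed, kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 1000003 * k) %% .Machine$integer.max)
}
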