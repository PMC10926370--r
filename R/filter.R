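#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF v4.2 file (via vcfR) and returns the per-site / per-sample
#' dosage and depth matrices the pipeline works on. Only biallelic SNP
#' records are kept; multi-allelic records and indels are dropped with a
#' message stating the count. Genotypes `./.` (or `.`) become `NA` dosage;
#' a missing or absent per-sample DP is recorded as depth 0, consistent
#' with a caller that emits reference calls at zero coverage.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return a [variant_table()], sites sorted by (chrom, pos).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_in <- nrow(fix)
  if (n_in == 0) {
    samples <- colnames(vcf@gt)[-1]
    if (is.null(samples)) samples <- character(0)
    empty <- matrix(integer(0), 0, length(samples))
    return(variant_table(
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), qual = numeric(0)),
      empty, empty, samples
    ))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0)
    message(n_drop, " non-biallelic-SNP record(s) dropped")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt),
                                dimnames = dimnames(gt))
  gt <- gt[snp, , drop = FALSE]
  dp <- dp[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]

  dose <- gt_to_dosage(gt)
  dp[is.na(dp)] <- 0
  storage.mode(dp) <- "integer"

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = qual
  )
  ord <- order(sites$chrom, sites$pos)
  variant_table(sites[ord, , drop = FALSE],
                dose[ord, , drop = FALSE],
                dp[ord, , drop = FALSE],
                colnames(gt))
}

# "0/0"->0, "0/1"/"1|0"->1, "1/1"->2, "./." or "."->NA
gt_to_dosage <- function(gt) {
  al <- gsub("[^01.]", "", gt)
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[al == "00"] <- 0L
  dose[al %in% c("01", "10")] <- 1L
  dose[al == "11"] <- 2L
  dose
}

#' Site-filter thresholds
#'
#' Defaults follow the standard post-calling filtration for this analysis:
#' sites are removed when mean read depth < 5, QUAL < 20, or minor allele
#' frequency < 0.05, and the Z sex chromosome (chromosome 1) is excluded so
#' ancestry is estimated from autosomes only. Removal conditions are strict
#' (`<`), so thresholds are inclusive on the keep side.
#'
#' @param min_mean_dp minimum mean depth across all samples (zero-depth
#'   samples included in the mean, since the caller emits reference calls
#'   there).
#' @param min_qual minimum phred-scaled site quality.
#' @param min_maf minimum minor allele frequency, in [0, 0.5].
#' @param exclude_chroms chromosomes removed outright (default the sex
#'   chromosome `chr1`).
#' @param biallelic_only retain biallelic SNPs only (always true for
#'   tables from [read_vcf()], kept for config completeness).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(min_mean_dp = 5, min_qual = 20, min_maf = 0.05,
                        exclude_chroms = "chr1", biallelic_only = TRUE) {
  if (min_mean_dp < 0 || min_qual < 0) stop("thresholds must be >= 0")
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
  structure(
    list(min_mean_dp = min_mean_dp, min_qual = min_qual, min_maf = min_maf,
         exclude_chroms = as.character(exclude_chroms),
         biallelic_only = isTRUE(biallelic_only)),
    class = "filter_spec"
  )
}

#' Per-site minor allele frequency
#'
#' Alt-allele frequency is the dosage sum over called samples divided by
#' twice the number of called samples; MAF folds it onto [0, 0.5]. Missing
#' genotypes are excluded from both numerator and denominator. A site with
#' no called genotype has undefined MAF (`NA`) and fails the MAF filter.
#'
#' @param table a [variant_table()].
#' @return numeric vector of per-site MAF in [0, 0.5], `NA` where undefined.
#' @export
compute_maf <- function(table) {
  called <- rowSums(!is.na(table$geno))
  alt <- rowSums(table$geno, na.rm = TRUE)
  af <- ifelse(called > 0, alt / (2 * called), NA_real_)
  pmin(af, 1 - af)
}

#' Apply site-level filters
#'
#' All criteria are evaluated on the unfiltered table; a site is retained
#' iff it passes every one. The report counts each criterion independently
#' (a site failing two criteria appears in both breakdown rows) plus the
#' union, which equals rows(in) - rows(out).
#'
#' @param table a [variant_table()].
#' @param spec a [filter_spec()].
#' @return list with `table` (the filtered [variant_table()]) and `report`
#'   (data.frame: criterion, n_removed).
#' @export
apply_site_filters <- function(table, spec = filter_spec()) {
  stopifnot(inherits(table, "variant_table"), inherits(spec, "filter_spec"))
  mean_dp <- if (ncol(table$depth) > 0) rowMeans(table$depth) else
    rep(0, n_sites(table))
  maf <- compute_maf(table)
  fail_dp <- mean_dp < spec$min_mean_dp
  fail_qual <- is.na(table$sites$qual) | table$sites$qual < spec$min_qual
  fail_maf <- is.na(maf) | maf < spec$min_maf
  fail_chrom <- table$sites$chrom %in% spec$exclude_chroms
  fail_any <- fail_dp | fail_qual | fail_maf | fail_chrom
  report <- data.frame(
    criterion = c("mean_depth", "qual", "maf", "excluded_chrom", "union"),
    n_removed = c(sum(fail_dp), sum(fail_qual), sum(fail_maf),
                  sum(fail_chrom), sum(fail_any))
  )
  list(table = subset_sites(table, !fail_any), report = report)
}
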