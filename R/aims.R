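#' Discover ancestry informative markers (AIMs)
#'
#' A site is a zea-diagnostic AIM when (a) every genome of the
#' unhybridized zea reference panel carries at least one alt allele (no
#' 0/0 and no missing genotype — missingness cannot certify presence), and
#' (b) at most one genome of the unhybridized armigera reference panel
#' carries the alt allele. With 7 zea reference genomes this is the
#' "minor allele count 7 in zea / at most 1 in armigera" rule. The alt
#' allele is the diagnostic allele because variants are called against an
#' armigera-derived reference genome.
#'
#' @param table a [variant_table()].
#' @param zea_ids,armigera_ids sample ids of the unhybridized reference
#'   panels (from [classify_purity()]).
#' @param max_armigera_carriers maximum number of armigera reference
#'   genomes allowed to carry the diagnostic allele (default 1; 0 gives
#'   the strict variant).
#' @return object of class `aim_set`: data.frame with `site` (row index
#'   into `table`), `chrom`, `pos`, `diagnostic_allele`,
#'   `n_zea_carriers`, `n_armigera_carriers`.
#' @export
discover_aims <- function(table, zea_ids, armigera_ids,
                          max_armigera_carriers = 1) {
  stopifnot(inherits(table, "variant_table"))
  if (!length(zea_ids)) stop("zea reference panel is empty: AIM criterion undefined")
  if (!length(armigera_ids)) stop("armigera reference panel is empty")
  gz <- table$geno[, match(zea_ids, table$samples), drop = FALSE]
  ga <- table$geno[, match(armigera_ids, table$samples), drop = FALSE]
  nz <- length(zea_ids)
  all_zea_carry <- rowSums(!is.na(gz) & gz >= 1) == nz
  arm_carriers <- rowSums(ga >= 1, na.rm = TRUE)
  is_aim <- all_zea_carry & arm_carriers <= max_armigera_carriers
  out <- data.frame(
    site = which(is_aim),
    chrom = table$sites$chrom[is_aim],
    pos = table$sites$pos[is_aim],
    diagnostic_allele = table$sites$alt[is_aim],
    n_zea_carriers = rep.int(nz, sum(is_aim)),
    n_armigera_carriers = arm_carriers[is_aim]
  )
  rownames(out) <- NULL
  structure(out, class = c("aim_set", "data.frame"))
}

#' AIM-based ancestry proportion of one sample
#'
#' The percentage of zea-specific AIM alleles a sample carries.
#' Dosage coding counts alt-allele copies: 100 x sum(dosage) /
#' (2 x n scored AIMs) — the coding whose expectation for an ideal F1 is
#' exactly 50%. Presence coding counts AIMs with at least one alt copy:
#' 100 x n(dosage >= 1) / n scored. With `mask_below_dp` set, AIMs where
#' the sample's depth is below the threshold are excluded from numerator
#' and denominator — removing the positions where a joint caller's
#' zero/low-coverage reference calls masquerade as armigera alleles.
#'
#' @param table a [variant_table()].
#' @param sample a sample id present in `table`.
#' @param aims an [discover_aims()] result.
#' @param coding `"dosage"` (default) or `"presence"`.
#' @param mask_below_dp optional depth threshold; AIMs with DP below it
#'   are not scored.
#' @return list with `percent` (in [0, 100], `NA` if nothing scored) and
#'   `n_scored`.
#' @export
aim_ancestry_proportion <- function(table, sample, aims,
                                    coding = c("dosage", "presence"),
                                    mask_below_dp = NULL) {
  coding <- match.arg(coding)
  stopifnot(inherits(table, "variant_table"))
  if (nrow(aims) == 0) stop("AIM set is empty")
  si <- match(sample, table$samples)
  if (is.na(si)) stop("unknown sample: ", sample)
  d <- table$geno[aims$site, si]
  dp <- table$depth[aims$site, si]
  keep <- !is.na(d)
  if (!is.null(mask_below_dp)) keep <- keep & dp >= mask_below_dp
  d <- d[keep]
  n <- length(d)
  if (n == 0) {
    warning("all AIMs masked or missing for sample ", sample)
    return(list(percent = NA_real_, n_scored = 0L))
  }
  pct <- if (coding == "dosage") 100 * sum(d) / (2 * n)
         else 100 * mean(d >= 1)
  list(percent = pct, n_scored = n)
}

#' Low-coverage diagnostics at AIM positions for one sample
#'
#' Counts the AIM positions where the sample has no coverage (DP = 0 —
#' force-called as the armigera reference genotype by a joint caller) and
#' where depth is below the confidence threshold, and returns the flagged
#' positions for masking.
#'
#' @inheritParams aim_ancestry_proportion
#' @param dp_threshold confidence threshold on DP (default 5).
#' @return list with `n_dp0`, `n_below_threshold`, and `flagged`
#'   (data.frame chrom, pos, dp of the below-threshold AIMs).
#' @export
depth_diagnostics <- function(table, sample, aims, dp_threshold = 5) {
  stopifnot(inherits(table, "variant_table"))
  si <- match(sample, table$samples)
  if (is.na(si)) stop("unknown sample: ", sample)
  dp <- table$depth[aims$site, si]
  below <- dp < dp_threshold
  list(
    n_dp0 = sum(dp == 0L),
    n_below_threshold = sum(below),
    flagged = data.frame(chrom = aims$chrom[below], pos = aims$pos[below],
                         dp = dp[below])
  )
}

#' Per-sample AIM ancestry report
#'
#' Scores every sample of a variant table against an AIM set under both
#' codings, with the low-depth diagnostics and the masked (DP-filtered)
#' re-estimate.
#'
#' @param table a [variant_table()].
#' @param aims an [discover_aims()] result.
#' @param dp_threshold depth threshold used for diagnostics and masking.
#' @return data.frame, one row per sample: `sample_id`,
#'   `prop_zea_dosage`, `prop_zea_presence`, `n_aims_dp0`,
#'   `n_aims_dp_below_thresh`, `prop_zea_masked` (dosage coding on AIMs
#'   with DP >= threshold).
#' @export
aim_report <- function(table, aims, dp_threshold = 5) {
  rows <- lapply(table$samples, function(s) {
    diag <- depth_diagnostics(table, s, aims, dp_threshold)
    masked <- suppressWarnings(
      aim_ancestry_proportion(table, s, aims, "dosage",
                              mask_below_dp = dp_threshold))
    data.frame(
      sample_id = s,
      prop_zea_dosage = aim_ancestry_proportion(table, s, aims,
                                                "dosage")$percent,
      prop_zea_presence = aim_ancestry_proportion(table, s, aims,
                                                  "presence")$percent,
      n_aims_dp0 = diag$n_dp0,
      n_aims_dp_below_thresh = diag$n_below_threshold,
      prop_zea_masked = masked$percent
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
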