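#' Simulation configuration for a two-species genotype panel
#'
#' Describes a synthetic *Helicoverpa armigera* / *H. zea* style dataset:
#' two divergent populations under a Balding-Nichols model, pure and hybrid
#' individuals, Poisson read depths, and a joint-caller emulation in which
#' zero-coverage positions are emitted as homozygous reference (the
#' low-coverage reference bias this pipeline diagnoses).
#'
#' Defaults mirror the reference panel the method was designed around:
#' 34 pure armigera genomes, 7 pure zea genomes, two F1 hybrids, and a mean
#' genome-wide depth of 30x. Chromosome 1 plays the role of the Z sex
#' chromosome and is excludable downstream.
#'
#' @param n_sites number of biallelic SNP sites.
#' @param n_chromosomes number of chromosomes; sites are assigned
#'   round-robin and chromosome 1 is designated the sex chromosome.
#' @param fst divergence parameter in (0, 1) of the Balding-Nichols model.
#' @param n_pure_armigera,n_pure_zea counts of pure individuals.
#' @param hybrid_spec data.frame with columns `class` (one of `"F1"`,
#'   `"BC_toward_A"`, `"BC_toward_Z"`, `"admixed"`), `n` (count) and
#'   `q_armigera` (armigera ancestry fraction, used for `"admixed"` only).
#'   See [hybrid_panel()].
#' @param mean_depth expected reads per site per sample (Poisson mean).
#' @param fixed_diff_frac fraction of sites forced to fixed differences
#'   (armigera alt frequency 0, zea alt frequency 1), guaranteeing
#'   AIM-like diagnostic sites.
#' @param low_qual_frac fraction of sites forced below QUAL 20, to exercise
#'   the site-quality filter.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#'
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_sites = 5000,
                       n_chromosomes = 5,
                       fst = 0.3,
                       n_pure_armigera = 34,
                       n_pure_zea = 7,
                       hybrid_spec = hybrid_panel(f1 = 2),
                       mean_depth = 30,
                       fixed_diff_frac = 0.05,
                       low_qual_frac = 0.05,
                       seed = 1L) {
  if (!is.numeric(fst) || length(fst) != 1 || fst <= 0 || fst >= 1)
    stop("fst must lie strictly in (0, 1)")
  if (n_sites < 0 || n_pure_armigera < 0 || n_pure_zea < 0)
    stop("counts must be non-negative")
  if (n_chromosomes < 1) stop("need at least one chromosome")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (fixed_diff_frac < 0 || fixed_diff_frac > 1 ||
      low_qual_frac < 0 || low_qual_frac > 1)
    stop("fractions must lie in [0, 1]")
  hybrid_spec <- validate_hybrid_spec(hybrid_spec)
  structure(
    list(
      n_sites = as.integer(n_sites),
      n_chromosomes = as.integer(n_chromosomes),
      fst = fst,
      n_pure_armigera = as.integer(n_pure_armigera),
      n_pure_zea = as.integer(n_pure_zea),
      hybrid_spec = hybrid_spec,
      mean_depth = mean_depth,
      fixed_diff_frac = fixed_diff_frac,
      low_qual_frac = low_qual_frac,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Specify the hybrid individuals of a simulated panel
#'
#' @param f1 number of F1 hybrids (one allele drawn from each species'
#'   frequency at every site; heterozygous at all fixed differences).
#' @param bc_armigera,bc_zea numbers of first-generation backcrosses,
#'   modeled as unlinked admixed individuals with armigera ancestry 0.75
#'   and 0.25 respectively.
#' @param admixed numeric vector of armigera ancestry fractions, one
#'   arbitrary admixed individual per entry.
#' @return data.frame with columns `class`, `n`, `q_armigera`.
#' @export
hybrid_panel <- function(f1 = 0, bc_armigera = 0, bc_zea = 0,
                         admixed = numeric(0)) {
  spec <- data.frame(
    class = c("F1", "BC_toward_A", "BC_toward_Z",
              rep("admixed", length(admixed))),
    n = c(f1, bc_armigera, bc_zea, rep(1L, length(admixed))),
    q_armigera = c(0.5, 0.75, 0.25, admixed)
  )
  spec[spec$n > 0, , drop = FALSE]
}

validate_hybrid_spec <- function(spec) {
  spec <- as.data.frame(spec)
  if (nrow(spec) == 0)
    return(data.frame(class = character(0), n = integer(0),
                      q_armigera = numeric(0)))
  stopifnot(all(c("class", "n", "q_armigera") %in% names(spec)))
  ok <- spec$class %in% c("F1", "BC_toward_A", "BC_toward_Z", "admixed")
  if (!all(ok))
    stop("unknown hybrid class: ", paste(spec$class[!ok], collapse = ", "))
  if (any(spec$n < 0)) stop("hybrid counts must be non-negative")
  adm <- spec$class == "admixed"
  if (any(is.na(spec$q_armigera[adm])) ||
      any(spec$q_armigera[adm] < 0 | spec$q_armigera[adm] > 1))
    stop("admixed q_armigera must lie in [0, 1]")
  spec$q_armigera[spec$class == "F1"] <- 0.5
  spec$q_armigera[spec$class == "BC_toward_A"] <- 0.75
  spec$q_armigera[spec$class == "BC_toward_Z"] <- 0.25
  rownames(spec) <- NULL
  spec
}

#' Draw per-site population allele frequencies (Balding-Nichols model)
#'
#' Each site has an ancestral alt-allele frequency p0 ~ Uniform(0.05, 0.95);
#' each species' frequency is then drawn from
#' Beta(p0 (1-F)/F, (1-p0)(1-F)/F) with F the configured divergence, so the
#' frequency has mean p0 and variance F p0 (1 - p0). A configured fraction
#' of sites is forced to fixed differences (armigera frequency 0, zea
#' frequency 1): the alternate allele is defined against an armigera-like
#' reference, so diagnostic alt alleles segregate in zea.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed` (`NULL` leaves the
#'   ambient RNG stream untouched).
#' @return list with numeric vectors `freq_armigera`, `freq_zea`, `p0`
#'   (length `n_sites`) and integer vector `fixed_diff_sites`.
#' @export
draw_population_frequencies <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    J <- config$n_sites
    p0 <- stats::runif(J, 0.05, 0.95)
    F <- config$fst
    shape <- (1 - F) / F
    fa <- stats::rbeta(J, p0 * shape, (1 - p0) * shape)
    fz <- stats::rbeta(J, p0 * shape, (1 - p0) * shape)
    n_fd <- floor(config$fixed_diff_frac * J)
    fd <- if (n_fd > 0) sort(sample.int(J, n_fd)) else integer(0)
    fa[fd] <- 0
    fz[fd] <- 1
    list(freq_armigera = fa, freq_zea = fz, p0 = p0,
         fixed_diff_sites = fd)
  })
}

#' Build the sample panel implied by a simulation configuration
#'
#' @param config a [sim_config()].
#' @return data.frame with `sample_id`, `class`, `q_armigera`, `q_zea`,
#'   and the putative `species_label` a field worker would assign
#'   (hybrids are labeled with their nominal species of collection, zea,
#'   since cryptic hybrids arrive labeled as the local species).
#' @export
sim_sample_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  if (config$n_pure_armigera > 0)
    rows[[length(rows) + 1]] <- data.frame(
      class = "pure_armigera", q_armigera = 1,
      stringsAsFactors = FALSE
    )[rep(1, config$n_pure_armigera), , drop = FALSE]
  if (config$n_pure_zea > 0)
    rows[[length(rows) + 1]] <- data.frame(
      class = "pure_zea", q_armigera = 0
    )[rep(1, config$n_pure_zea), , drop = FALSE]
  hs <- config$hybrid_spec
  for (i in seq_len(nrow(hs)))
    rows[[length(rows) + 1]] <- data.frame(
      class = hs$class[i], q_armigera = hs$q_armigera[i]
    )[rep(1, hs$n[i]), , drop = FALSE]
  panel <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(0), q_armigera = numeric(0))
  n <- nrow(panel)
  panel$q_zea <- 1 - panel$q_armigera
  panel$sample_id <- sprintf("S%03d_%s", seq_len(n), abbrev_class(panel$class))
  panel$species_label <- ifelse(panel$class == "pure_armigera",
                                "armigera", "zea")
  rownames(panel) <- NULL
  panel[c("sample_id", "class", "q_armigera", "q_zea", "species_label")]
}

abbrev_class <- function(class) {
  c(pure_armigera = "arm", pure_zea = "zea", F1 = "f1",
    BC_toward_A = "bca", BC_toward_Z = "bcz", admixed = "adm")[class]
}

#' Simulate true genotypes for a panel of individuals
#'
#' Pure individuals of species S draw dosage ~ Binomial(2, freq_S). An F1
#' draws one allele Bernoulli(freq_armigera) and one Bernoulli(freq_zea),
#' so it is heterozygous at every fixed difference. An admixed individual
#' with armigera fraction q draws each of its two alleles from the armigera
#' frequency with probability q and from the zea frequency otherwise
#' (unlinked-loci approximation; backcrosses are admixed with q = 0.75 or
#' 0.25).
#'
#' @param freq_armigera,freq_zea per-site alt-allele frequencies in [0, 1].
#' @param panel data.frame as from [sim_sample_panel()] (needs `class` and
#'   `q_armigera`).
#' @param seed optional integer seed (`NULL` = ambient stream).
#' @return integer matrix of true dosages, sites x individuals.
#' @export
simulate_genotypes <- function(freq_armigera, freq_zea, panel, seed = NULL) {
  stopifnot(length(freq_armigera) == length(freq_zea),
            all(freq_armigera >= 0 & freq_armigera <= 1),
            all(freq_zea >= 0 & freq_zea <= 1))
  J <- length(freq_armigera)
  N <- nrow(panel)
  with_seed(seed, {
    G <- matrix(0L, J, N)
    for (i in seq_len(N)) {
      cls <- panel$class[i]
      G[, i] <- if (cls == "pure_armigera") {
        stats::rbinom(J, 2, freq_armigera)
      } else if (cls == "pure_zea") {
        stats::rbinom(J, 2, freq_zea)
      } else if (cls == "F1") {
        stats::rbinom(J, 1, freq_armigera) + stats::rbinom(J, 1, freq_zea)
      } else {
        q <- panel$q_armigera[i]
        p <- q * freq_armigera + (1 - q) * freq_zea
        stats::rbinom(J, 2, p)
      }
    }
    storage.mode(G) <- "integer"
    if (!is.null(panel$sample_id)) colnames(G) <- panel$sample_id
    G
  })
}

#' Emulate joint variant calling over true genotypes
#'
#' Per sample and site, read depth DP ~ Poisson(`mean_depth`); each read
#' carries one of the individual's two allele copies uniformly at random.
#' The called genotype is homozygous for the observed allele if only one
#' allele is seen and heterozygous if both are. Crucially, DP = 0 yields a
#' homozygous-*reference* call (dosage 0), never a missing genotype: joint
#' callers emit the reference (armigera) genotype where a sample has no
#' coverage, which is the low-coverage bias the downstream diagnostics
#' quantify. Site QUAL is min(99, 3 x mean DP at the site), with a
#' configured fraction of sites forced below 20 to exercise the quality
#' filter.
#'
#' @param genotype_true integer matrix of true dosages (sites x samples).
#' @param mean_depth positive Poisson mean.
#' @param seed optional integer seed.
#' @param low_qual_frac fraction of sites whose QUAL is forced to 10.
#' @return list with integer matrices `dosage` and `depth`
#'   (sites x samples) and numeric vector `qual` (per site, 2 decimals).
#' @export
emulate_caller <- function(genotype_true, mean_depth, seed = NULL,
                           low_qual_frac = 0) {
  if (!is.numeric(mean_depth) || mean_depth <= 0)
    stop("mean_depth must be positive")
  g <- genotype_true
  if (length(g) && !all(g %in% 0:2)) stop("true dosages must be 0, 1 or 2")
  J <- nrow(g); N <- ncol(g)
  with_seed(seed, {
    dp <- matrix(stats::rpois(J * N, mean_depth), J, N)
    called <- g
    called[dp == 0L] <- 0L            # reference bias: no coverage => 0/0
    het <- which(g == 1L & dp > 0L)
    if (length(het)) {
      nalt <- stats::rbinom(length(het), dp[het], 0.5)
      called[het] <- ifelse(nalt == 0L, 0L,
                            ifelse(nalt == dp[het], 2L, 1L))
    }
    qual <- pmin(99, round(3 * rowMeans(dp), 2))
    n_lq <- floor(low_qual_frac * J)
    if (n_lq > 0) qual[sample.int(J, n_lq)] <- 10
    storage.mode(called) <- "integer"
    storage.mode(dp) <- "integer"
    dimnames(called) <- dimnames(g)
    dimnames(dp) <- dimnames(g)
    list(dosage = called, depth = dp, qual = qual)
  })
}

#' Simulate a complete two-species dataset in memory
#'
#' Runs frequency drawing, genotype simulation and caller emulation under
#' sub-seeds derived from `config$seed`, assigns sites round-robin to
#' chromosomes `chr1..chrN` (sorted by chromosome then position), and
#' returns both the caller-emulated [variant_table()] and the ground truth.
#'
#' @param config a [sim_config()].
#' @return object of class `hybrid_sim`: list with `table`
#'   (a `variant_table`), `panel` (sample sheet data.frame), and `truth`
#'   (list: `q_true` data.frame, `freq_armigera`, `freq_zea`,
#'   `genotype_true`, `fixed_diff_sites`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- draw_population_frequencies(config, seed = derive_seed(config$seed, 1))
  panel <- sim_sample_panel(config)
  gt <- simulate_genotypes(freqs$freq_armigera, freqs$freq_zea, panel,
                           seed = derive_seed(config$seed, 2))
  call <- emulate_caller(gt, config$mean_depth,
                         seed = derive_seed(config$seed, 3),
                         low_qual_frac = config$low_qual_frac)

  J <- config$n_sites
  chrom_idx <- rep_len(seq_len(config$n_chromosomes), J)
  pos <- 100L * (((seq_len(J) - 1L) %/% config$n_chromosomes) + 1L)
  bases <- c("A", "C", "G", "T")
  alleles <- with_seed(derive_seed(config$seed, 4), {
    ref <- sample(bases, J, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    list(ref = ref, alt = unname(alt))
  })
  ord <- order(chrom_idx, pos)

  sites <- data.frame(
    chrom = sprintf("chr%d", chrom_idx[ord]),
    pos = pos[ord],
    ref = alleles$ref[ord],
    alt = alleles$alt[ord],
    qual = call$qual[ord]
  )
  fd <- match(freqs$fixed_diff_sites, ord)
  table <- variant_table(sites,
                         geno = call$dosage[ord, , drop = FALSE],
                         depth = call$depth[ord, , drop = FALSE],
                         samples = panel$sample_id)
  truth <- list(
    q_true = data.frame(sample_id = panel$sample_id,
                        q_armigera = panel$q_armigera,
                        q_zea = panel$q_zea),
    freq_armigera = freqs$freq_armigera[ord],
    freq_zea = freqs$freq_zea[ord],
    genotype_true = gt[ord, , drop = FALSE],
    fixed_diff_sites = sort(fd)
  )
  structure(list(table = table, panel = panel, truth = truth,
                 config = config),
            class = "hybrid_sim")
}

#' Write a simulated dataset to disk as VCF + sample sheet + manifest
#'
#' Serializes the caller-emulated genotype matrix as a VCF v4.2 file
#' (FORMAT `GT:DP`, per-site QUAL), the sample panel as a TSV sample sheet
#' (`sample_id`, `species_label`, `truth_class`), and a JSON manifest
#' holding the configuration, the ground-truth ancestry fractions and
#' per-site population frequencies, and the MD5 checksum of the VCF.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with paths `vcf`, `sample_sheet`, `manifest`
#'   and the `hybrid_sim` object under `sim`.
#' @export
generate_dataset <- function(config, out_dir) {
  sim <- simulate_dataset(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  vcf_path <- file.path(out_dir, "simulated.vcf")
  sheet_path <- file.path(out_dir, "samples.tsv")
  manifest_path <- file.path(out_dir, "manifest.json")

  write_sim_vcf(sim$table, vcf_path, n_chromosomes = config$n_chromosomes)

  sheet <- data.frame(sample_id = sim$panel$sample_id,
                      species_label = sim$panel$species_label,
                      truth_class = sim$panel$class)
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    config = unclass(config),
    files = list(vcf = basename(vcf_path), sample_sheet = basename(sheet_path)),
    vcf_md5 = unname(tools::md5sum(vcf_path)),
    truth = list(
      q_true = sim$truth$q_true,
      freq_armigera = sim$truth$freq_armigera,
      freq_zea = sim$truth$freq_zea,
      fixed_diff_sites = sim$truth$fixed_diff_sites
    )
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(vcf = vcf_path, sample_sheet = sheet_path,
                 manifest = manifest_path, sim = sim))
}

write_sim_vcf <- function(table, path, n_chromosomes = NULL) {
  chroms <- if (is.null(n_chromosomes)) unique(table$sites$chrom) else
    paste0("chr", seq_len(n_chromosomes))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=helihybrid_simulator",
    paste0("##contig=<ID=", chroms, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  J <- n_sites(table)
  if (J > 0) {
    gt_str <- c("0/0", "0/1", "1/1")[table$geno + 1L]
    dim(gt_str) <- dim(table$geno)
    cells <- matrix(paste(gt_str, table$depth, sep = ":"),
                    nrow = J)
    body <- paste(
      table$sites$chrom, table$sites$pos, ".", table$sites$ref,
      table$sites$alt, sprintf("%.2f", table$sites$qual), ".", ".",
      "GT:DP",
      apply(cells, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(body, con)
  }
  invisible(path)
}
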