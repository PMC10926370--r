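#' Assemble a full pipeline configuration
#'
#' One serializable object holding every threshold and seed of the
#' simulate -> filter -> prune -> ancestry -> AIM workflow. Either `sim`
#' (synthetic run with ground truth) or `vcf` + `sample_sheet` (real
#' data) must be supplied.
#'
#' @param sim optional [sim_config()] for a synthetic run.
#' @param vcf,sample_sheet optional paths to a multi-sample VCF and a TSV
#'   sample sheet (`sample_id`, `species_label`).
#' @param filter a [filter_spec()].
#' @param prune a [prune_spec()].
#' @param ancestry list of ancestry-fit settings: `K`, `seed`, `tol`,
#'   `max_iter`, `purity_threshold`.
#' @param aims list of AIM settings: `coding`, `mask_below_dp`.
#' @param out_dir output directory for reports and the plot.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, vcf = NULL, sample_sheet = NULL,
                            filter = filter_spec(),
                            prune = prune_spec(),
                            ancestry = list(K = 2, seed = 1L, tol = 1e-6,
                                            max_iter = 2000,
                                            purity_threshold = 0.99),
                            aims = list(coding = "dosage",
                                        mask_below_dp = 5),
                            out_dir = tempfile("helihybrid_run_")) {
  if (is.null(sim) && is.null(vcf))
    stop("either a simulation config or an input VCF is required")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  defaults <- list(K = 2, seed = 1L, tol = 1e-6, max_iter = 2000,
                   purity_threshold = 0.99)
  ancestry <- utils::modifyList(defaults, ancestry)
  aims <- utils::modifyList(list(coding = "dosage", mask_below_dp = 5), aims)
  structure(
    list(sim = sim, vcf = vcf, sample_sheet = sample_sheet,
         filter = filter, prune = prune, ancestry = ancestry, aims = aims,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Serialize / restore a pipeline configuration
#'
#' Round-trips a [pipeline_config()] through JSON losslessly (class
#' attributes are restored on read).
#'
#' @param config a `pipeline_config`.
#' @param path destination / source path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- strip_classes(config)
  x$.sim_present <- !is.null(config$sim)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (isTRUE(x$.sim_present)) {
    s <- x$sim
    sim <- sim_config(
      n_sites = s$n_sites, n_chromosomes = s$n_chromosomes, fst = s$fst,
      n_pure_armigera = s$n_pure_armigera, n_pure_zea = s$n_pure_zea,
      hybrid_spec = as.data.frame(s$hybrid_spec),
      mean_depth = s$mean_depth, fixed_diff_frac = s$fixed_diff_frac,
      low_qual_frac = s$low_qual_frac, seed = s$seed
    )
  }
  pipeline_config(
    sim = sim, vcf = x$vcf, sample_sheet = x$sample_sheet,
    filter = do.call(filter_spec, x$filter),
    prune = do.call(prune_spec, x$prune),
    ancestry = x$ancestry, aims = x$aims,
    out_dir = x$out_dir
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full hybrid-detection pipeline
#'
#' Executes, in order: data acquisition (simulation with ground truth, or
#' VCF + sample sheet), site filtering, LD pruning, unsupervised K=2
#' ancestry estimation, purity classification, AIM discovery from the
#' unhybridized panels, AIM scoring with depth diagnostics, and the
#' stacked-bar ancestry plot. Writes per-stage TSV outputs, a combined
#' per-sample table, and a JSON manifest (seeds, thresholds, per-stage
#' SNP counts) to `config$out_dir`. On synthetic runs the ground-truth
#' ancestry is joined into the per-sample table.
#'
#' @param config a [pipeline_config()].
#' @param plot whether to render the ancestry bar plot (PNG).
#' @return list with `samples` (combined per-sample data.frame),
#'   `estimate` (the `ancestry_estimate`), `aims`, `counts` (per-stage
#'   site counts), `purity`, and `paths` of all written files.
#' @export
run_pipeline <- function(config, plot = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  acq <- run_stage("input", {
    if (!is.null(config$sim)) {
      sim <- simulate_dataset(config$sim)
      list(table = sim$table, labels = sim$panel$species_label,
           truth = sim$truth$q_true, classes = sim$panel$class)
    } else {
      table <- read_vcf(config$vcf)
      labels <- rep(NA_character_, length(table$samples))
      classes <- rep(NA_character_, length(table$samples))
      if (!is.null(config$sample_sheet)) {
        sheet <- utils::read.delim(config$sample_sheet)
        m <- match(table$samples, sheet$sample_id)
        labels <- sheet$species_label[m]
        if ("truth_class" %in% names(sheet)) classes <- sheet$truth_class[m]
      }
      list(table = table, labels = labels, truth = NULL, classes = classes)
    }
  })
  table <- acq$table
  counts <- list(input = n_sites(table))

  filt <- run_stage("filter", apply_site_filters(table, config$filter))
  counts$filtered <- n_sites(filt$table)
  paths$filter_report <- file.path(config$out_dir, "filter_report.tsv")
  utils::write.table(filt$report, paths$filter_report, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  kept <- run_stage("prune", prune_ld(filt$table, config$prune))
  pruned <- subset_sites(filt$table, kept)
  counts$pruned <- n_sites(pruned)
  paths$retained_sites <- file.path(config$out_dir, "retained_sites.tsv")
  utils::write.table(pruned$sites[c("chrom", "pos")], paths$retained_sites,
                     sep = "\t", quote = FALSE, row.names = FALSE)

  est <- run_stage("ancestry", fit_admixture(
    pruned, K = config$ancestry$K, seed = config$ancestry$seed,
    tol = config$ancestry$tol, max_iter = config$ancestry$max_iter,
    labels = acq$labels
  ))
  paths$q_matrix <- file.path(config$out_dir, "ancestry_q.tsv")
  qdf <- data.frame(sample_id = pruned$samples,
                    q_armigera = est$Q[, "armigera"],
                    q_zea = est$Q[, "zea"])
  utils::write.table(format_num_df(qdf), paths$q_matrix, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  purity <- run_stage("purity", classify_purity(
    est, threshold = config$ancestry$purity_threshold))

  aims <- run_stage("aims", discover_aims(
    pruned, zea_ids = purity$pure_zea, armigera_ids = purity$pure_armigera))
  counts$aims <- nrow(aims)
  paths$aims <- file.path(config$out_dir, "aims.tsv")
  bed <- data.frame(chrom = aims$chrom, start = aims$pos - 1L,
                    end = aims$pos,
                    diagnostic_allele = aims$diagnostic_allele,
                    n_zea_carriers = aims$n_zea_carriers,
                    n_armigera_carriers = aims$n_armigera_carriers)
  utils::write.table(bed, paths$aims, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  aim_tab <- run_stage("aim_score", aim_report(
    pruned, aims, dp_threshold = config$aims$mask_below_dp))

  samples <- data.frame(
    sample_id = pruned$samples,
    species_label = acq$labels,
    class = acq$classes,
    q_armigera = est$Q[, "armigera"],
    q_zea = est$Q[, "zea"],
    purity = ifelse(pruned$samples %in% purity$pure_armigera,
                    "pure_armigera",
                    ifelse(pruned$samples %in% purity$pure_zea,
                           "pure_zea", "hybrid"))
  )
  samples <- merge(samples, aim_tab, by = "sample_id", sort = FALSE)
  if (!is.null(acq$truth)) {
    truth <- acq$truth
    names(truth) <- c("sample_id", "q_armigera_true", "q_zea_true")
    samples <- merge(samples, truth, by = "sample_id", sort = FALSE)
  }
  samples <- samples[match(pruned$samples, samples$sample_id), ]
  rownames(samples) <- NULL
  paths$samples <- file.path(config$out_dir, "per_sample_report.tsv")
  utils::write.table(format_num_df(samples), paths$samples, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (plot) {
    paths$plot <- file.path(config$out_dir, "admixture_plot.png")
    run_stage("plot", {
      p <- plot_admixture(est$Q)
      save_plot_png(p, paths$plot)
    })
  }

  manifest <- list(
    config = serializable_config(config),
    counts = counts,
    n_samples = length(pruned$samples),
    files = lapply(paths, basename)
  )
  paths$manifest <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  list(samples = samples, estimate = est, aims = aims, counts = counts,
       purity = purity, paths = paths)
}

serializable_config <- function(config) strip_classes(config)

strip_classes <- function(x) {
  if (is.data.frame(x)) return(lapply(unclass(x), strip_classes))
  x <- if (is.list(x)) lapply(x, strip_classes) else x
  attr(x, "class") <- NULL
  x
}

# Fixed-width numeric formatting so identical runs write identical bytes.
format_num_df <- function(df) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  df
}

#' Stacked-bar ancestry plot
#'
#' One stacked bar per sample showing its ancestry fractions, the
#' conventional visualization of a Q matrix (armigera red, zea blue).
#'
#' @param Q ancestry matrix, individuals x K, rows on the simplex, with
#'   species column names and sample row names.
#' @param sample_order optional explicit ordering of samples on the x
#'   axis.
#' @return a ggplot object; its `$data` holds the long-format fractions.
#' @export
plot_admixture <- function(Q, sample_order = NULL) {
  if (is.null(dim(Q)) || nrow(Q) == 0) stop("Q matrix is empty")
  ids <- rownames(Q)
  if (is.null(ids)) ids <- sprintf("sample%d", seq_len(nrow(Q)))
  pops <- colnames(Q)
  if (is.null(pops)) pops <- paste0("pop", seq_len(ncol(Q)))
  long <- data.frame(
    sample = rep(ids, times = ncol(Q)),
    population = rep(pops, each = nrow(Q)),
    fraction = as.vector(Q)
  )
  if (is.null(sample_order)) sample_order <- ids
  long$sample <- factor(long$sample, levels = sample_order)
  cols <- c(armigera = "#c23b22", zea = "#2166ac")
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$sample, y = .data$fraction, fill = .data$population)) +
    ggplot2::geom_col(width = 1, position = "stack") +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
  if (all(pops %in% names(cols)))
    p <- p + ggplot2::scale_fill_manual(values = cols)
  p
}

save_plot_png <- function(p, path, width = 1600, height = 600) {
  grDevices::png(path, width = width, height = height, res = 150,
                 type = if (capabilities("cairo")) "cairo" else "Xlib")
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
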