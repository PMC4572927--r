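# Keys accepted in a pipeline config (file or list). Unknown keys error.
.pipeline_keys <- c("preset", "seed", "out_dir",
                    "expression_path", "annotation_path", "cytoband_path",
                    "assembly", "scale", "normalization", "groups_path",
                    "cutoffs", "bootstrap_B", "bootstrap_m", "ci_level",
                    "de_group_a", "de_group_b", "high_expression_floor",
                    "very_low_floor", "enrichment_alpha")

#' Parse a flat key-value pipeline config file
#'
#' One `key = value` (or `key<TAB>value`) pair per line; blank lines and
#' `#` comments ignored. Unknown keys are errors, guarding against silent
#' typos.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- lapply(lines, function(l) {
    m <- regmatches(l, regexec("^([A-Za-z_.]+)[ \t=]+(.+)$", l))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", l)
    m[2:3]
  })
  cfg <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  unknown <- setdiff(names(cfg), .pipeline_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in c("seed", "bootstrap_B", "bootstrap_m", "ci_level",
              "high_expression_floor", "very_low_floor",
              "enrichment_alpha"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg
}

#' Run the whole X:A dosage analysis end to end
#'
#' Stages, in order: simulate (preset) or ingest (expression + annotation
#' files) -> per-group expressed-in-all-replicates filtering and replicate
#' averaging -> bootstrap X:A ratio curve and per-chromosome median-ratio
#' matrix -> distribution statistics (KS test of X vs pooled autosomes,
#' kernel densities, bimodality score, frequency bins, cytoband
#' enrichment) -> differential expression when two groups are named.
#' Each random stage draws its own seed via [derive_seed()] from the
#' master seed, and every output file is written with fixed formatting, so
#' a re-run with the same config is byte-identical.
#'
#' @param config a named list or the path of a [read_pipeline_config()]
#'   file. `preset` and `expression_path` are mutually exclusive.
#' @return an object of class `pipeline_report`: output paths, the config
#'   echo, the seed ledger, per-stage summary statistics and warnings.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  has_preset <- !is.null(config$preset)
  has_files <- !is.null(config$expression_path)
  if (has_preset && has_files)
    stop("config must name either a preset or input files, not both")
  if (!has_preset && !has_files)
    stop("config must name a preset or an expression_path")
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  warnings <- character()
  seeds <- list(master = seed)
  smry <- list()

  # --- stage 1: data ---
  if (has_preset) {
    seeds$simulate <- derive_seed(seed, "simulate")
    scfg <- build_preset(config$preset, seed = seeds$simulate)
    sim <- simulate_dataset(scfg)
    expr <- sim$expression
    annotation <- sim$annotation
  } else {
    expr <- read_expression_table(config$expression_path,
                                  scale = config$scale %||% "linear",
                                  normalization = config$normalization %||%
                                    "FPKM",
                                  groups = config$groups_path)
    annotation <- read_gene_annotation(config$annotation_path,
                                       assembly = config$assembly %||%
                                         "mouse")
    if (!is.null(config$cytoband_path))
      annotation <- assign_cytobands(annotation,
                                     read_cytobands(config$cytoband_path))
    joined <- suppressMessages(join_annotation(expr, annotation))
    expr <- joined$expr
    annotation <- joined$annotation
    smry$join <- as.list(joined$join_log)
  }

  acfg <- analysis_config(
    bootstrap_B = config$bootstrap_B %||% 2000L,
    bootstrap_m = config$bootstrap_m %||% 100L,
    ci_level = config$ci_level %||% 0.95,
    high_expression_floor = config$high_expression_floor %||% 10,
    very_low_floor = config$very_low_floor %||% -5,
    enrichment_alpha = config$enrichment_alpha %||% 0.01,
    rng_seed = seed)
  scheme <- cutoff_scheme(config$cutoffs %||% "FPKM_default")
  groups <- unique(expr$groups)
  paths <- character()

  # --- stages 2-4 per group: filter/average, ratio, distributions ---
  for (g in groups) {
    genes <- filter_expressed_in_all_replicates(expr, g)
    smry[[paste0("n_expressed_all_reps.", g)]] <- length(genes)
    if (length(genes) < 2L) {
      warnings <- c(warnings,
                    sprintf("group %s: too few expressed genes; skipped", g))
      next
    }
    means <- average_replicates(expr, g, genes)
    ann_g <- annotation[match(genes, annotation$gene_id), ]
    is_x <- ann_g$chromosome == "chrX" & !ann_g$excluded_from_xa
    is_a <- ann_g$chromosome != "chrX" & !ann_g$excluded_from_xa
    smry[[paste0("n_x_expressed.", g)]] <- sum(is_x)
    smry[[paste0("n_autosomal_expressed.", g)]] <- sum(is_a)
    if (!any(is_x) || !any(is_a)) {
      warnings <- c(warnings,
                    sprintf("group %s: empty X or autosomal class; skipped", g))
      next
    }
    seeds[[paste0("ratio.", g)]] <- derive_seed(seed, paste0("ratio:", g))
    cfg_g <- acfg
    cfg_g$rng_seed <- seeds[[paste0("ratio.", g)]]
    curve <- xa_ratio_curve(means, annotation, scheme, cfg_g)
    paths <- c(paths, write_result_tables(curve, out_dir,
                                          paste0("ratio_curve_", g)))
    first <- which(curve$available)[1]
    smry[[paste0("xa_ratio_expressed.", g)]] <- curve$median_ratio[first]
    chrom <- per_chromosome_median_ratios(means, annotation, scheme)
    paths <- c(paths, write_result_tables(chrom, out_dir,
                                          paste0("chrom_ratios_", g)))
    freq <- expressed_fraction_table(means, annotation,
                                     bin_edges = acfg$frequency_bin_edges,
                                     alpha = acfg$enrichment_alpha)
    paths <- c(paths, write_result_tables(freq, out_dir,
                                          paste0("frequency_bins_", g)))
    x_log2 <- log2(means[is_x][means[is_x] > 0])
    a_log2 <- log2(means[is_a][means[is_a] > 0])
    ks <- ks_two_sample(x_log2, a_log2)
    smry[[paste0("ks_D.", g)]] <- ks$statistic
    smry[[paste0("ks_p.", g)]] <- ks$p_label
    seeds[[paste0("bimodality.", g)]] <-
      derive_seed(seed, paste0("bimodality:", g))
    bm <- bimodality_mixture_score(x_log2,
                                   seed = seeds[[paste0("bimodality.", g)]])
    smry[[paste0("bimodal_x.", g)]] <- bm$bimodal
    smry[[paste0("delta_bic_x.", g)]] <- bm$delta_bic
    if (any(!is.na(ann_g$band[is_x]))) {
      enr <- band_low_expression_enrichment(means, annotation,
                                            acfg$very_low_floor,
                                            acfg$enrichment_alpha)
      paths <- c(paths, write_result_tables(enr, out_dir,
                                            paste0("band_enrichment_", g)))
      smry[[paste0("enriched_bands.", g)]] <-
        paste(enr$band[enr$enriched], collapse = ",")
    }
  }

  # --- stage 5: differential expression ---
  de_groups <- c(config$de_group_a %||% NA, config$de_group_b %||% NA)
  if (all(is.na(de_groups)) && length(groups) == 2L) de_groups <- groups
  if (!anyNA(de_groups)) {
    de <- classify_differential(expr, de_groups, acfg)
    paths <- c(paths, write_result_tables(de, out_dir, "de_records"))
    smry <- c(smry, stats::setNames(
      attr(de, "summary")[c("n_tested", "n_de", "n_up_in_a", "n_up_in_b",
                            "n_slight", "n_moderate", "n_high")],
      paste0("de.", c("n_tested", "n_de", "n_up_in_a", "n_up_in_b",
                      "n_slight", "n_moderate", "n_high"))))
    if (attr(de, "summary")$n_de > 0) {
      enr <- chromosome_category_enrichment(de, annotation,
                                            alpha = acfg$enrichment_alpha)
      paths <- c(paths, write_result_tables(enr, out_dir,
                                            "chromosome_enrichment"))
    }
  } else {
    smry$de_skipped <- "single group"
  }

  report <- structure(
    list(paths = paths, config = config, seeds = seeds,
         summary = smry, warnings = warnings),
    class = "pipeline_report")
  report_path <- file.path(out_dir, "report.tsv")
  kv <- c(
    stats::setNames(lapply(names(config), function(k)
      as.character(config[[k]])), paste0("config.", names(config))),
    stats::setNames(seeds, paste0("seed.", names(seeds))),
    smry,
    list(n_warnings = length(warnings)))
  write_summary_kv(kv, report_path)
  report$paths <- c(report$paths, report_path)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  outputs:", length(x$paths), "files\n")
  for (k in names(x$summary))
    cat(sprintf("  %s: %s\n", k, paste(as.character(x$summary[[k]]),
                                       collapse = ",")))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
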