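#' Expression matrix with declared scale and normalization
#'
#' The central container for gene-level expression values: a genes x samples
#' numeric matrix tagged with its scale (`"linear"` or `"log2"`) and its
#' normalization (`"count"`, `"FPKM"`, `"TMM"`), plus a sample-to-group map.
#'
#' On the linear scale all values are finite and non-negative, and a value of
#' exactly 0 means "not expressed". On the log2 scale not-expressed entries
#' are `NA` (an explicit mask), never `-Inf`.
#'
#' @param values numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids).
#' @param scale `"linear"` or `"log2"`.
#' @param normalization `"count"`, `"FPKM"` or `"TMM"`.
#' @param groups named character vector mapping every sample id to a group
#'   label; defaults to a single group `"all"`.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values,
                              scale = c("linear", "log2"),
                              normalization = c("count", "FPKM", "TMM"),
                              groups = NULL) {
  scale <- match.arg(scale)
  normalization <- match.arg(normalization)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(gid)) {
    dup <- unique(gid[duplicated(gid)])
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(sid))
    stop("duplicated sample id(s)")
  if (scale == "linear") {
    if (anyNA(values) || any(values < 0) || any(!is.finite(values)))
      stop("linear-scale values must be finite and >= 0 (0 = not expressed)")
  } else {
    if (any(is.infinite(values)))
      stop("log2-scale values must use NA, not -Inf, for unexpressed genes")
  }
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", length(sid)), sid)
  } else {
    groups <- stats::setNames(as.character(groups), names(groups) %||% sid)
    if (!setequal(names(groups), sid))
      stop("`groups` must name every sample id exactly once")
    groups <- groups[sid]
  }
  structure(
    list(values = values, scale = scale, normalization = normalization,
         groups = groups),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$scale, x$normalization))
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$groups)),
                               as.integer(table(x$groups))), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Sample ids belonging to a group
#'
#' @param expr an [expression_matrix()].
#' @param group group label.
#' @return character vector of sample ids.
#' @export
samples_in_group <- function(expr, group) {
  stopifnot(inherits(expr, "expr_matrix"))
  out <- names(expr$groups)[expr$groups == group]
  if (length(out) == 0L)
    stop("unknown group: ", group)
  out
}

#' Gene annotation: chromosome, optional cytoband, length and position
#'
#' Validates and normalizes a gene annotation table. Chromosome labels are
#' normalized to `"chr*"` form; genes on chromosomes outside the declared
#' assembly set (e.g. chrY, chrM, scaffolds) are retained but flagged
#' `excluded_from_xa` and never counted as X or autosomal.
#'
#' @param df data.frame with columns `gene_id`, `chromosome` and optionally
#'   `band`, `length_bp`, `start` (0-based).
#' @param assembly `"mouse"` or `"human"`.
#' @return a data.frame of class `gene_annotation` with attribute `assembly`.
#' @export
gene_annotation <- function(df, assembly = c("mouse", "human")) {
  assembly <- match.arg(assembly)
  if (!all(c("gene_id", "chromosome") %in% names(df)))
    stop("annotation needs `gene_id` and `chromosome` columns")
  df$gene_id <- as.character(df$gene_id)
  df$chromosome <- normalize_chromosome(df$chromosome)
  if (is.null(df$band)) df$band <- NA_character_
  if (is.null(df$length_bp)) df$length_bp <- NA_real_
  if (is.null(df$start)) df$start <- NA_real_
  df <- df[, c("gene_id", "chromosome", "band", "length_bp", "start")]
  if (anyDuplicated(df$gene_id)) {
    conflicting <- unique(df$gene_id[duplicated(df$gene_id)])
    chrs <- split(df$chromosome, df$gene_id)[conflicting]
    bad <- conflicting[vapply(chrs, function(z) length(unique(z)) > 1L,
                              logical(1))]
    if (length(bad))
      stop("gene(s) annotated on conflicting chromosomes: ",
           paste(bad, collapse = ", "))
    df <- df[!duplicated(df$gene_id), ]
  }
  universe <- chromosome_set(assembly)
  df$excluded_from_xa <- !(df$chromosome %in% universe)
  rownames(df) <- NULL
  structure(df, class = c("gene_annotation", "data.frame"),
            assembly = assembly)
}

#' Expression-level cutoff ladder
#'
#' The ladders of lower bounds (log2 scale) at which the X:A ratio is
#' re-estimated. `FPKM_default` is `(-Inf, -3, -1, 0.1, 0.5, 1, 2, 3)`;
#' `TMM_default` (for collapsed TMM values, where negative log2 values are
#' 0) is `(0, 1, 3, 5, 7, 9, 11)`.
#'
#' @param name `"FPKM_default"`, `"TMM_default"` or `"custom"`.
#' @param thresholds strictly increasing numeric vector; required when
#'   `name = "custom"`.
#' @param scale scale the thresholds live on (always `"log2"` for the
#'   built-in ladders).
#' @return an object of class `cutoff_scheme`.
#' @export
cutoff_scheme <- function(name = c("FPKM_default", "TMM_default", "custom"),
                          thresholds = NULL, scale = "log2") {
  name <- match.arg(name)
  if (name == "FPKM_default") {
    thresholds <- c(-Inf, -3, -1, 0.1, 0.5, 1, 2, 3)
  } else if (name == "TMM_default") {
    thresholds <- c(0, 1, 3, 5, 7, 9, 11)
  } else if (is.null(thresholds)) {
    stop("custom scheme requires `thresholds`")
  }
  thresholds <- as.numeric(thresholds)
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  structure(list(name = name, thresholds = thresholds, scale = scale),
            class = "cutoff_scheme")
}

#' Analysis configuration
#'
#' Bundles the tunable constants of the whole analysis: bootstrap size
#' (`bootstrap_B` replications of `bootstrap_m` draws per side),
#' confidence level, differential-expression thresholds (p < 0.05 and
#' fold change >= 2), the high-expression floor (10 on the linear
#' normalized scale), the enrichment alpha (0.01), the very-low expression
#' floor (-5 log2), the log2 frequency-bin edges, and the master RNG seed.
#'
#' @param bootstrap_B bootstrap replications (default 2000).
#' @param bootstrap_m values drawn per side per replication (default 100).
#' @param ci_level confidence level of the quantile interval (default 0.95).
#' @param de_p_threshold,de_fc_threshold DE thresholds.
#' @param high_expression_floor linear floor defining "highly expressed".
#' @param enrichment_alpha significance level for enrichment tests.
#' @param very_low_floor log2 floor defining "very low" expression.
#' @param frequency_bin_edges inner log2 bin edges (outermost bins open).
#' @param rng_seed master seed.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(bootstrap_B = 2000L,
                            bootstrap_m = 100L,
                            ci_level = 0.95,
                            de_p_threshold = 0.05,
                            de_fc_threshold = 2,
                            high_expression_floor = 10,
                            enrichment_alpha = 0.01,
                            very_low_floor = -5,
                            frequency_bin_edges = c(-6, -4, -2, 0, 2, 4, 6),
                            rng_seed = 1L) {
  stopifnot(bootstrap_B >= 1, bootstrap_m >= 1,
            ci_level > 0, ci_level < 1,
            de_p_threshold > 0, de_fc_threshold >= 1,
            high_expression_floor > 0, enrichment_alpha > 0)
  structure(
    list(bootstrap_B = as.integer(bootstrap_B),
         bootstrap_m = as.integer(bootstrap_m),
         ci_level = ci_level,
         de_p_threshold = de_p_threshold,
         de_fc_threshold = de_fc_threshold,
         high_expression_floor = high_expression_floor,
         enrichment_alpha = enrichment_alpha,
         very_low_floor = very_low_floor,
         frequency_bin_edges = as.numeric(frequency_bin_edges),
         rng_seed = as.integer(rng_seed)),
    class = "analysis_config"
  )
}
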