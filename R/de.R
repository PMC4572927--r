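#' Two-sample t-test with degenerate-case handling
#'
#' Pooled-variance two-sample t-test by default (Welch by flag), two-sided.
#' When both groups have zero variance the usual statistic is undefined:
#' equal means give `t = 0, p = 1`; unequal means give `p = 0`, flagged
#' degenerate.
#'
#' @param values_a,values_b replicate values (>= 2 each), log2 scale with
#'   the collapse convention applied.
#' @param variant `"pooled"` or `"welch"`.
#' @return list with `t`, `df`, `p_value`, `degenerate`.
#' @export
two_sample_t_test <- function(values_a, values_b,
                              variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  va <- stats::var(values_a)
  vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(t = 0, df = NA_real_, p_value = 1, degenerate = TRUE))
    return(list(t = sign(mean(values_a) - mean(values_b)) * Inf,
                df = NA_real_, p_value = 0, degenerate = TRUE))
  }
  res <- stats::t.test(values_a, values_b,
                       var.equal = (variant == "pooled"))
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, degenerate = FALSE)
}

#' Classify differential expression between two groups
#'
#' Genes expressed in all replicates of at least one group are tested.
#' Fold change is the ratio of the larger to the smaller linear group mean;
#' the p-value is a two-sample t-test on log2 values with the collapse
#' convention (positive values below 1 count as log2 value 0, zeros too).
#' A gene is differentially expressed iff `p < de_p_threshold` and
#' `fold_change >= de_fc_threshold`, and then falls in exactly one
#' half-open fold-change category: slight `[2, 4)`, moderate `[4, 10)`,
#' high `[10, Inf)`. Genes whose larger group mean exceeds
#' `high_expression_floor` (linear) are flagged highly expressed.
#'
#' @param expr a linear-scale [expression_matrix()] of normalized values.
#' @param groups length-2 character vector: the two group labels (A, B).
#' @param config an [analysis_config()].
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @return data.frame of class `de_records` (one row per tested gene:
#'   `gene_id`, `mean_a`, `mean_b`, `fold_change`, `direction`, `p_value`,
#'   `category`, `highly_expressed`) with a `summary` attribute holding the
#'   stage-specific counts.
#' @export
classify_differential <- function(expr, groups, config = analysis_config(),
                                  variant = "pooled") {
  stopifnot(inherits(expr, "expr_matrix"), expr$scale == "linear",
            length(groups) == 2L)
  sa <- samples_in_group(expr, groups[1])
  sb <- samples_in_group(expr, groups[2])
  ga <- filter_expressed_in_all_replicates(expr, groups[1])
  gb <- filter_expressed_in_all_replicates(expr, groups[2])
  genes <- union(ga, gb)
  if (!length(genes)) stop("no gene expressed in all replicates of either group")
  va <- expr$values[genes, sa, drop = FALSE]
  vb <- expr$values[genes, sb, drop = FALSE]
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  hi <- pmax(mean_a, mean_b)
  lo <- pmin(mean_a, mean_b)
  fc <- ifelse(lo == 0, Inf, hi / lo)
  la <- matrix(log2_collapsed(va), nrow = nrow(va))
  lb <- matrix(log2_collapsed(vb), nrow = nrow(vb))
  la[is.na(la)] <- 0  # zeros carry log2 value 0 under the collapse scale
  lb[is.na(lb)] <- 0
  p <- vapply(seq_along(genes), function(i) {
    two_sample_t_test(la[i, ], lb[i, ], variant = variant)$p_value
  }, numeric(1))
  de <- p < config$de_p_threshold & fc >= config$de_fc_threshold
  category <- rep("none", length(genes))
  category[de & fc >= 2 & fc < 4] <- "slight"
  category[de & fc >= 4 & fc < 10] <- "moderate"
  category[de & fc >= 10] <- "high"
  direction <- ifelse(mean_a >= mean_b, "up_in_A", "up_in_B")
  direction[!de] <- "none"
  out <- data.frame(gene_id = genes, mean_a = mean_a, mean_b = mean_b,
                    fold_change = fc, direction = direction,
                    p_value = p, category = category,
                    highly_expressed = hi > config$high_expression_floor,
                    row.names = NULL)
  smry <- list(
    group_a = groups[1], group_b = groups[2],
    n_tested = length(genes),
    n_de = sum(de),
    n_up_in_a = sum(out$direction == "up_in_A"),
    n_up_in_b = sum(out$direction == "up_in_B"),
    n_up_in_a_high_expr = sum(out$direction == "up_in_A" &
                                out$highly_expressed),
    n_up_in_b_high_expr = sum(out$direction == "up_in_B" &
                                out$highly_expressed),
    n_slight = sum(category == "slight"),
    n_moderate = sum(category == "moderate"),
    n_high = sum(category == "high")
  )
  structure(out, class = c("de_records", "data.frame"), summary = smry)
}

#' Per-chromosome concentration of high-fold-change DE genes
#'
#' Among upregulated genes (optionally of one direction), tests each
#' chromosome for excess of the high (>= 10-fold) category relative to the
#' slight + moderate categories: the 2x2 Fisher exact test of (this
#' chromosome vs all others) x (high vs slight + moderate). Significance
#' tiers at the three conventional thresholds 0.01, 0.002 and 4.5e-5 are
#' reported alongside the per-chromosome category composition.
#'
#' Chromosomes with no DE genes are excluded and listed in the
#' `excluded_chromosomes` attribute.
#'
#' @param de_records a [classify_differential()] result.
#' @param annotation a [gene_annotation()].
#' @param alpha base significance level (first tier).
#' @param direction optional `"up_in_A"` or `"up_in_B"` filter.
#' @param tiers decreasing significance thresholds.
#' @return data.frame of class `chromosome_enrichment`: per chromosome the
#'   category counts and fractions, odds ratio, p-value and `tier`
#'   (0 = not significant, 1..3 = tiers passed).
#' @export
chromosome_category_enrichment <- function(de_records, annotation,
                                           alpha = 0.01,
                                           direction = NULL,
                                           tiers = c(0.01, 0.002, 4.5e-5)) {
  stopifnot(inherits(de_records, "de_records"),
            inherits(annotation, "gene_annotation"))
  de <- de_records[de_records$category != "none", ]
  if (!is.null(direction)) de <- de[de$direction == direction, ]
  if (!nrow(de)) stop("no differentially expressed genes")
  chr <- annotation$chromosome[match(de$gene_id, annotation$gene_id)]
  if (anyNA(chr)) stop("annotation does not cover all DE genes")
  universe <- chromosome_set(attr(annotation, "assembly"))
  excluded <- setdiff(universe, unique(chr))
  high <- de$category == "high"
  rows <- lapply(intersect(universe, unique(chr)), function(cc) {
    onc <- chr == cc
    tab <- matrix(c(sum(onc & high), sum(onc & !high),
                    sum(!onc & high), sum(!onc & !high)), 2)
    ft <- fisher_exact_2x2(tab)
    data.frame(chromosome = cc,
               n_de = sum(onc),
               n_slight = sum(onc & de$category == "slight"),
               n_moderate = sum(onc & de$category == "moderate"),
               n_high = sum(onc & high),
               frac_slight = mean(de$category[onc] == "slight"),
               frac_moderate = mean(de$category[onc] == "moderate"),
               frac_high = mean(de$category[onc] == "high"),
               odds_ratio = ft$odds_ratio,
               p_value = ft$p_value,
               tier = sum(ft$p_value < tiers))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("chromosome_enrichment", "data.frame"),
            alpha = alpha, tiers = tiers, direction = direction,
            excluded_chromosomes = excluded)
}
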