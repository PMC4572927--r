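#' Select expression values above a log2 cutoff
#'
#' Keeps values that are strictly positive on the linear scale and whose
#' log2 exceeds the cutoff (strict). `cutoff = -Inf` reduces to the
#' ">0" expressed set: zeros are always excluded.
#'
#' @param values numeric linear-scale expression values.
#' @param cutoff log2 lower bound (`-Inf` allowed).
#' @return the selected values (names kept).
#' @export
select_by_cutoff <- function(values, cutoff) {
  keep <- !is.na(values) & values > 0
  keep[keep] <- log2(values[keep]) > cutoff
  values[keep]
}

#' Bootstrap estimate of the median X:A expression ratio
#'
#' For each of `B` replications, `m` values are drawn from the X-linked
#' pool and `m` from the autosomal pool — without replacement when the pool
#' holds at least `m` values, with replacement otherwise — and the ratio of
#' the two sample medians is formed on the linear scale. The reported
#' estimate is the median of the `B` ratios; the confidence interval is the
#' pair of empirical `alpha/2` and `1 - alpha/2` quantiles. Draws are made
#' from the sorted value multiset, so permuting gene order never changes
#' the result under a fixed seed.
#'
#' Replications whose autosomal median is 0 are discarded and counted; a
#' warning is raised when more than 1% are discarded, an error when all are.
#'
#' @param x_values linear expression of X-linked genes (non-empty).
#' @param a_values linear expression of autosomal genes (non-empty).
#' @param config an [analysis_config()] supplying `bootstrap_B`,
#'   `bootstrap_m`, `ci_level` and `rng_seed`.
#' @return an object of class `xa_ratio_result`: `median_ratio`, `ci_low`,
#'   `ci_high`, `n_x`, `n_a`, `B`, `m`, `seed`, the replacement flags and
#'   the discard count.
#' @export
bootstrap_xa_ratio <- function(x_values, a_values,
                               config = analysis_config()) {
  stopifnot(length(x_values) >= 1L, length(a_values) >= 1L,
            inherits(config, "analysis_config"))
  B <- config$bootstrap_B
  m <- config$bootstrap_m
  xs <- sort(as.numeric(x_values))
  as_ <- sort(as.numeric(a_values))
  nx <- length(xs); na_ <- length(as_)
  rep_x <- nx < m; rep_a <- na_ < m
  r <- numeric(B)
  with_seed(config$rng_seed, {
    for (b in seq_len(B)) {
      mx <- stats::median(xs[sample.int(nx, m, replace = rep_x)])
      ma <- stats::median(as_[sample.int(na_, m, replace = rep_a)])
      r[b] <- if (ma == 0) NA_real_ else mx / ma
    }
  })
  discarded <- sum(is.na(r))
  if (discarded == B)
    stop("all bootstrap replications had autosomal median 0")
  if (discarded > 0.01 * B)
    warning(sprintf("%d of %d bootstrap replications discarded (autosomal median 0)",
                    discarded, B))
  r <- r[!is.na(r)]
  alpha <- 1 - config$ci_level
  q <- stats::quantile(r, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(
    list(median_ratio = stats::median(r),
         ci_low = q[1], ci_high = q[2],
         n_x = nx, n_a = na_, B = B, m = m,
         seed = config$rng_seed,
         with_replacement_x = rep_x, with_replacement_a = rep_a,
         n_discarded = discarded),
    class = "xa_ratio_result"
  )
}

#' @export
print.xa_ratio_result <- function(x, ...) {
  cat(sprintf("X:A median ratio %.4g [%.4g, %.4g] (n_X=%d, n_A=%d, B=%d, m=%d)\n",
              x$median_ratio, x$ci_low, x$ci_high, x$n_x, x$n_a, x$B, x$m))
  invisible(x)
}

#' Bootstrap X:A ratio across a cutoff ladder
#'
#' Runs [bootstrap_xa_ratio()] once per cutoff of the scheme, on the genes
#' passing that cutoff. X pool = genes on chrX; autosomal pool = genes on
#' the assembly's autosomes (genes flagged excluded never enter). Per-cutoff
#' seeds are the master seed plus the cutoff index, so every cutoff is
#' independently re-runnable.
#'
#' A cutoff leaving either pool empty yields a row flagged
#' `available = FALSE` rather than being skipped.
#'
#' @param values named numeric vector of averaged per-gene linear
#'   expression.
#' @param annotation a [gene_annotation()] covering the genes.
#' @param scheme a [cutoff_scheme()].
#' @param config an [analysis_config()].
#' @return data.frame of class `xa_ratio_curve`: one row per cutoff with
#'   `cutoff`, `median_ratio`, `ci_low`, `ci_high`, `n_x`, `n_a`, `seed`,
#'   `available`.
#' @export
xa_ratio_curve <- function(values, annotation, scheme = cutoff_scheme(),
                           config = analysis_config()) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(scheme, "cutoff_scheme"),
            !is.null(names(values)))
  ann <- annotation[match(names(values), annotation$gene_id), ]
  if (anyNA(ann$gene_id)) stop("annotation does not cover all genes")
  x_pool <- values[ann$chromosome == "chrX" & !ann$excluded_from_xa]
  a_pool <- values[ann$chromosome != "chrX" & !ann$excluded_from_xa]
  rows <- lapply(seq_along(scheme$thresholds), function(i) {
    t <- scheme$thresholds[i]
    xi <- select_by_cutoff(x_pool, t)
    ai <- select_by_cutoff(a_pool, t)
    seed_i <- config$rng_seed + i
    if (!length(xi) || !length(ai)) {
      return(data.frame(cutoff = t, median_ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_x = length(xi), n_a = length(ai),
                        seed = seed_i, available = FALSE))
    }
    cfg_i <- config
    cfg_i$rng_seed <- seed_i
    res <- bootstrap_xa_ratio(xi, ai, cfg_i)
    data.frame(cutoff = t, median_ratio = res$median_ratio,
               ci_low = res$ci_low, ci_high = res$ci_high,
               n_x = res$n_x, n_a = res$n_a,
               seed = seed_i, available = TRUE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("xa_ratio_curve", "data.frame"),
            B = config$bootstrap_B, m = config$bootstrap_m,
            ci_level = config$ci_level, master_seed = config$rng_seed)
}

#' Median X:chromosome expression ratios per autosome and cutoff
#'
#' For each autosome `c` and cutoff `t`: `median(X genes passing t) /
#' median(genes of c passing t)` on the linear scale, with no resampling;
#' plus the per-cutoff arithmetic mean over autosomes ("Ave" row). Cells
#' where the autosome has no genes passing are `NA` and excluded from the
#' average.
#'
#' @inheritParams xa_ratio_curve
#' @return data.frame of class `chromosome_ratio_matrix`: one row per
#'   autosome plus an `"Ave"` row; one column per cutoff.
#' @export
per_chromosome_median_ratios <- function(values, annotation,
                                         scheme = cutoff_scheme()) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(scheme, "cutoff_scheme"))
  ann <- annotation[match(names(values), annotation$gene_id), ]
  if (anyNA(ann$gene_id)) stop("annotation does not cover all genes")
  assembly <- attr(annotation, "assembly")
  autosomes <- chromosome_set(assembly, autosomes_only = TRUE)
  x_pool <- values[ann$chromosome == "chrX" & !ann$excluded_from_xa]
  cells <- sapply(scheme$thresholds, function(t) {
    xs <- select_by_cutoff(x_pool, t)
    xm <- if (length(xs)) stats::median(xs) else NA_real_
    vapply(autosomes, function(chr) {
      ci <- select_by_cutoff(values[ann$chromosome == chr], t)
      if (!length(ci) || is.na(xm)) NA_real_
      else xm / stats::median(ci)
    }, numeric(1))
  })
  cells <- matrix(cells, nrow = length(autosomes),
                  dimnames = list(autosomes,
                                  paste0(">", scheme$thresholds)))
  ave <- colMeans(cells, na.rm = TRUE)
  out <- data.frame(chromosome = c(autosomes, "Ave"),
                    rbind(cells, Ave = ave),
                    check.names = FALSE, row.names = NULL)
  structure(out, class = c("chromosome_ratio_matrix", "data.frame"),
            assembly = assembly, n_x = length(x_pool))
}
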