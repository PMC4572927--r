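#' FPKM from counts, gene lengths and library sizes
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length[g] * library_size[s])`:
#' fragments per kilobase of gene per million mapped fragments. The
#' library size defaults to the column sum of assigned fragments.
#'
#' @param counts genes x samples count matrix (rownames, colnames set).
#' @param lengths per-gene length in bp (named or in row order).
#' @param library_sizes per-sample totals; default `colSums(counts)`.
#' @param groups optional sample -> group map, passed through.
#' @return an [expression_matrix()] (FPKM, linear).
#' @export
compute_fpkm <- function(counts, lengths, library_sizes = colSums(counts),
                         groups = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("every gene needs a positive length")
  if (any(library_sizes <= 0))
    stop("every sample needs a positive library size")
  fpkm <- counts * 1e9 / outer(as.numeric(lengths),
                               as.numeric(library_sizes))
  dimnames(fpkm) <- dimnames(counts)
  expression_matrix(fpkm, scale = "linear", normalization = "FPKM",
                    groups = groups)
}

# One sample vs the reference: doubly trimmed, precision-weighted mean of
# M-values (log2 ratios of library-size-scaled proportions).
.tmm_pair <- function(x, r, Nx, Nr, trim_M, trim_A) {
  keep <- x > 0 & r > 0
  x <- x[keep]; r <- r[keep]
  if (!length(x)) stop("degenerate input: no gene expressed in both samples")
  M <- log2((x / Nx) / (r / Nr))
  A <- 0.5 * log2((x / Nx) * (r / Nr))
  # asymptotic variance of M (delta method) -> precision weights
  v <- (Nx - x) / (Nx * x) + (Nr - r) / (Nr * r)
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) stop("degenerate input: no genes survive TMM trimming")
  f <- sum(M[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f) || abs(f) < 1e-6) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' For each sample against a reference: genes with a zero count in either
#' sample are excluded; `M` is the log2 ratio of library-size-scaled
#' proportions and `A` the average log2 proportion; the gene set is doubly
#' trimmed (30% of M, 5% of A, both two-sided) and the factor is 2 to the
#' precision-weighted mean of the remaining M-values. Factors are rescaled
#' to geometric mean 1. The reference defaults to the sample whose
#' upper-quartile count fraction is closest to the mean upper-quartile
#' fraction.
#'
#' @param counts genes x samples count matrix (>= 2 samples).
#' @param reference optional reference sample id or index.
#' @param trim_M,trim_A two-sided trim fractions (published defaults 0.30
#'   and 0.05).
#' @return an object of class `tmm_factors`: named `factors`, the
#'   `reference` sample id, and the trim fractions.
#' @export
compute_tmm_factors <- function(counts, reference = NULL,
                                trim_M = 0.30, trim_A = 0.05) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2L,
            !is.null(colnames(counts)))
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample needs >= 1 nonzero gene")
  if (is.null(reference)) {
    f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(reference)) match(reference, colnames(counts))
           else as.integer(reference)
    if (is.na(ref) || ref < 1L || ref > ncol(counts))
      stop("unknown reference sample")
  }
  fac <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_M, trim_A)
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  structure(list(factors = stats::setNames(fac, colnames(counts)),
                 reference = colnames(counts)[ref],
                 trim_M = trim_M, trim_A = trim_A),
            class = "tmm_factors")
}

#' Apply TMM factors to counts
#'
#' Normalized value = count / (library_size * factor), scaled to counts per
#' million. With `output = "log2"` and `collapse_negative_log = TRUE`,
#' positive values below 1 (negative log2) are collapsed to log2 value 0 —
#' the convention of the toolchain era in which TMM ladders start at 0.
#' Zeros remain not-expressed (`NA` on the log2 scale).
#'
#' @param counts genes x samples count matrix.
#' @param factors a [compute_tmm_factors()] result.
#' @param collapse_negative_log collapse (0,1) values to log2 0 (log2
#'   output only).
#' @param output `"linear"` or `"log2"`.
#' @param groups optional sample -> group map.
#' @return an [expression_matrix()] (TMM).
#' @export
apply_tmm <- function(counts, factors, collapse_negative_log = FALSE,
                      output = c("linear", "log2"), groups = NULL) {
  output <- match.arg(output)
  stopifnot(inherits(factors, "tmm_factors"))
  f <- factors$factors
  if (ncol(counts) != length(f) ||
      !all(colnames(counts) %in% names(f)))
    stop("factor/sample mismatch")
  f <- f[colnames(counts)]
  lib <- colSums(counts)
  cpm <- sweep(counts, 2, lib * f, `/`) * 1e6
  if (output == "linear")
    return(expression_matrix(cpm, scale = "linear", normalization = "TMM",
                             groups = groups))
  l <- cpm
  l[cpm == 0] <- NA_real_
  pos <- cpm > 0
  l[pos] <- log2(cpm[pos])
  if (collapse_negative_log) l[pos & cpm < 1] <- 0
  expression_matrix(l, scale = "log2", normalization = "TMM",
                    groups = groups)
}

#' Genes expressed in every replicate of a group
#'
#' "Expressed" means strictly positive on the linear scale. This is the
#' replicate filter applied before averaging and all downstream X:A
#' analyses.
#'
#' @param expr a linear-scale [expression_matrix()].
#' @param group group label.
#' @return character vector of gene ids.
#' @export
filter_expressed_in_all_replicates <- function(expr, group) {
  stopifnot(inherits(expr, "expr_matrix"), expr$scale == "linear")
  s <- samples_in_group(expr, group)
  v <- expr$values[, s, drop = FALSE]
  rownames(v)[rowSums(v > 0) == length(s)]
}

#' Average replicate values of a group on the linear scale
#'
#' Arithmetic mean of linear-scale values per gene (log2 is applied after
#' averaging where needed; the two orders differ and the linear order is
#' the one used throughout).
#'
#' @param expr a linear-scale [expression_matrix()].
#' @param group group label.
#' @param genes optional gene subset (e.g. from
#'   [filter_expressed_in_all_replicates()]).
#' @return named numeric vector of per-gene means.
#' @export
average_replicates <- function(expr, group, genes = NULL) {
  stopifnot(inherits(expr, "expr_matrix"), expr$scale == "linear")
  s <- samples_in_group(expr, group)
  v <- expr$values[, s, drop = FALSE]
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) stop("unknown gene(s): ",
                              paste(utils::head(missing, 3), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  rowMeans(v)
}
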