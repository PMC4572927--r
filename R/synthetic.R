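#' Synthetic-data generator configuration
#'
#' Parameters of the generative model that stands in for oocyte RNA-seq
#' data. Autosomal genes draw a true log2 expression from
#' `Normal(mu_A, sigma_A^2)`. X-linked genes draw from the two-component
#' mixture `(1 - pi_low) * Normal(mu_A + delta, sigma_X^2) +
#' pi_low * Normal(mu_low, sigma_low^2)`: `delta` is the X dosage shift in
#' log2 units (true linear dosage ratio `2^delta`) and `pi_low` the
#' fraction of X genes in the very-low (silenced) mode. Replicate values
#' add `Normal(0, sigma_rep^2)` noise and are zeroed ("dropout") with
#' probability `dropout`.
#'
#' @param n_autosomal,n_x gene counts (defaults 20000 and 1000).
#' @param n_autosomes 19 (mouse) or 22 (human).
#' @param replicates replicate samples per group (default 3).
#' @param mu_A,sigma_A autosomal log2 mean and sd.
#' @param delta X dosage shift (log2).
#' @param pi_low fraction of X genes in the very-low mode.
#' @param mu_low,sigma_low very-low mode mean and sd (log2).
#' @param sigma_X X main-mode sd; defaults to `sigma_A`.
#' @param sigma_rep replicate noise sd (log2).
#' @param dropout per-gene-per-replicate zeroing probability.
#' @param band_bias probability that a very-low-mode X gene falls in the two
#'   target cytobands (qA2, qA3.1); 0.2 is the uniform (neutral) value for
#'   the 10 synthetic bands.
#' @param count_layer `NULL`, or `list(dispersion =, depth =)` enabling the
#'   negative-binomial count layer.
#' @param seed RNG seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_autosomal = 20000L, n_x = 1000L,
                             n_autosomes = 19L, replicates = 3L,
                             mu_A = 3, sigma_A = 2,
                             delta = 0, pi_low = 0,
                             mu_low = -6, sigma_low = 1,
                             sigma_X = NULL,
                             sigma_rep = 0.25, dropout = 0.05,
                             band_bias = 0.2,
                             count_layer = NULL,
                             seed = 1L) {
  sigma_X <- sigma_X %||% sigma_A
  stopifnot(n_autosomal >= 1, n_x >= 1, replicates >= 1,
            n_autosomes %in% c(19L, 22L),
            pi_low >= 0, pi_low <= 1,
            sigma_A > 0, sigma_X > 0, sigma_low > 0, sigma_rep >= 0,
            dropout >= 0, dropout <= 1,
            band_bias >= 0, band_bias <= 1)
  if (!is.null(count_layer)) {
    count_layer$dispersion <- count_layer$dispersion %||% 0.1
    count_layer$depth <- count_layer$depth %||% 1
    stopifnot(count_layer$dispersion >= 0, count_layer$depth > 0)
  }
  structure(
    list(n_autosomal = as.integer(n_autosomal), n_x = as.integer(n_x),
         n_autosomes = as.integer(n_autosomes),
         replicates = as.integer(replicates),
         mu_A = mu_A, sigma_A = sigma_A, delta = delta, pi_low = pi_low,
         mu_low = mu_low, sigma_low = sigma_low, sigma_X = sigma_X,
         sigma_rep = sigma_rep, dropout = dropout, band_bias = band_bias,
         count_layer = count_layer, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Preset generator configurations for the regimes the analysis distinguishes
#'
#' * `null` — X and autosomal genes share one distribution (`delta = 0`,
#'   `pi_low = 0`): the no-dosage-difference reference.
#' * `ngo` — nongrowing-oocyte-like: matched X/A distributions with a
#'   negligible silenced fraction (`delta = 0`, `pi_low = 0.02`).
#' * `fgo` — fully-grown-oocyte-like: bimodal X expression with a
#'   substantial very-low mode (`delta = -0.4`, `pi_low = 0.30`,
#'   `mu_low = -6`).
#' * `mii` — mouse ovulated-oocyte-like (`delta = -0.5`, `pi_low = 0.25`).
#' * `human_mii` — human-oocyte-like skew: no second mode, a negative mean
#'   shift plus inflated variance (`delta = -0.35`, `pi_low = 0`,
#'   `sigma_X = 1.1 * sigma_A`, 22 autosomes).
#'
#' Shared defaults: `mu_A = 3`, `sigma_A = 2`, `sigma_rep = 0.25`,
#' `dropout = 0.05`, 20000 autosomal and 1000 X genes, 3 replicates.
#'
#' @param name preset name.
#' @param seed RNG seed stored in the config.
#' @param ... overrides passed to [synthetic_config()].
#' @return a [synthetic_config()] with attribute `preset`.
#' @export
build_preset <- function(name = c("null", "ngo", "fgo", "mii", "human_mii"),
                         seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    null = list(delta = 0, pi_low = 0),
    ngo = list(delta = 0, pi_low = 0.02),
    fgo = list(delta = -0.4, pi_low = 0.30, mu_low = -6),
    mii = list(delta = -0.5, pi_low = 0.25, mu_low = -6),
    human_mii = list(delta = -0.35, pi_low = 0, sigma_X = 1.1 * 2,
                     n_autosomes = 22L)
  )
  dots <- list(...)
  args[names(dots)] <- dots
  args$seed <- seed
  cfg <- do.call(synthetic_config, args)
  attr(cfg, "preset") <- name
  cfg
}

# Synthetic X cytobands: 10 equal-width bands; very-low-mode genes land in
# the two target bands with probability band_bias (0.2 = uniform).
.x_band_names <- c("qA1", "qA1.1", "qA2", "qA3.1", "qA3.2", "qA3.3",
                   "qB", "qC1", "qC3", "qD")
.x_target_bands <- c("qA2", "qA3.1")
.x_chrom_length <- 1.7e8

# Draw per-gene truth: ids, chromosomes, bands, starts, log2 truth, mode.
.simulate_genes <- function(config) {
  nA <- config$n_autosomal
  nX <- config$n_x
  autosomes <- paste0("chr", seq_len(config$n_autosomes))
  gene_id <- c(sprintf("geneA%05d", seq_len(nA)),
               sprintf("geneX%04d", seq_len(nX)))
  chromosome <- c(sample(autosomes, nA, replace = TRUE),
                  rep("chrX", nX))
  truth_A <- stats::rnorm(nA, config$mu_A, config$sigma_A)
  low <- stats::runif(nX) < config$pi_low
  truth_X <- ifelse(low,
                    stats::rnorm(nX, config$mu_low, config$sigma_low),
                    stats::rnorm(nX, config$mu_A + config$delta,
                                 config$sigma_X))
  mode <- c(rep("autosomal", nA), ifelse(low, "very-low", "main"))
  # band assignment, then a start coordinate consistent with the band
  n_bands <- length(.x_band_names)
  target_idx <- match(.x_target_bands, .x_band_names)
  other_idx <- setdiff(seq_len(n_bands), target_idx)
  # very-low genes: target bands with total probability band_bias (0.2 =
  # uniform, since the targets are 2 of 10 bands); others uniform
  in_target <- stats::runif(nX) < config$band_bias
  band_idx <- ifelse(in_target,
                     sample(target_idx, nX, replace = TRUE),
                     sample(other_idx, nX, replace = TRUE))
  # non-low genes: uniform over all bands regardless of bias
  uni <- sample(seq_len(n_bands), nX, replace = TRUE)
  band_idx[!low] <- uni[!low]
  width <- .x_chrom_length / n_bands
  start_X <- (band_idx - 1) * width + floor(stats::runif(nX) * width)
  start_A <- floor(stats::runif(nA) * 1.5e8)
  data.frame(gene_id = gene_id, chromosome = chromosome,
             band = c(rep(NA_character_, nA), .x_band_names[band_idx]),
             start = c(start_A, start_X),
             log2_truth = c(truth_A, truth_X),
             mode = mode, stringsAsFactors = FALSE)
}

#' Simulate an expression dataset with recorded ground truth
#'
#' Draws per-gene true log2 expression under the configured model, adds
#' replicate noise and dropout, and emits a linear-scale
#' [expression_matrix()] (zeros at dropouts), a [gene_annotation()] with
#' synthetic X cytobands, and a `synthetic_truth` object holding the
#' per-gene truth and the generating parameters. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param group_labels character vector of group names; each group gets
#'   `config$replicates` columns with independent replicate noise over the
#'   same per-gene truth. Defaults to the preset name (or `"G1"`).
#' @return `list(expression =, annotation =, truth =)`.
#' @export
simulate_dataset <- function(config, group_labels = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  group_labels <- group_labels %||% attr(config, "preset") %||% "G1"
  with_seed(config$seed, {
    genes <- .simulate_genes(config)
    n <- nrow(genes)
    cols <- list()
    for (g in group_labels) {
      for (r in seq_len(config$replicates)) {
        obs <- genes$log2_truth + stats::rnorm(n, 0, config$sigma_rep)
        v <- 2^obs
        v[stats::runif(n) < config$dropout] <- 0
        cols[[paste0(g, "_r", r)]] <- v
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes$gene_id
    groups <- stats::setNames(rep(group_labels, each = config$replicates),
                              colnames(values))
    expr <- expression_matrix(values, scale = "linear",
                              normalization = "FPKM", groups = groups)
    ann <- gene_annotation(
      genes[, c("gene_id", "chromosome", "band", "start")],
      assembly = if (config$n_autosomes == 19L) "mouse" else "human")
    truth <- structure(
      list(genes = genes, delta = config$delta, pi_low = config$pi_low,
           config = config),
      class = "synthetic_truth")
    list(expression = expr, annotation = ann, truth = truth)
  })
}

#' True X:A ratio of a simulated dataset at given cutoffs
#'
#' The ratio of the median linear true expression of X genes to that of
#' autosomal genes, among genes whose true log2 expression exceeds each
#' cutoff. `NA` where either side is empty.
#'
#' @param truth a `synthetic_truth` from [simulate_dataset()].
#' @param cutoffs numeric log2 lower bounds (`-Inf` allowed).
#' @return named numeric vector, one ratio per cutoff.
#' @export
true_xa_ratio <- function(truth, cutoffs = -Inf) {
  stopifnot(inherits(truth, "synthetic_truth"))
  g <- truth$genes
  x <- g$log2_truth[g$chromosome == "chrX"]
  a <- g$log2_truth[g$chromosome != "chrX"]
  out <- vapply(cutoffs, function(t) {
    xi <- x[x > t]; ai <- a[a > t]
    if (!length(xi) || !length(ai)) return(NA_real_)
    stats::median(2^xi) / stats::median(2^ai)
  }, numeric(1))
  names(out) <- as.character(cutoffs)
  out
}

#' Simulate a negative-binomial count layer
#'
#' Draws gene lengths `LogNormal(log 1500, 0.5)` bp and, per replicate,
#' counts `NegBin(mu = length/1000 * 2^truth * depth, dispersion)` over the
#' same per-gene truth as [simulate_dataset()] (same seed, same genes).
#' `dispersion = 0` gives the Poisson limit.
#'
#' @param config a [synthetic_config()] with `count_layer` set.
#' @param group_labels as in [simulate_dataset()].
#' @return `list(counts =, lengths =, annotation =, truth =)`.
#' @export
simulate_counts <- function(config, group_labels = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$count_layer))
    stop("count_layer is off; set count_layer = list(dispersion =, depth =)")
  depth <- config$count_layer$depth
  disp <- config$count_layer$dispersion
  group_labels <- group_labels %||% attr(config, "preset") %||% "G1"
  with_seed(config$seed, {
    genes <- .simulate_genes(config)
    n <- nrow(genes)
    lengths <- stats::setNames(stats::rlnorm(n, log(1500), 0.5),
                               genes$gene_id)
    cols <- list()
    for (g in group_labels) {
      for (r in seq_len(config$replicates)) {
        mu <- lengths / 1000 * 2^genes$log2_truth * depth
        cols[[paste0(g, "_r", r)]] <-
          if (disp == 0) stats::rpois(n, mu)
          else stats::rnbinom(n, size = 1 / disp, mu = mu)
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- genes$gene_id
    ann <- gene_annotation(
      genes[, c("gene_id", "chromosome", "band", "start")],
      assembly = if (config$n_autosomes == 19L) "mouse" else "human")
    truth <- structure(
      list(genes = genes, delta = config$delta, pi_low = config$pi_low,
           config = config),
      class = "synthetic_truth")
    list(counts = counts, lengths = lengths, annotation = ann, truth = truth)
  })
}
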