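# Small in-code fixtures shared across test files.

make_expr <- function(values, genes = NULL, samples = NULL,
                      groups = NULL, ...) {
  genes <- genes %||% rownames(values) %||%
    sprintf("g%02d", seq_len(nrow(values)))
  samples <- samples %||% colnames(values) %||%
    sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, groups = groups, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal mouse annotation for a named value vector: X genes are the ids
# matching `x_pattern`, the rest spread over chr1..chr19.
make_annotation <- function(gene_ids, x_pattern = "^geneX|^x",
                            assembly = "mouse", bands = NULL) {
  is_x <- grepl(x_pattern, gene_ids)
  n_auto <- if (assembly == "mouse") 19L else 22L
  chrom <- ifelse(is_x, "chrX",
                  paste0("chr", (seq_along(gene_ids) %% n_auto) + 1L))
  df <- data.frame(gene_id = gene_ids, chromosome = chrom,
                   stringsAsFactors = FALSE)
  if (!is.null(bands)) df$band <- ifelse(is_x, bands, NA_character_)
  gene_annotation(df, assembly = assembly)
}

# Independent step-by-step TMM recomputation (spreadsheet style): explicit
# sort/order operations, no shared code with the implementation.
tmm_oracle_pair <- function(obs, ref, N_obs, N_ref,
                            trim_M = 0.30, trim_A = 0.05) {
  both <- which(obs > 0 & ref > 0)
  p_o <- obs[both] / N_obs
  p_r <- ref[both] / N_ref
  M <- log2(p_o) - log2(p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  w <- (N_obs - obs[both]) / (N_obs * obs[both]) +
    (N_ref - ref[both]) / (N_ref * ref[both])
  n <- length(M)
  lo_m <- floor(n * trim_M) + 1
  lo_a <- floor(n * trim_A) + 1
  ord_m <- order(M)
  keep_m <- rep(FALSE, n)
  keep_m[ord_m[lo_m:(n + 1 - lo_m)]] <- TRUE
  ord_a <- order(A)
  keep_a <- rep(FALSE, n)
  keep_a[ord_a[lo_a:(n + 1 - lo_a)]] <- TRUE
  keep <- keep_m & keep_a
  f <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
  if (abs(f) < 1e-6) f <- 0
  2^f
}

# Exhaustive two-sided Fisher p for one table, via binomial coefficients
# only (independent of dhyper).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  support <- max(0, k - r2):min(k, r1)
  lp <- lchoose(r1, support) + lchoose(r2, k - support) - lchoose(n, k)
  p <- exp(lp)
  p_obs <- p[match(a, support)]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Exact two-sample KS p by exhaustive label-permutation enumeration.
ks_perm_oracle <- function(s1, s2) {
  pool <- c(s1, s2)
  n1 <- length(s1); n2 <- length(s2)
  ks_d <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(g) - ecdf(b)(g)))
  }
  d_obs <- ks_d(s1, s2)
  picks <- utils::combn(n1 + n2, n1)
  ds <- apply(picks, 2, function(idx) ks_d(pool[idx], pool[-idx]))
  list(D = d_obs, p = mean(ds >= d_obs - 1e-12))
}
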