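test_that("t-test handles identical, degenerate and textbook cases", {
  r <- two_sample_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(r$t, 0)
  expect_identical(r$p_value, 1)
  d <- two_sample_t_test(c(0, 0, 0), c(5, 5, 5))
  expect_true(d$degenerate)
  expect_identical(d$p_value, 0)
  e <- two_sample_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_identical(e$p_value, 1)
  # direct textbook-formula recomputation (pooled and Welch)
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3, 0.5)
    sp2 <- (2 * var(a) + 2 * var(b)) / 4
    t_pool <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
    p_pool <- 2 * pt(-abs(t_pool), df = 4)
    r1 <- two_sample_t_test(a, b, variant = "pooled")
    expect_equal(r1$t, t_pool, tolerance = 1e-10)
    expect_equal(r1$p_value, p_pool, tolerance = 1e-10)
    se_w <- sqrt(var(a) / 3 + var(b) / 3)
    df_w <- se_w^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
    p_w <- 2 * pt(-abs((mean(a) - mean(b)) / se_w), df = df_w)
    expect_equal(two_sample_t_test(a, b, "welch")$p_value, p_w,
                 tolerance = 1e-10)
  }
})

# fixture with planted fold changes and hand-computed categories
make_de_fixture <- function() {
  planted <- c(1, 2.5, 5, 12, 60, 3, 1.2, 25)  # fold up in B per gene
  n <- length(planted)
  base <- c(4, 4, 8, 2, 1.5, 0.02, 6, 20)
  a <- matrix(rep(base, 3), n, 3) * matrix(2^rnorm(n * 3, 0, 0.05), n, 3)
  b <- a * planted
  v <- cbind(a, b)
  dimnames(v) <- list(sprintf("g%02d", seq_len(n)),
                      c(paste0("A_r", 1:3), paste0("B_r", 1:3)))
  make_expr(v, genes = rownames(v),
            groups = stats::setNames(rep(c("A", "B"), each = 3),
                                     colnames(v)))
}

test_that("fold-change categories match hand-enumerated truth", {
  set.seed(5)
  expr <- make_de_fixture()
  de <- classify_differential(expr, c("A", "B"))
  rec <- function(g) de[de$gene_id == g, ]
  # planted folds: 1 (none), 2.5 (slight), 5 (moderate), 12 (high),
  # 60 (high), 3 on a sub-collapse baseline (p fails: collapsed log2
  # values are all 0), 1.2 (none), 25 (high)
  expect_identical(rec("g01")$category, "none")
  expect_identical(rec("g02")$category, "slight")
  expect_identical(rec("g03")$category, "moderate")
  expect_identical(rec("g04")$category, "high")
  expect_identical(rec("g05")$category, "high")
  expect_identical(rec("g06")$category, "none")  # fc ok, collapsed p = 1
  expect_identical(rec("g07")$category, "none")  # fc < 2
  expect_identical(rec("g08")$category, "high")
  expect_true(all(de$direction[de$category != "none"] == "up_in_B"))
  expect_identical(attr(de, "summary")$n_de, 5L)
  expect_identical(attr(de, "summary")$n_high, 3L)
  # every DE gene has exactly one category; boundaries are half-open
  expect_true(all(de$fold_change[de$category == "slight"] >= 2 &
                    de$fold_change[de$category == "slight"] < 4))
  expect_true(all(de$fold_change[de$category == "high"] >= 10))
})

test_that("classification is symmetric under swapping the groups", {
  set.seed(7)
  expr <- make_de_fixture()
  ab <- classify_differential(expr, c("A", "B"))
  ba <- classify_differential(expr, c("B", "A"))
  ba <- ba[match(ab$gene_id, ba$gene_id), ]
  expect_equal(ab$fold_change, ba$fold_change)
  expect_equal(ab$p_value, ba$p_value)
  expect_identical(ab$category, ba$category)
  swap <- c(up_in_A = "up_in_B", up_in_B = "up_in_A", none = "none")
  expect_identical(unname(swap[ab$direction]), ba$direction)
})

test_that("a gene failing p or fold thresholds is never called", {
  # fc = 12 but huge within-group spread -> p >> 0.05
  v <- rbind(g1 = c(1, 90, 2, 300, 3, 1100))
  colnames(v) <- c(paste0("A_r", 1:3), paste0("B_r", 1:3))
  expr <- make_expr(v, genes = "g1",
                    groups = stats::setNames(rep(c("A", "B"), each = 3),
                                             colnames(v)))
  de <- classify_differential(expr, c("A", "B"))
  expect_gte(de$p_value, 0.05)
  expect_identical(de$category, "none")
})

test_that("null data with 3 replicates yields a DE rate below 5 percent", {
  sim <- simulate_dataset(
    synthetic_config(n_autosomal = 3000, n_x = 200, seed = 91),
    group_labels = c("A", "B"))  # same truth, independent replicate noise
  de <- classify_differential(sim$expression, c("A", "B"))
  rate <- attr(de, "summary")$n_de / attr(de, "summary")$n_tested
  expect_lt(rate, 0.05)
})

test_that("chromosome enrichment flags a planted excess of high-fold genes on X", {
  set.seed(97)
  n <- 600
  genes <- sprintf("g%03d", 1:n)
  chrom <- c(rep("chrX", 100), paste0("chr", rep(1:19, length.out = n - 100)))
  ann <- gene_annotation(data.frame(gene_id = genes, chromosome = chrom),
                         "mouse")
  # categories independent of chromosome except X gets 3x the high rate
  category <- ifelse(runif(n) < ifelse(chrom == "chrX", 0.6, 0.2),
                     "high", sample(c("slight", "moderate"), n, TRUE))
  de <- structure(
    data.frame(gene_id = genes, mean_a = 1, mean_b = 4, fold_change = 4,
               direction = "up_in_B", p_value = 0.01, category = category,
               highly_expressed = TRUE),
    class = c("de_records", "data.frame"))
  enr <- chromosome_category_enrichment(de, ann)
  x <- enr[enr$chromosome == "chrX", ]
  expect_gte(x$tier, 1L)
  expect_gt(x$odds_ratio, 1)
  # composition fractions sum to 1 per chromosome
  sums <- enr$frac_slight + enr$frac_moderate + enr$frac_high
  expect_equal(sums, rep(1, nrow(enr)))
})

test_that("chromosome enrichment stays quiet when categories are independent of chromosome", {
  set.seed(101)
  flagged <- vapply(1:10, function(i) {
    n <- 500
    genes <- sprintf("g%03d", 1:n)
    chrom <- sample(c(paste0("chr", 1:19), "chrX"), n, TRUE)
    category <- sample(c("slight", "moderate", "high"), n, TRUE,
                       prob = c(0.4, 0.4, 0.2))
    de <- structure(
      data.frame(gene_id = genes, mean_a = 1, mean_b = 4, fold_change = 4,
                 direction = "up_in_B", p_value = 0.01, category = category,
                 highly_expressed = TRUE),
      class = c("de_records", "data.frame"))
    any(chromosome_category_enrichment(de, gene_annotation(
      data.frame(gene_id = genes, chromosome = chrom), "mouse"))$tier >= 1)
  }, logical(1))
  expect_lte(sum(flagged), 3)
})
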