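test_that("Fisher exact p follows the probability-mass rule", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  r <- fisher_exact_2x2(matrix(c(2, 8, 8, 2), 2))
  expect_equal(r$p_value, fisher_oracle(2, 8, 8, 2), tolerance = 1e-12)
  expect_equal(r$p_value, 0.023, tolerance = 1e-2)
  expect_identical(r$odds_ratio, (2 * 2) / (8 * 8))
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")
  expect_error(fisher_exact_2x2(matrix(c(0.5, 1, 1, 1), 2)), "integer")
})

test_that("Fisher p matches enumeration and fisher.test over many tables", {
  set.seed(6)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(2, 8, 20), 1)), 2)
    if (sum(tab) == 0) next
    mine <- fisher_exact_2x2(tab)$p_value
    expect_equal(mine, fisher_oracle(tab[1, 1], tab[1, 2],
                                     tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
    expect_equal(mine, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    # transposition invariance
    expect_equal(mine, fisher_exact_2x2(t(tab))$p_value, tolerance = 1e-12)
    expect_true(mine > 0 && mine <= 1)
  }
})

test_that("two-sample KS statistic and small-n exact p match permutation enumeration", {
  r0 <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_identical(r0$statistic, 0)
  expect_identical(r0$p_value, 1)
  r1 <- ks_two_sample(c(1, 2, 3), c(4, 5, 6), method = "exact-small-n")
  expect_identical(r1$statistic, 1)
  expect_equal(r1$p_value, 0.1)  # 2 of the 20 label assignments reach D >= 1
  set.seed(17)
  for (i in 1:15) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    s1 <- rnorm(n1); s2 <- rnorm(n2, sample(c(0, 2), 1))
    exact <- ks_two_sample(s1, s2, method = "exact-small-n")
    oracle <- ks_perm_oracle(s1, s2)
    expect_equal(exact$statistic, oracle$D, tolerance = 1e-12)
    expect_equal(exact$p_value, oracle$p, tolerance = 1e-10)
    # the asymptotic approximation is loose at these sizes
    asym <- ks_two_sample(s1, s2, method = "asymptotic")
    expect_lt(abs(asym$p_value - oracle$p), 0.15)
    # symmetry in the arguments
    sw <- ks_two_sample(s2, s1, method = "exact-small-n")
    expect_identical(exact$statistic, sw$statistic)
    expect_identical(exact$p_value, sw$p_value)
  }
})

test_that("KS D is invariant under joint strictly monotone transforms", {
  set.seed(23)
  s1 <- rnorm(40); s2 <- rnorm(40, 1)
  f <- function(z) exp(z) + z^3
  a <- ks_two_sample(s1, s2)
  b <- ks_two_sample(f(s1), f(s2))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("tiny p-values carry the conventional floor label", {
  set.seed(2)
  r <- ks_two_sample(rnorm(2000), rnorm(2000, 5))
  expect_identical(r$p_label, "<2.2e-16")
})

test_that("the density estimate integrates to 1 and behaves with bandwidth", {
  set.seed(19)
  x <- rnorm(10000)
  d <- kde_density(x)
  integral <- sum(diff(d$grid) * (head(d$height, -1) + tail(d$height, -1)) / 2)
  expect_lt(abs(integral - 1), 1e-3)
  expect_lt(abs(d$grid[which.max(d$height)]), 0.1)
  d2 <- kde_density(x, bandwidth = 2 * d$bandwidth)
  expect_lt(max(d2$height), max(d$height))
  expect_error(kde_density(rep(1, 10)), "distinct")
})

test_that("bimodality score separates unimodal from planted bimodal samples", {
  set.seed(29)
  not_bi <- sum(vapply(1:8, function(i) {
    bimodality_mixture_score(rnorm(500), seed = i)$bimodal
  }, logical(1)))
  expect_lte(not_bi, 1)
  hits <- 0
  for (i in 1:8) {
    x <- c(rnorm(250, -6), rnorm(250, 2))
    b <- bimodality_mixture_score(x, seed = i)
    hits <- hits + (b$bimodal && abs(b$means[1] + 6) < 0.5 &&
                      abs(b$means[2] - 2) < 0.5)
  }
  expect_equal(hits, 8)
  expect_error(bimodality_mixture_score(rnorm(10)), "n >= 20")
})

test_that("bimodality score is invariant under location-scale transforms", {
  set.seed(37)
  x <- c(rnorm(150, -4, 0.8), rnorm(200, 1, 1.2))
  a <- bimodality_mixture_score(x, seed = 1)
  b <- bimodality_mixture_score(3 * x + 10, seed = 1)
  expect_equal(a$delta_bic - b$delta_bic, 0, tolerance = 1e-3)
  expect_equal(b$means, 3 * a$means + 10, tolerance = 1e-3)
})

test_that("the 2-component fit agrees with an independent EM implementation", {
  suppressMessages(withr::local_package("mclust"))
  set.seed(43)
  x <- c(rnorm(200, -5), rnorm(300, 2, 1.5))
  mine <- bimodality_mixture_score(x, seed = 3)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(mine$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(mine$weights[order(mine$means)],
               mc$parameters$pro[order(mc$parameters$mean)],
               tolerance = 0.05)
})

test_that("frequency tables conserve counts and expose the human-skew signature", {
  sim <- simulate_dataset(build_preset("human_mii", seed = 55))
  g <- filter_expressed_in_all_replicates(sim$expression, "human_mii")
  m <- average_replicates(sim$expression, "human_mii", g)
  ft <- expressed_fraction_table(m, sim$annotation)
  expect_identical(sum(ft$n_x), attr(ft, "n_x_total"))
  expect_identical(sum(ft$n_a), attr(ft, "n_a_total"))
  expect_equal(sum(ft$frac_x), 1)
  k <- nrow(ft)
  low <- 1:4; high <- 6:8  # log2 <= 0 vs > 2
  expect_gt(sum(ft$frac_x[low]), sum(ft$frac_a[low]))
  expect_lt(sum(ft$frac_x[high]), sum(ft$frac_a[high]))
  # cutoff mode: fractions are per-class passing proportions
  fc <- expressed_fraction_table(m, sim$annotation,
                                 scheme = cutoff_scheme("FPKM_default"))
  expect_identical(nrow(fc), 8L)
  expect_true(all(fc$frac_x >= 0 & fc$frac_x <= 1))
  expect_true(all(diff(fc$n_x) <= 0))
})

test_that("no cutoff is significant when X and autosomes share one distribution", {
  set.seed(61)
  flags <- vapply(1:10, function(i) {
    v <- 2^rnorm(3000, 3, 2)
    names(v) <- c(sprintf("geneX%03d", 1:300), sprintf("geneA%04d", 1:2700))
    ft <- expressed_fraction_table(v, make_annotation(names(v)),
                                   scheme = cutoff_scheme("FPKM_default"),
                                   alpha = 0.01)
    any(ft$significant)
  }, logical(1))
  expect_lte(sum(flags), 2)
})

test_that("band enrichment recovers planted concentration and calibrates on null", {
  cfg <- build_preset("fgo", seed = 71, band_bias = 0.8)
  sim <- simulate_dataset(cfg)
  g <- filter_expressed_in_all_replicates(sim$expression, "fgo")
  m <- average_replicates(sim$expression, "fgo", g)
  enr <- band_low_expression_enrichment(m, sim$annotation)
  expect_setequal(enr$band[enr$enriched], c("qA2", "qA3.1"))
  # uniform low-mode placement: no band flagged (band_bias 0.2 is neutral)
  sim0 <- simulate_dataset(build_preset("fgo", seed = 72))
  g0 <- filter_expressed_in_all_replicates(sim0$expression, "fgo")
  m0 <- average_replicates(sim0$expression, "fgo", g0)
  enr0 <- band_low_expression_enrichment(m0, sim0$annotation)
  expect_identical(sum(enr0$enriched), 0L)
  # degenerate one-band annotation
  v <- stats::setNames(2^rnorm(50, 0, 3), sprintf("geneX%02d", 1:50))
  ann1 <- make_annotation(names(v), bands = "qA1")
  e1 <- band_low_expression_enrichment(v, ann1)
  expect_identical(nrow(e1), 1L)
  expect_false(any(e1$enriched))
})
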