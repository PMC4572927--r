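test_that("FPKM matches its closed form", {
  cnt <- matrix(c(10, 0), 2, 1,
                dimnames = list(c("a", "b"), "s1"))
  f <- compute_fpkm(cnt, lengths = c(a = 1000, b = 500),
                    library_sizes = 1e6)
  expect_identical(unname(f$values[, 1]), c(10, 0))
  # random matrix against per-cell brute force
  set.seed(4)
  cnt2 <- matrix(rpois(60, 50), 20, 3,
                 dimnames = list(sprintf("g%02d", 1:20), c("s1", "s2", "s3")))
  len <- runif(20, 300, 5000)
  lib <- colSums(cnt2)
  f2 <- compute_fpkm(cnt2, len)
  for (g in 1:20) for (s in 1:3)
    expect_equal(f2$values[g, s],
                 unname(cnt2[g, s] * 1e9 / (len[g] * lib[s])))
  expect_error(compute_fpkm(cnt2, rep(0, 20)), "length")
})

test_that("TMM factors are 1 for identical and exactly rescaled libraries", {
  set.seed(9)
  x <- rpois(100, 80) + 1
  same <- cbind(s1 = x, s2 = x)
  f <- compute_tmm_factors(same)
  expect_equal(unname(f$factors), c(1, 1))
  doubled <- cbind(s1 = x, s2 = 2L * x)  # all M-values 0 after lib scaling
  f2 <- compute_tmm_factors(doubled)
  expect_equal(unname(f2$factors), c(1, 1))
})

test_that("TMM factors equal a step-by-step independent recomputation", {
  set.seed(14)
  cnt <- matrix(rnbinom(150, size = 5, mu = 200 * runif(150, 0.2, 5)),
                50, 3, dimnames = list(sprintf("g%02d", 1:50),
                                       c("s1", "s2", "s3")))
  cnt[1:3, 1] <- 0  # exercise zero exclusion
  f <- compute_tmm_factors(cnt, reference = "s2")
  lib <- colSums(cnt)
  raw <- c(tmm_oracle_pair(cnt[, 1], cnt[, 2], lib[1], lib[2]),
           1,
           tmm_oracle_pair(cnt[, 3], cnt[, 2], lib[3], lib[2]))
  expected <- raw / exp(mean(log(raw)))
  expect_equal(unname(f$factors), unname(expected), tolerance = 1e-6)
})

test_that("TMM agrees with edgeR and is antisymmetric on two samples", {
  set.seed(7)
  cnt <- matrix(rnbinom(150, size = 5, mu = 200 * runif(150, 0.2, 5)),
                50, 3, dimnames = list(sprintf("g%02d", 1:50),
                                       c("s1", "s2", "s3")))
  f <- compute_tmm_factors(cnt)
  ref_idx <- match(f$reference, colnames(cnt))
  fe <- edgeR::calcNormFactors(cnt, method = "TMM", refColumn = ref_idx)
  expect_equal(unname(f$factors), unname(fe), tolerance = 1e-10)
  # antisymmetry: swapping the reference inverts the pair factor
  two <- cnt[, 1:2]
  fa <- compute_tmm_factors(two, reference = 2)$factors
  fb <- compute_tmm_factors(two, reference = 1)$factors
  expect_equal(unname(fa[1] * fb[2]), 1, tolerance = 1e-6)
})

test_that("rescaling one library leaves TMM factors nearly unchanged", {
  # exact invariance would need unweighted means; the precision weights
  # depend on absolute counts, so a uniform rescale shifts factors only
  # marginally
  set.seed(7)
  cnt <- matrix(rnbinom(150, size = 5, mu = 200 * runif(150, 0.2, 5)),
                50, 3, dimnames = list(sprintf("g%02d", 1:50),
                                       c("s1", "s2", "s3")))
  f1 <- compute_tmm_factors(cnt, reference = 3)$factors
  cnt2 <- cnt; cnt2[, 1] <- cnt2[, 1] * 50L
  f2 <- compute_tmm_factors(cnt2, reference = 3)$factors
  expect_equal(unname(f1), unname(f2), tolerance = 0.05)
})

test_that("TMM normalization collapses negative log2 values to 0", {
  # two identical libraries of size 2e6, factor 1 -> CPM = count/2
  cnt <- matrix(c(1, 16, 0, 2e6 - 17,
                  1, 16, 0, 2e6 - 17), 4, 2,
                dimnames = list(c("low", "mid", "zero", "big"),
                                c("s1", "s2")))
  fac <- compute_tmm_factors(cnt)
  lg <- apply_tmm(cnt, fac, collapse_negative_log = TRUE, output = "log2")
  expect_identical(unname(lg$values["low", 1]), 0)    # 0.5 CPM in (0,1)
  expect_identical(unname(lg$values["mid", 1]), 3)    # 8 CPM -> log2 = 3
  expect_true(is.na(lg$values["zero", 1]))            # not expressed
  off <- apply_tmm(cnt, fac, collapse_negative_log = FALSE,
                   output = "log2")
  lin <- apply_tmm(cnt, fac, output = "linear")
  differ <- which(lg$values != off$values)
  expect_true(all(lin$values[differ] > 0 & lin$values[differ] < 1))
  expect_identical(lg$values[-differ], off$values[-differ])
})

test_that("replicate filtering and averaging follow the expressed-in-all rule", {
  v <- rbind(g1 = c(1, 2, 0), g2 = c(0.1, 0.1, 0.1), g3 = c(5, 4, 3))
  expr <- make_expr(v, genes = rownames(v),
                    groups = c(s1 = "A", s2 = "A", s3 = "A"))
  expect_setequal(filter_expressed_in_all_replicates(expr, "A"),
                  c("g2", "g3"))
  expect_error(filter_expressed_in_all_replicates(expr, "nope"), "group")
  # brute-force scan oracle on a random matrix
  set.seed(12)
  m <- matrix(rbinom(300, 1, 0.7) * runif(300), 100, 3,
              dimnames = list(sprintf("g%03d", 1:100), c("a", "b", "c")))
  e2 <- make_expr(m, genes = rownames(m))
  brute <- rownames(m)[apply(m, 1, function(r) all(r > 0))]
  expect_identical(filter_expressed_in_all_replicates(e2, "all"), brute)
  # averaging is arithmetic on the linear scale
  e3 <- make_expr(rbind(g1 = c(2, 4, 6), g2 = c(1, 4, 1)),
                  genes = c("g1", "g2"))
  av <- average_replicates(e3, "all")
  expect_identical(unname(av["g1"]), 4)
  expect_identical(unname(average_replicates(make_expr(matrix(7, 1, 1),
                                                       genes = "g"),
                                             "all")["g"]), 7)
  # log-then-average differs from average-then-log: mean(1, 4) is 2.5
  expect_identical(unname(average_replicates(
    make_expr(matrix(c(1, 4), 1, 2), genes = "g"), "all")["g"]), 2.5)
  # filtering then averaging never yields a 0 mean
  genes <- filter_expressed_in_all_replicates(e2, "all")
  expect_true(all(average_replicates(e2, "all", genes) > 0))
})
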