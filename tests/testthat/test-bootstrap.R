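test_that("a constant ratio vector gives a degenerate bootstrap", {
  b <- suppressWarnings(bootstrap_means(rep(3, 40), B = 100, m = 50,
                                        seed = 1))
  expect_identical(b$means, rep(3, 100))
  expect_identical(b$sigma_hat, 0)
  expect_identical(b$mu_hat, 3)
})

test_that("the grand bootstrap mean matches the population mean", {
  # law of large numbers: sd of the grand mean ~ sd_pop / sqrt(m * B)
  b <- suppressWarnings(bootstrap_means(c(1, 2, 3, 4), B = 10000, m = 50,
                                        seed = 2))
  expect_lt(abs(mean(b$means) - 2.5), 0.01)
  expect_identical(b$mu_hat, mean(b$means))
  expect_identical(b$sigma_hat, sd(b$means))
  expect_true(all(b$means >= 1 & b$means <= 4))
})

test_that("bootstrap is deterministic under a fixed seed and warns when small", {
  x <- live_ratios(1, n = 2000, seed = 3)$ratios
  b1 <- bootstrap_means(x, B = 200, m = 50, seed = 7)
  b2 <- bootstrap_means(x, B = 200, m = 50, seed = 7)
  expect_identical(b1$means, b2$means)
  expect_warning(bootstrap_means(x[1:100], B = 10, m = 50, seed = 1),
                 "100 cells")
  expect_error(bootstrap_means(numeric(), B = 10, m = 50, seed = 1),
               "empty")
})

test_that("self-comparison on a shared stream is an exact null", {
  x <- live_ratios(1, n = 2000, seed = 4)$ratios
  b1 <- bootstrap_means(x, B = 500, m = 50, seed = 11)
  b2 <- bootstrap_means(x, B = 500, m = 50, seed = 11)
  call <- dual_one_sided_test(b1, b2)
  expect_identical(call$t_stat, 0)
  expect_identical(call$p_decrease, 0.5)
  expect_identical(call$p_increase, 0.5)
  expect_identical(call$category, "wt_like")
})

test_that("an extreme downward shift is called decreased at any cutoff", {
  x <- live_ratios(1, n = 2000, seed = 5)$ratios
  wt <- bootstrap_means(x, B = 300, m = 50, seed = 13)
  mut <- wt
  mut$means <- wt$means - 10 * sd(wt$means)
  mut$mu_hat <- mean(mut$means)
  call <- dual_one_sided_test(mut, wt)
  expect_lt(call$p_decrease, 1e-30)
  expect_identical(call$category, "decreased")
})

test_that("welch p-values match an independent t.test oracle for small B", {
  # dual-route check: our hand-coded Welch statistic against stats::t.test
  set.seed(71)
  for (B in c(5, 12, 20)) {
    x <- rlnorm(300, 0, 0.4)
    y <- rlnorm(250, -0.3, 0.5)
    bm <- suppressWarnings(bootstrap_means(x, B = B, m = 7, seed = B))
    bw <- suppressWarnings(bootstrap_means(y, B = B, m = 7, seed = B + 1))
    call <- dual_one_sided_test(bm, bw)
    oracle <- t.test(bm$means, bw$means, alternative = "less")
    expect_equal(call$p_decrease, oracle$p.value, tolerance = 1e-12)
    expect_equal(call$t_stat, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(call$df, unname(oracle$parameter), tolerance = 1e-9)
    oracle_hi <- t.test(bm$means, bw$means, alternative = "greater")
    expect_equal(call$p_increase, oracle_hi$p.value, tolerance = 1e-12)
  }
})

test_that("pooled and z variants agree with their oracles", {
  set.seed(72)
  b1 <- suppressWarnings(bootstrap_means(rlnorm(200), B = 15, m = 9, seed = 1))
  b2 <- suppressWarnings(bootstrap_means(rlnorm(200), B = 15, m = 9, seed = 2))
  pooled <- dual_one_sided_test(b1, b2, variant = "pooled")
  oracle <- t.test(b1$means, b2$means, alternative = "less",
                   var.equal = TRUE)
  expect_equal(pooled$p_decrease, oracle$p.value, tolerance = 1e-12)
  zcall <- dual_one_sided_test(b1, b2, variant = "z")
  z <- (b1$mu_hat - b2$mu_hat) /
    sqrt(b1$sigma_hat^2 / b1$B + b2$sigma_hat^2 / b2$B)
  expect_equal(zcall$p_decrease, pnorm(z), tolerance = 1e-12)
})

test_that("p-values are complementary and categories follow the cutoff", {
  set.seed(73)
  for (i in 1:25) {
    b1 <- suppressWarnings(
      bootstrap_means(rlnorm(150, 0, 0.5), B = 50, m = 10, seed = i))
    b2 <- suppressWarnings(
      bootstrap_means(rlnorm(150, 0, 0.5), B = 50, m = 10, seed = i + 1000))
    call <- dual_one_sided_test(b1, b2, alpha = 0.05)
    expect_equal(call$p_decrease + call$p_increase, 1, tolerance = 1e-12)
    expected <- if (call$p_decrease < 0.05) "decreased"
                else if (call$p_increase < 0.05) "increased" else "wt_like"
    expect_identical(call$category, expected)
  }
})

test_that("swapping mutant and wild type mirrors the call", {
  b1 <- bootstrap_means(live_ratios(0.7, n = 1500, seed = 6)$ratios,
                        B = 200, m = 50, seed = 21)
  b2 <- bootstrap_means(live_ratios(1, n = 1500, seed = 7)$ratios,
                        B = 200, m = 50, seed = 22)
  fwd <- dual_one_sided_test(b1, b2)
  rev <- dual_one_sided_test(b2, b1)
  expect_equal(fwd$p_decrease, rev$p_increase, tolerance = 1e-12)
  expect_equal(fwd$t_stat, -rev$t_stat, tolerance = 1e-12)
  expect_identical(fwd$category, "decreased")
  expect_identical(rev$category, "increased")
})

test_that("shifting the mutant downward strictly decreases p_decrease", {
  x <- live_ratios(1, n = 1500, seed = 8)$ratios
  wt <- bootstrap_means(x, B = 200, m = 50, seed = 31)
  mut <- bootstrap_means(x, B = 200, m = 50, seed = 32)
  shifts <- c(0, 0.005, 0.02, 0.08)
  ps <- vapply(shifts, function(s) {
    m2 <- mut
    m2$means <- mut$means - s
    m2$mu_hat <- mean(m2$means)
    dual_one_sided_test(m2, wt)$p_decrease
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("zero-variance degenerate cases are defined deterministically", {
  ca <- suppressWarnings(bootstrap_means(rep(2, 10), B = 20, m = 5, seed = 1))
  cb <- suppressWarnings(bootstrap_means(rep(2, 10), B = 20, m = 5, seed = 2))
  eq <- dual_one_sided_test(ca, cb)
  expect_identical(eq$p_decrease, 0.5)
  expect_identical(eq$category, "wt_like")
  lo <- suppressWarnings(bootstrap_means(rep(1, 10), B = 20, m = 5, seed = 3))
  dn <- dual_one_sided_test(lo, ca)
  expect_identical(dn$p_decrease, 0)
  expect_identical(dn$p_increase, 1)
  expect_identical(dn$category, "decreased")
})

test_that("mismatched bootstrap settings are rejected", {
  b1 <- suppressWarnings(bootstrap_means(1:10, B = 10, m = 5, seed = 1))
  b2 <- suppressWarnings(bootstrap_means(1:10, B = 10, m = 6, seed = 1))
  expect_error(dual_one_sided_test(b1, b2), "mismatched")
})

test_that("classify maps complementary p-values to categories", {
  expect_identical(classify(0.001, 0.999, 0.01), "decreased")
  expect_identical(classify(0.5, 0.5, 0.01), "wt_like")
  expect_identical(classify(0.999, 0.001, 0.01), "increased")
  expect_error(classify(0.3, 0.3, 0.01), "complementary")
  expect_error(classify(-0.1, 1.1, 0.01), "\\[0, 1\\]")
})
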