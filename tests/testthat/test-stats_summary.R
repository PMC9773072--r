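# Reporting conventions and the nonparametric test battery.

test_that("quartiles follow the selected interpolation convention", {
  q6 <- quartiles(1:5)
  expect_equal(c(q6$p25, q6$p50, q6$p75), c(1.5, 3, 4.5))  # SPSS HAVERAGE
  q7 <- quartiles(1:5, type = 7)
  expect_equal(c(q7$p25, q7$p50, q7$p75), c(2, 3, 4))
  expect_equal(unlist(quartiles(7)), c(p50 = 7, p25 = 7, p75 = 7))
  expect_equal(unlist(quartiles(c(1, 1, 1, 1))), c(p50 = 1, p25 = 1, p75 = 1))
  expect_error(quartiles(numeric(0)), "empty")
})

test_that("quartiles are permutation-invariant and monotone", {
  set.seed(31)
  for (i in 1:10) {
    x <- rlnorm(sample(5:50, 1))
    expect_equal(unlist(quartiles(sample(x))), unlist(quartiles(x)))
    y <- x + runif(length(x), 0, 2)
    qx <- quartiles(x); qy <- quartiles(y)
    expect_true(qy$p25 >= qx$p25 && qy$p50 >= qx$p50 && qy$p75 >= qx$p75)
    q <- quartiles(x)
    expect_true(q$p25 <= q$p50 && q$p50 <= q$p75)
  }
})

test_that("percent rounds half-up at two decimals", {
  expect_equal(percent(597, 676), 88.31)
  expect_equal(percent(622, 676), 92.01)
  expect_equal(percent(0, 676), 0)
  expect_equal(round_half_up(0.125), 0.13)   # banker's rounding would give 0.12
  expect_equal(round_half_up(-0.125), -0.13) # half away from zero
  expect_error(percent(1, 0), "positive")
  expect_error(percent(5, 4), "\\[0, n\\]")
})

test_that("pp_change uses the rounded-operand convention", {
  expect_equal(pp_change(91.57, 75.44), 16.13)  # raw counts 109/676 give 16.12
  expect_equal(pp_change(68.79, 55.47), 13.32)
  expect_equal(pp_change(42.42, 42.42), 0)
  expect_equal(pp_change(10, 12.5), -2.5)
})

test_that("signed-rank test follows the zeros-dropped tie-corrected convention", {
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "no non-zero pairs")
  r <- wilcoxon_signed_rank(rep(0, 5), 1:5)
  expect_equal(r$W, 15)
  expect_equal(r$statistic, (15 - 7.5) / sqrt(5 * 6 * 11 / 24))
  expect_equal(r$p_value, 0.04311445, tolerance = 1e-6)
  rex <- wilcoxon_signed_rank(rep(0, 5), 1:5, method = "exact")
  expect_equal(rex$p_value, 0.0625)  # 2/32
  # antisymmetric differences: z = 0, p = 1
  ra <- wilcoxon_signed_rank(rep(0, 4), c(1, -1, 2, -2))
  expect_equal(ra$statistic, 0)
  expect_equal(ra$p_value, 1)
  # dual route: agrees with the base-R implementation without correction
  set.seed(17)
  for (i in 1:10) {
    before <- rnorm(30); after <- before + rnorm(30)
    ours <- wilcoxon_signed_rank(before, after)
    ref <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE,
                                               exact = FALSE, correct = FALSE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("McNemar switches between exact binomial and corrected chi-square at 25", {
  r <- mcnemar(rep(c(TRUE, FALSE), c(10, 10)), rep(FALSE, 20))  # b=10, c=0
  expect_equal(r$p_value, 2 * 0.5^10)
  expect_equal(r$method, "exact binomial")
  r2 <- mcnemar(rep(c(TRUE, FALSE), c(5, 5)), rep(c(FALSE, TRUE), c(5, 5)))  # b=c=5
  expect_equal(r2$p_value, 1)
  fb <- rep(c(TRUE, FALSE, TRUE), c(30, 10, 5)); fa <- rep(c(FALSE, TRUE, TRUE), c(30, 10, 5))
  r3 <- mcnemar(fb, fa)  # b=30, c=10
  expect_equal(r3$statistic, (abs(30 - 10) - 1)^2 / 40)  # 9.025
  expect_equal(r3$p_value, stats::pchisq(9.025, 1, lower.tail = FALSE))
  # matches base R's continuity-corrected form
  ref <- stats::mcnemar.test(matrix(c(5, 10, 30, 5), 2), correct = TRUE)
  expect_equal(r3$statistic, unname(ref$statistic))
  r4 <- mcnemar(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_true(r4$degenerate)
  expect_equal(r4$p_value, 1)
})

test_that("Kruskal-Wallis and Mann-Whitney agree with references and each other", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis(g)$statistic, 0)
  expect_equal(kruskal_wallis(g)$p_value, 1)
  expect_equal(kruskal_wallis(list(1:3, 4:6, 7:9))$statistic, 7.2)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")

  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  mw <- mann_whitney(1:3, 4:6)
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1)  # 2/20 arrangements at either tail
  # shift invariance of U
  expect_equal(mann_whitney(1:5 + 100, c(2, 8, 9) + 100)$U_a,
               mann_whitney(1:5, c(2, 8, 9))$U_a)
  # two-group Kruskal-Wallis is the squared Mann-Whitney z
  set.seed(23)
  a <- rnorm(25); b <- rnorm(25) + 0.5
  expect_equal(kruskal_wallis(list(a, b))$p_value,
               mann_whitney(a, b, exact_limit = 0)$p_value, tolerance = 1e-10)
})

test_that("chi-square independence is uncorrected Pearson", {
  prop <- rbind(c(10, 20), c(20, 40))
  expect_equal(chi_square_independence(prop)$statistic, 0)
  expect_equal(chi_square_independence(prop)$p_value, 1)
  r <- chi_square_independence(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1)
  # milk-powder consumption by age stratum: strongly age-dependent
  tab <- rbind(c(112, 224 - 112), c(95, 226 - 95), c(70, 226 - 70))
  r2 <- chi_square_independence(tab)
  expect_equal(r2$df, 2)
  expect_lt(r2$p_value, 0.001)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("exact modes agree with independent enumeration oracles on small inputs", {
  set.seed(41)
  for (i in 1:15) {
    n <- sample(3:8, 1)
    before <- round(rnorm(n), 1)
    after <- round(before + rnorm(n), 1)
    if (all(after == before)) after[1] <- after[1] + 1
    expect_equal(wilcoxon_signed_rank(before, after, method = "exact")$p_value,
                 oracle_signed_rank(before, after), tolerance = 1e-9)
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- round(rnorm(na), 1); b <- round(rnorm(nb), 1)
    expect_equal(mann_whitney(a, b)$p_value, oracle_mann_whitney(a, b),
                 tolerance = 1e-9)
    bb <- sample(0:8, 1); cc <- sample(0:8, 1)
    fb <- rep(c(TRUE, FALSE, TRUE), c(bb, cc, 3))
    fa <- rep(c(FALSE, TRUE, TRUE), c(bb, cc, 3))
    expect_equal(mcnemar(fb, fa)$p_value, oracle_mcnemar(bb, cc), tolerance = 1e-9)
  }
})
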