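test_that("daily aggregation reports M and SE of double determinations", {
  got <- daily_aggregate(c(1, 1, 2), c(4, 6, 7))
  expect_equal(got$mean, c(5, 7))
  expect_equal(got$sem, c(1, NA))    # |a - b| / 2 for duplicates
  expect_equal(got$n, c(2L, 1L))
  expect_equal(daily_aggregate(c(3, 3), c(3, 3))$sem, 0)
})

test_that("the peak function has its analytic maximum at xc", {
  expect_equal(eval_extreme(34, y0 = 1, A = 10, xc = 34, w = 8), 11)
  # decays to the offset far from the peak
  expect_equal(eval_extreme(1e6, y0 = 2, A = 10, xc = 34, w = 8), 2)
  # direct arithmetic evaluation at z = 1
  expect_equal(eval_extreme(1, 0, 1, 0, 1), exp(-exp(-1)),
               tolerance = 1e-12)
  expect_equal(exp(-exp(-1)), 0.69220, tolerance = 1e-5)
  # numeric argmax on a fine grid sits at xc
  x <- seq(0, 100, by = 0.01)
  y <- eval_extreme(x, y0 = 0.5, A = 3, xc = 42.37, w = 11)
  expect_equal(x[which.max(y)], 42.37, tolerance = 0.011)
  expect_error(eval_extreme(1, 0, 1, 0, w = 0))
})

test_that("peak fitting recovers noiseless parameters and rejects
           degenerate input", {
  days <- seq(0, 150, length.out = 40)
  truth <- list(y0 = 1.2, A = 8, xc = 55, w = 12)
  y <- do.call(eval_extreme, c(list(x = days), truth))
  ft <- fit_extreme(days, y)
  expect_true(ft$converged)
  expect_equal(coef(ft), unlist(truth), tolerance = 1e-4)
  expect_gt(ft$adj_r2, 0.9999)
  expect_equal(predict(ft), y, tolerance = 1e-6)
  expect_equal(residuals(ft), y - predict(ft))
  expect_output(print(ft), "adj. R")
  expect_error(fit_extreme(days, rep(3, 40)), "flat")
  expect_error(fit_extreme(1:4, c(1, 2, 3, 1)), ">= 5 points")
})

test_that("kendall tau matches pair counting and the tau-b closed form", {
  expect_equal(kendall_tau(1:10, 1:10)$tau, 1)
  expect_equal(kendall_tau(1:10, 10:1)$tau, -1)
  # brute-force concordant/discordant count over all 6 pairs
  got <- kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(got$tau, (5 - 1) / 6, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:25) {
    x <- sample(1:6, 12, replace = TRUE)   # tied
    y <- sample(1:6, 12, replace = TRUE)
    expect_equal(kendall_tau(x, y)$tau, tau_oracle(x, y), tolerance = 1e-12)
    u <- rnorm(12); v <- rnorm(12)         # tie-free
    expect_equal(kendall_tau(u, v)$tau, tau_oracle(u, v), tolerance = 1e-12)
  }
  expect_error(kendall_tau(1:2, 1:2), ">= 3")
})

test_that("tau grouping is single-linkage on significant correlations", {
  base <- data.frame(day = 1:20, mean = sin((1:20) / 3) + (1:20) / 10)
  flip <- data.frame(day = 1:20, mean = -base$mean)
  ser3 <- list(a = base, b = base, c = base)
  tg <- tau_group(ser3)
  expect_equal(tg$groups$group, rep(1L, 3))
  expect_equal(unname(diag(tg$tau)), rep(1, 3))
  expect_equal(tg$tau, t(tg$tau))
  # uncorrelated series stay singletons
  tg2 <- tau_group(list(a = base, b = flip))
  expect_equal(length(unique(tg2$groups$group)), 2L)
  # chain a-b, b-c above threshold links all three even though a-c is
  # below it (b is a rank blend of a and c)
  mk <- function(v) data.frame(day = seq_along(v), mean = v)
  a <- 1:20
  c_ <- c(12, 6, 4, 16, 1, 11, 13, 20, 7, 14, 2, 17, 9, 8, 18, 3, 19, 10,
          15, 5)
  b <- c(4.5, 3, 2, 10, 1, 7, 9, 15.5, 6, 13, 4.5, 17, 11.5, 11.5, 18, 8,
         20, 15.5, 19, 14)
  expect_gte(kendall_tau(a, b)$tau, 0.5)
  expect_gte(kendall_tau(b, c_)$tau, 0.5)
  expect_lt(kendall_tau(a, c_)$tau, 0.5)
  tg3 <- tau_group(list(a = mk(a), b = mk(b), c = mk(c_)),
                   tau_min = 0.5, alpha = 0.05)
  expect_equal(length(unique(tg3$groups$group)), 1L)
})

test_that("kruskal-wallis handles ties, degeneracy and the two-group
           special case", {
  expect_equal(kw_test(list(c(1, 1), c(1, 1, 1))), list(H = 0, p = 1, df = 1L))
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  got <- kw_test(g)
  expect_equal(got$H, kw_oracle_H(g), tolerance = 1e-12)
  # two groups: H equals the squared normal deviate of the
  # Wilcoxon/Mann-Whitney U statistic (no ties)
  set.seed(3)
  x <- rnorm(8); y <- rnorm(10) + 1
  U <- unname(wilcox.test(x, y, exact = FALSE, correct = FALSE)$statistic)
  n1 <- 8; n2 <- 10; N <- n1 + n2
  z <- (U - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(kw_test(list(x, y))$H, z^2, tolerance = 1e-10)
  # tie-corrected H still matches the rank-formula oracle
  gt <- list(c(1, 2, 2, 3), c(2, 3, 3, 4), c(4, 4, 5, 5))
  expect_equal(kw_test(gt)$H, kw_oracle_H(gt), tolerance = 1e-12)
})

test_that("dunn post hoc flags the shifted group and respects adjustment
           dominance", {
  g0 <- list(a = c(1, 2), b = c(1, 2, 1.5))
  d0 <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_true(all(abs(d0$z) < 1e-12) && all(d0$p > 0.999))
  set.seed(5)
  g <- list(a = rnorm(12), b = rnorm(12), c = rnorm(12) + 1000)
  dn <- dunn_posthoc(g)
  sig <- dn$p < 0.05
  involves_c <- dn$group1 == "c" | dn$group2 == "c"
  expect_true(all(sig[involves_c]))
  expect_false(any(sig[!involves_c]))
  dh <- dunn_posthoc(g, adjust = "holm")
  expect_true(all(dh$p_adj >= dh$p - 1e-15))
})
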