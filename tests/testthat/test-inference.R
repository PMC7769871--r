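test_that("Kruskal-Wallis H matches the rank-sum formula on fixtures", {
  k <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(k$H, 7.2, tolerance = 1e-12)
  expect_equal(k$df, 2)

  set.seed(31)
  for (rep in 1:10) {
    g <- lapply(sample(2:8, sample(2:4, 1), replace = TRUE),
                function(n) sample(1:6, n, replace = TRUE))  # with ties
    k <- kruskal_wallis(g)
    expect_equal(k$H, oracle_kw_h(g), tolerance = 1e-10)
  }
})

test_that("identical observations give H = 0 and p = 1", {
  k <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(k$H, 0)
  expect_equal(k$p_value, 1)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)),
                              exact = TRUE)$p_exact, 1)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(32)
  g <- list(rlnorm(6), rlnorm(8), rlnorm(5))
  h0 <- kruskal_wallis(g)$H
  expect_equal(kruskal_wallis(lapply(g, log))$H, h0)
  expect_equal(kruskal_wallis(lapply(g, function(v) v^3))$H, h0)
  expect_equal(kruskal_wallis(lapply(g, function(v) 5 * v - 2))$H, h0)
})

test_that("the exact permutation p agrees with a sampled permutation oracle", {
  g <- list(c(1.2, 3.4, 2.2), c(4.1, 5.7), c(0.3, 6.6, 7.1))
  k <- kruskal_wallis(g, exact = TRUE)
  set.seed(33)
  p_mc <- oracle_kw_perm_p(g, n_perm = 2e4)
  expect_lt(abs(k$p_exact - p_mc),
            3 * sqrt(p_mc * (1 - p_mc) / 2e4) + 1e-3)
  expect_error(kruskal_wallis(list(1:6, 7:12), exact = TRUE), "N <= 10")
})

test_that("the chi-square p is close to the permutation p for moderate N", {
  set.seed(34)
  g <- list(rnorm(6), rnorm(6, 0.5), rnorm(6, 1))
  k <- kruskal_wallis(g)
  p_mc <- oracle_kw_perm_p(g, n_perm = 1e4)
  expect_lt(abs(k$p_value - p_mc), 0.02)
})

test_that("pairwise post-hoc uses the k(k-1)/2 Bonferroni multiplier", {
  set.seed(35)
  g <- lapply(1:4, function(i) rnorm(8, mean = i / 2))
  names(g) <- age_categories()
  ph <- pairwise_posthoc(g)
  expect_equal(nrow(ph), 6)
  for (i in seq_len(6)) {
    raw <- wilcox.test(g[[ph$group1[i]]], g[[ph$group2[i]]])$p.value
    expect_equal(ph$p_raw[i], raw)
    expect_equal(ph$p_adj[i], min(1, 6 * raw))
  }
  expect_true(all(ph$p_adj >= ph$p_raw))
  expect_true(all(ph$p_adj <= 1))
  # adjusted p monotone in raw p
  ord <- order(ph$p_raw)
  expect_true(all(diff(ph$p_adj[ord]) >= 0))
})

test_that("identical groups compare as indistinguishable", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(pairwise_posthoc(g)$p_adj, 1)
  expect_equal(pairwise_posthoc(g, method = "signed_rank")$p_adj, 1)
})

test_that("the paired flavour requires aligned groups and differs from unpaired", {
  set.seed(36)
  base <- rnorm(12)
  g <- list(a = base, b = base + rnorm(12, 0.3), c = base + rnorm(12, 0.6))
  ph <- pairwise_posthoc(g, method = "signed_rank")
  expect_equal(nrow(ph), 3)
  raw <- suppressWarnings(wilcox.test(g$a, g$b, paired = TRUE))$p.value
  expect_equal(ph$p_raw[ph$group1 == "a" & ph$group2 == "b"], raw)
  expect_error(pairwise_posthoc(list(a = 1:3, b = 1:4),
                                method = "signed_rank"), "equal")
})

test_that("the pairwise procedure controls familywise error under the null", {
  set.seed(37)
  n_sim <- 2000
  any_rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8), d = rnorm(8))
    any_rej[i] <- any(pairwise_posthoc(g)$p_adj <= 0.05)
  }
  fwer <- mean(any_rej)
  # Bonferroni is conservative; allow Monte-Carlo slack above the nominal level
  expect_lt(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("simple regression matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4, 5)
  fit <- simple_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_equal(fit$adj_r2, 1)

  set.seed(38)
  x6 <- c(2.1, 3.7, 5.0, 6.2, 8.8, 9.3)
  y6 <- c(1.0, 2.2, 1.8, 3.9, 4.1, 5.6)
  fit <- simple_regression(x6, y6)
  sxx <- sum((x6 - mean(x6))^2)
  slope_hat <- sum((x6 - mean(x6)) * (y6 - mean(y6))) / sxx
  intercept_hat <- mean(y6) - slope_hat * mean(x6)
  expect_equal(fit$slope, slope_hat, tolerance = 1e-10)
  expect_equal(fit$intercept, intercept_hat, tolerance = 1e-10)
  resid <- y6 - intercept_hat - slope_hat * x6
  se_hat <- sqrt(sum(resid^2) / (6 - 2) / sxx)
  expect_equal(fit$slope_se, se_hat, tolerance = 1e-10)
  expect_equal(fit$t_statistic, slope_hat / se_hat, tolerance = 1e-10)
  expect_equal(fit$p_value, 2 * pt(abs(slope_hat / se_hat), 4,
                                   lower.tail = FALSE), tolerance = 1e-10)
  r2_hat <- 1 - sum(resid^2) / sum((y6 - mean(y6))^2)
  expect_equal(fit$r2, r2_hat, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1 - (1 - r2_hat) * 5 / 4, tolerance = 1e-10)
})

test_that("adjusted R2 follows 1 - (1 - R2)(n-1)/(n-2)", {
  # construct n = 10 with R2 exactly 0.5: noise orthogonal to x, equal energy
  x <- 1:10
  xc <- x - mean(x)
  set.seed(39)
  e <- residuals(lm(rnorm(10) ~ x))
  e <- e * sqrt(sum(xc^2) / sum(e^2))
  fit <- simple_regression(x, xc + e)
  expect_equal(fit$r2, 0.5, tolerance = 1e-12)
  expect_equal(fit$adj_r2, 0.4375, tolerance = 1e-12)
})

test_that("degenerate designs are rejected", {
  expect_error(simple_regression(rep(2, 5), 1:5), "constant")
  expect_error(simple_regression(1:2, 1:2), "at least 3")
})

test_that("the regression suite runs the six category pairs plus herd size", {
  set.seed(40)
  wide <- tibble::tibble(
    farm_id = sprintf("f%02d", 1:20),
    sow = rlnorm(20), weaner = rlnorm(20), fattener = rlnorm(20),
    sows_kept = round(rlnorm(20, log(70), 0.5))
  )
  wide$piglet <- 0.7 * wide$sow  # noiseless linkage
  wide$total <- wide$piglet + wide$weaner + wide$fattener + wide$sow
  rs <- regression_suite(wide)
  expect_equal(nrow(rs), 7)
  expect_equal(rs$predictor[7], "sows_kept")
  sp <- rs[rs$predictor == "sow" & rs$response == "piglet", ]
  expect_equal(sp$slope, 0.7, tolerance = 1e-12)
  expect_equal(sp$r2, 1, tolerance = 1e-12)
  # permutation of farms leaves every fit unchanged
  rs2 <- regression_suite(wide[sample(20), ])
  expect_equal(rs2$slope, rs$slope, tolerance = 1e-12)
  expect_equal(rs2$p_value, rs$p_value, tolerance = 1e-12)
})

test_that("residual diagnostics detect what they should at n = 200", {
  n <- 200
  ok_norm <- 0
  flagged_het <- 0
  n_seed <- 40
  for (s in seq_len(n_seed)) {
    set.seed(s)
    x <- runif(n, 1, 10)
    fit_n <- simple_regression(x, 1 + 0.5 * x + rnorm(n))
    d_n <- residual_diagnostics(fit_n)
    ok_norm <- ok_norm + !d_n$normality$rejected
    fit_h <- simple_regression(x, 1 + 0.5 * x + rnorm(n, sd = 0.3 * x^2))
    d_h <- residual_diagnostics(fit_h)
    flagged_het <- flagged_het + d_h$heteroscedasticity$flagged
  }
  expect_gte(ok_norm / n_seed, 0.9)
  expect_gte(flagged_het / n_seed, 0.9)
})

test_that("the heteroscedasticity statistic equals the studentized Breusch-Pagan", {
  set.seed(41)
  x <- runif(50, 1, 5)
  y <- 1 + x + rnorm(50, sd = x)
  fit <- simple_regression(x, y)
  d <- residual_diagnostics(fit)
  bp <- lmtest::bptest(lm(y ~ x))
  expect_equal(d$heteroscedasticity$statistic, unname(bp$statistic),
               tolerance = 1e-10)
  expect_equal(d$heteroscedasticity$p_value, unname(bp$p.value),
               tolerance = 1e-10)
})

test_that("a perfect fit is reported as not assessable", {
  fit <- simple_regression(1:5, 2 * (1:5))
  d <- residual_diagnostics(fit)
  expect_false(d$assessable)
  expect_true(is.na(d$normality$p_value))
})
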