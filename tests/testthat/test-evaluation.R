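test_that("paired t statistic matches the textbook formula on a hand case", {
  # d = b - a = (0.2, 0.3, 0.3, 0.3): mean 0.275, sd 0.05, t = 11
  a <- c(0, 0, 0, 0)
  b <- c(0.2, 0.3, 0.3, 0.3)
  res <- paired_t_test(a, b)
  expect_equal(res$t_statistic, 11.0, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$mean_difference, 0.275)
})

test_that("paired t-test agrees with the closed-form oracle over random instances", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    a <- rnorm(n)
    b <- a + rnorm(n, mean = runif(1, -1, 1))
    d <- b - a
    if (sd(d) < 1e-8) next
    t_oracle <- mean(d) / (sd(d) / sqrt(n))
    p_oracle <- 2 * stats::pt(-abs(t_oracle), n - 1)
    res <- paired_t_test(a, b)
    expect_equal(res$t_statistic, t_oracle, tolerance = 1e-9)
    expect_equal(res$p_value, p_oracle, tolerance = 1e-9)
  }
})

test_that("swapping the paired samples flips the sign of t but not p", {
  set.seed(7)
  a <- rnorm(10); b <- a + rnorm(10, 0.5)
  r1 <- paired_t_test(a, b)
  r2 <- paired_t_test(b, a)
  expect_equal(r1$t_statistic, -r2$t_statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("degenerate paired inputs are rejected", {
  expect_error(paired_t_test(1:3, 1:4), class = "biohackr_error")
  expect_error(paired_t_test(1, 2), class = "biohackr_error")
  expect_error(paired_t_test(c(1, NA, 3), c(1, 2, 3)),
               class = "biohackr_error")
  expect_error(paired_t_test(c(1, 2, 3), c(2, 3, 4)),
               class = "biohackr_error")  # zero-variance differences
})

test_that("regression matches lm and cor on random instances", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 2000, 800)
    y <- x / 7700 + rnorm(n, 0, 0.3)
    fit <- lm(y ~ x)
    reg <- regress_dw_on_deb(tibble::tibble(delta_eb = x, dw = y))
    expect_equal(reg$slope, unname(coef(fit)[2]), tolerance = 1e-9)
    expect_equal(reg$intercept, unname(coef(fit)[1]), tolerance = 1e-9)
    expect_equal(reg$r_squared, summary(fit)$r.squared, tolerance = 1e-9)
    expect_equal(reg$pearson_r, cor(x, y), tolerance = 1e-9)
    expect_equal(reg$p_value, summary(fit)$coefficients[2, 4],
                 tolerance = 1e-9)
  }
})

test_that("r squared is the square of the correlation in simple regression", {
  set.seed(3)
  x <- rnorm(30, 1000, 500); y <- x / 7700 + rnorm(30, 0, 0.2)
  reg <- regress_dw_on_deb(tibble::tibble(delta_eb = x, dw = y))
  expect_equal(reg$r_squared, reg$pearson_r^2, tolerance = 1e-12)
})

test_that("regression refuses degenerate designs", {
  expect_error(regress_dw_on_deb(tibble::tibble(delta_eb = c(1, 2),
                                                dw = c(1, 2))),
               class = "biohackr_error")
  expect_error(regress_dw_on_deb(tibble::tibble(delta_eb = rep(5, 10),
                                                dw = rnorm(10))),
               class = "biohackr_error")
})

test_that("cohort evaluation collects per-participant rows and means", {
  set.seed(5)
  mk <- function(seed) {
    set.seed(seed)
    eb <- runif(30, 500, 3500)
    tibble::tibble(period_start = as.Date("2023-01-01") + 1:30,
                   period_end = as.Date("2023-01-15") + 1:30,
                   dw_actual = rnorm(30, 0.3, 0.5),
                   dw_simulated = rnorm(30, -0.1, 0.5),
                   delta_eb = eb, n_substitutions = rpois(30, 10))
  }
  results <- list(p1 = mk(1), p2 = mk(2))
  report <- evaluate_cohort(results)
  expect_s3_class(report, "cohort_report")
  expect_equal(nrow(report$weight_comparison), 2)
  expect_equal(nrow(report$regression), 2)
  expect_equal(report$weight_comparison$participant, c("p1", "p2"))
  direct <- paired_t_test(results$p1$dw_actual, results$p1$dw_simulated)
  expect_equal(report$weight_comparison$t_statistic[1], direct$t_statistic)
})
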