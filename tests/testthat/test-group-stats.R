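test_that("exact rate test matches full pmf enumeration over a totals grid", {
  grid <- expand.grid(n1 = c(12, 5, 10), n0 = c(6, 7, 10))
  for (g in seq_len(nrow(grid))) {
    n1 <- grid$n1[g]; n0 <- grid$n0[g]
    for (T in c(0:8, 20, 65, 120, 200)) {
      for (y1 in unique(c(0, T %/% 3, (2 * T) %/% 3, T))) {
        res <- exact_rate_test(y1, n1, T - y1, n0)
        orc <- rate_test_oracle(y1, n1, T - y1, n0)
        expect_equal(res$p_one_sided, orc$one, tolerance = 1e-12)
        expect_equal(res$p_two_sided, orc$two, tolerance = 1e-12)
      }
    }
  }
})

test_that("rate test handles its boundary cases", {
  # symmetric mode with equal groups: two-sided p = 1
  res <- exact_rate_test(5, 8, 5, 8)
  expect_equal(res$p_two_sided, 1)
  # empty total: p = 1, ratio undefined
  res0 <- exact_rate_test(0, 12, 0, 6)
  expect_equal(res0$p_two_sided, 1)
  expect_true(res0$ratio_undefined)
  # zero reference events: infinite rate ratio
  expect_equal(exact_rate_test(5, 12, 0, 6)$rate_ratio_mle, Inf)
  expect_equal(exact_rate_test(6, 12, 3, 6)$rate_ratio_mle, 1)
  # the 5-vs-0 contrast equals the Binomial(5, 2/3) upper tail point mass
  expect_equal(exact_rate_test(5, 12, 0, 6)$p_one_sided, (2 / 3)^5,
               tolerance = 1e-12)
  # one-sided never exceeds two-sided for upper-tail outcomes
  # (T = 10, success probability 2/3: outcomes from the mode upward)
  for (y1 in 7:10) {
    r <- exact_rate_test(y1, 12, 10 - y1, 6)
    expect_lte(r$p_one_sided, r$p_two_sided + 1e-12)
  }
})

test_that("exact test keeps type-I error at or below nominal under the null", {
  set.seed(41)
  n1 <- 12; n0 <- 6; lambda <- 1.5
  reps <- 10000
  y1 <- rpois(reps, n1 * lambda)
  y0 <- rpois(reps, n0 * lambda)
  pvals <- vapply(seq_len(reps), function(i) {
    exact_rate_test(y1[i], n1, y0[i], n0)$p_two_sided
  }, 1)
  expect_lte(mean(pvals <= 0.05), 0.055)
})

test_that("weighted fit equals the closed-form normal equations", {
  set.seed(43)
  for (rep in 1:20) {
    n <- 40
    d <- data.frame(x1 = rnorm(n), x2 = runif(n),
                    sex = sample(c("M", "F"), n, TRUE))
    d$y <- 1 + 2 * d$x1 - 0.5 * d$x2 + (d$sex == "M") + rnorm(n)
    w <- runif(n, 0.2, 3)
    fit <- wls_fit(y ~ x1 + x2 + sex, d, weights = w)
    X <- model.matrix(y ~ x1 + x2 + sex, d)
    beta <- wls_oracle(X, d$y, w)
    expect_equal(unname(coef(fit)), unname(beta), tolerance = 1e-8)
    # weighted orthogonality of residuals to the design
    r <- residuals(fit)
    expect_lt(max(abs(t(X) %*% (w * r))) / max(abs(t(X) %*% (w * d$y))),
              1e-8)
  }
})

test_that("unit weights reduce the weighted fit to ordinary least squares", {
  set.seed(47)
  d <- data.frame(x = rnorm(30))
  d$y <- 2 + 3 * d$x + rnorm(30)
  fit <- wls_fit(y ~ x, d, weights = rep(1, 30))
  ols <- lm(y ~ x, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-12)
  # exactly linear outcome: zero residuals, vanishing p-values
  d$y <- 2 + 3 * d$x
  expect_warning(fit0 <- wls_fit(y ~ x, d, weights = rep(1, 30)),
                 "perfect fit")
  expect_lt(max(abs(residuals(fit0))), 1e-10)
})

test_that("group effects are recovered with age/sex adjustment", {
  set.seed(53)
  cover <- 0L
  reps <- 500
  for (rep in seq_len(reps)) {
    n <- 47
    d <- data.frame(
      group = factor(rep(c("IRRADIATED", "CONTROL"), c(36, 11)),
                     levels = c("CONTROL", "IRRADIATED")),
      age_months = runif(n, 12, 18),
      sex = sample(c("M", "F"), n, TRUE)
    )
    d$mye_pct <- 30 + 5 * (d$group == "IRRADIATED") + 0.5 * d$age_months +
      2 * (d$sex == "M") + rnorm(n, 0, ifelse(d$group == "IRRADIATED", 6, 3))
    fit <- wls_fit(mye_pct ~ group + age_months + sex, d)
    est <- fit$coefficients["groupIRRADIATED", ]
    if (abs(est[1] - 5) <= 2 * est[2]) cover <- cover + 1L
  }
  expect_gte(cover / reps, 0.95)
})

test_that("missing outcomes are dropped and singular designs error", {
  d <- data.frame(group = c("A", "A", "B", "B", "B"),
                  x = c(1, 2, 3, 4, 5))
  d$y <- c(1, NA, 3, 4, 5)
  expect_message(fit <- wls_fit(y ~ x, d, group_var = "group"), "dropped")
  expect_equal(fit$n, 4)
  expect_equal(fit$n_dropped, 1)
  d2 <- data.frame(x = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  expect_error(wls_fit(y ~ x + x2, d2, group_var = NULL), "singular")
})

test_that("Breusch-Pagan statistic matches the auxiliary-regression form", {
  set.seed(59)
  n <- 80
  X <- cbind(1, rnorm(n), runif(n))
  y <- X %*% c(1, 2, -1) + rnorm(n, 0, exp(X[, 2] / 2))
  r <- y - X %*% qr.solve(X, y)
  bp <- breusch_pagan(as.numeric(r), X)
  aux <- lm(as.numeric(r)^2 ~ X[, 2] + X[, 3])
  expect_equal(bp$bp_stat, n * summary(aux)$r.squared, tolerance = 1e-10)
  # cross-check against the reference implementation
  skip_if_not_installed("lmtest")
  d <- data.frame(y = as.numeric(y), a = X[, 2], b = X[, 3])
  ref <- lmtest::bptest(lm(y ~ a + b, d))
  fit <- lm(y ~ a + b, d)
  mine <- breusch_pagan(residuals(fit), model.matrix(fit))
  expect_equal(mine$bp_stat, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(mine$bp_p, unname(ref$p.value), tolerance = 1e-8)
  # degenerate: constant residuals
  expect_equal(breusch_pagan(rep(0.5, 10), cbind(1, 1:10))$bp_stat, 0)
})

test_that("Breusch-Pagan holds its size and has power against scaling", {
  set.seed(61)
  reps <- 2000; n <- 50
  rej <- 0L
  for (rep in seq_len(reps)) {
    X <- cbind(1, rnorm(n))
    y <- X %*% c(1, 1) + rnorm(n)  # homoskedastic null
    res <- y - X %*% qr.solve(X, y)
    if (breusch_pagan(as.numeric(res), X)$bp_p <= 0.05) rej <- rej + 1L
  }
  expect_gt(rej / reps, 0.030)
  expect_lt(rej / reps, 0.070)
  # power: residual variance proportional to a design column
  power_rej <- 0L
  for (rep in 1:200) {
    n2 <- 200
    X <- cbind(1, runif(n2, 1, 5))
    y <- X %*% c(1, 1) + rnorm(n2, 0, sqrt(X[, 2]))
    res <- y - X %*% qr.solve(X, y)
    if (breusch_pagan(as.numeric(res), X)$bp_p <= 0.05) power_rej <- power_rej + 1L
  }
  expect_gt(power_rej / 200, 0.5)
})
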