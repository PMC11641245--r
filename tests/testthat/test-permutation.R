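test_that("two-group fit is the difference of group means", {
  fit <- fit_two_group(c(0.1, 0.2, 0.4, 0.5), c(0, 0, 1, 1))
  expect_equal(fit$statistic, 0.30)
  expect_equal(unname(fit$coefficients["b0"]), 0.15)

  same <- fit_two_group(c(0.2, 0.4, 0.1, 0.5), c(0, 0, 1, 1))
  expect_equal(same$statistic, 0)

  # agreement with an independent least-squares solve on random inputs
  set.seed(10)
  for (i in 1:5) {
    y <- rnorm(12)
    g <- sample(rep(0:1, 6))
    want <- oracle_ols(cbind(1, g), y)
    fit <- fit_two_group(y, g)
    expect_equal(unname(fit$coefficients), unname(want), tolerance = 1e-10)
    expect_equal(sum(fit$residuals), 0, tolerance = 1e-10)
    expect_equal(sum(fit$residuals * g), 0, tolerance = 1e-10)
  }
  expect_error(fit_two_group(1:4, rep(1, 4)), "non-empty")
})

test_that("sampled permutation p follows (n+1)/(N+1) with ties counting", {
  # constant response: every shuffle ties the observed statistic
  res <- permutation_test_two_group(rep(0.3, 8), rep(0:1, 4), n_perm = 200,
                                    seed = 1)
  expect_equal(res$n, 200L)
  expect_equal(res$p, 1)

  y <- c(0, 0.05, 0.1, 0.4, 0.45, 0.5)
  g <- c(0, 0, 0, 1, 1, 1)
  res <- permutation_test_two_group(y, g, n_perm = 999, seed = 7)
  expect_equal(res$p, (res$n + 1) / (999 + 1))
  expect_true(res$p >= 1 / 1000 && res$p <= 1)
})

test_that("exhaustive enumeration gives the exact permutation distribution", {
  y <- c(0, 0, 0, 1, 1, 1)
  g <- c(0, 0, 0, 1, 1, 1)
  res <- exhaustive_two_group(y, g)
  expect_equal(res$n_perm, 20L)  # choose(6, 3)
  expect_equal(res$p, 1 / 20)   # only the observed assignment attains b1 = 1

  # label-exchange symmetric data: two-sided p = 1
  sym <- exhaustive_two_group(c(1, 2, 1, 2), c(0, 0, 1, 1),
                              alternative = "two.sided")
  expect_equal(sym$p, 1)

  expect_error(exhaustive_two_group(rnorm(25), rep(0:1, c(12, 13))), "bound")
})

test_that("sampled p converges to the exhaustive p within binomial error", {
  set.seed(30)
  for (sizes in list(c(3, 3), c(5, 5))) {
    y <- c(rnorm(sizes[1], 0), rnorm(sizes[2], 0.8))
    g <- rep(0:1, sizes)
    exact <- exhaustive_two_group(y, g)$p
    sampled <- permutation_test_two_group(y, g, n_perm = 1e5, seed = 31)$p
    se <- sqrt(exact * (1 - exact) / 1e5)
    expect_lt(abs(sampled - exact), 3 * se + 2 / 1e5)
  }
})

test_that("two-group test is invariant to affine rescaling of the response", {
  y <- c(0.02, 0.1, 0.07, 0.3, 0.25, 0.4)
  g <- c(0, 0, 0, 1, 1, 1)
  a <- permutation_test_two_group(y, g, n_perm = 499, seed = 5)
  b <- permutation_test_two_group(10 * y + 3, g, n_perm = 499, seed = 5)
  expect_equal(a$n, b$n)
  expect_equal(a$p, b$p)
})

test_that("interaction fit matches the saturated closed form and an OLS oracle", {
  fx <- fixture_interaction(means = c(p = 0.10, q = 0.20, double = 0.35))
  fit <- fit_interaction(fx$y, fx$ip, fx$iq)
  expect_equal(fit$statistic, 0.05, tolerance = 1e-12)

  additive <- fixture_interaction(means = c(p = 0.10, q = 0.20, double = 0.30))
  expect_equal(fit_interaction(additive$y, additive$ip, additive$iq)$statistic,
               0, tolerance = 1e-12)

  # b3 = mean(double) - mean(p) - mean(q) on noisy inputs too
  set.seed(8)
  noisy <- fixture_interaction(noise = 0.05)
  fit <- fit_interaction(noisy$y, noisy$ip, noisy$iq)
  only_p <- noisy$ip == 1 & noisy$iq == 0
  only_q <- noisy$ip == 0 & noisy$iq == 1
  both <- noisy$ip == 1 & noisy$iq == 1
  expect_equal(fit$statistic,
               mean(noisy$y[both]) - mean(noisy$y[only_p]) -
                 mean(noisy$y[only_q]),
               tolerance = 1e-10)
  want <- oracle_ols(cbind(noisy$ip, noisy$iq, noisy$ip * noisy$iq), noisy$y)
  expect_equal(unname(fit$coefficients), unname(want), tolerance = 1e-10)

  # a missing genotype group makes the no-intercept design rank-deficient
  expect_error(fit_interaction(rnorm(4), c(1, 1, 1, 1), c(1, 1, 1, 1)),
               "rank-deficient")
})

test_that("Smith orthogonalization removes the nuisance projection exactly", {
  x <- cbind(rep(c(1, 0, 1), each = 4), rep(c(0, 1, 1), each = 4))
  z <- as.numeric(x[, 1] * x[, 2])
  zres <- smith_orthogonalize(x, z)
  expect_equal(as.numeric(t(x) %*% zres), c(0, 0), tolerance = 1e-12)

  # already-orthogonal target returned unchanged; nuisance column -> zero
  z_orth <- c(1, -1, 0, 0, rep(0, 8))
  z_orth <- z_orth - mean(z_orth)
  x1 <- matrix(rep(1, 12), ncol = 1)
  expect_equal(smith_orthogonalize(x1, z_orth), z_orth, tolerance = 1e-12)
  expect_equal(smith_orthogonalize(x, x[, 1]), rep(0, 12), tolerance = 1e-12)

  # norm matches residuals from an independent regression of z on x
  resid_oracle <- z - x %*% oracle_ols(x, z)
  expect_equal(sum(zres^2), sum(resid_oracle^2), tolerance = 1e-10)

  expect_error(smith_orthogonalize(cbind(x[, 1], x[, 1]), z), "dependent")
})

test_that("interaction permutation test flags synergy and respects the floor", {
  set.seed(9)
  synergy <- fixture_interaction(n_each = 8,
                                 means = c(p = 0.05, q = 0.05, double = 0.6),
                                 noise = 0.01)
  res <- permutation_test_interaction(synergy$y, synergy$ip, synergy$iq,
                                      n_perm = 499, seed = 2)
  expect_equal(res$p, (res$n + 1) / 500)
  expect_lt(res$p, 0.05)

  # observed statistic equals b3 from the direct no-intercept fit
  expect_equal(res$statistic,
               fit_interaction(synergy$y, synergy$ip, synergy$iq)$statistic,
               tolerance = 1e-10)
})

test_that("type-I error of both permutation tests is calibrated at alpha = 0.05", {
  # two-group: identical simulated rates in both groups
  n_rep <- 150
  alpha <- 0.05
  set.seed(123)
  rej2 <- 0
  for (r in seq_len(n_rep)) {
    y <- rbeta(20, 1, 8)
    g <- rep(0:1, each = 10)
    p <- permutation_test_two_group(y, g, n_perm = 400)$p
    rej2 <- rej2 + (p <= alpha)
  }
  se <- sqrt(alpha * (1 - alpha) / n_rep)
  expect_lt(abs(rej2 / n_rep - alpha), 3 * se)

  # interaction: additive effects, b3 = 0
  set.seed(124)
  reji <- 0
  for (r in seq_len(n_rep)) {
    fx <- fixture_interaction(n_each = 8,
                              means = c(p = 0.1, q = 0.1, double = 0.2),
                              noise = 0.05)
    p <- permutation_test_interaction(fx$y, fx$ip, fx$iq, n_perm = 400)$p
    reji <- reji + (p <= alpha)
  }
  expect_lt(abs(reji / n_rep - alpha), 3 * se)
})

test_that("power rises monotonically with the simulated effect size", {
  set.seed(55)
  rates_grid <- c(0, 0.1, 0.3)
  power <- vapply(rates_grid, function(shift) {
    mean(replicate(60, {
      y <- c(rbeta(8, 1, 12), rbeta(8, 1, 12) + shift)
      permutation_test_two_group(y, rep(0:1, each = 8), n_perm = 200)$p <= 0.05
    }))
  }, numeric(1))
  expect_true(all(diff(power) >= -0.05))  # non-decreasing up to MC noise
  expect_gt(power[3], power[1])
})
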