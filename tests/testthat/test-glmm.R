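test_that("specification validates, drops constants and aliased columns", {
  y <- c(0, 1, 0, 1, 1, 0)
  X <- cbind(1, x = c(1, 2, 3, 4, 5, 6), z = 2, x2 = c(2, 4, 6, 8, 10, 12))
  sp <- glmm_spec(y, X, rep(c("a", "b"), 3))
  expect_setequal(sp$dropped, c("z", "x2"))
  expect_equal(colnames(sp$X), c("(Intercept)", "x"))
  expect_error(glmm_spec(c(0, 2, 1), cbind(1), rep("a", 3)), "binary")
  expect_error(glmm_spec(y, X[1:3, ], rep("a", 6)), "dimensions")
})

test_that("sigma = 0 data give near-logistic fits; boundary fits are exact", {
  n_boundary <- 0L
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 1500
      x <- rnorm(n)
      grp <- sample(sprintf("g%02d", 1:25), n, TRUE)
      y <- rbinom(n, 1, plogis(-0.4 + 0.7 * x))   # no group effect
    })
    sp <- glmm_spec(y, cbind(1, x = x), grp)
    fit <- fit_glmm(sp)
    ml <- glm.fit(sp$X, y, family = binomial())
    se <- sqrt(diag(chol2inv(chol(
      crossprod(sp$X * sqrt(ml$fitted.values * (1 - ml$fitted.values)))))))
    # always within 3 SE of the logistic oracle, sigma-hat near 0
    expect_lt(max(abs(fit$beta - ml$coefficients) / se), 3)
    expect_lt(fit$sigma, 0.5)
    if (fit$sigma == 0) {
      n_boundary <- n_boundary + 1L
      # boundary fits ARE the logistic MLE
      expect_lt(max(abs(fit$beta - ml$coefficients)), 1e-6)
      expect_equal(fit$loglik,
                   sum(y * sp$X %*% ml$coefficients -
                         log1p(exp(sp$X %*% ml$coefficients))),
                   tolerance = 1e-8)
    }
  }
  expect_gte(n_boundary, 1L)   # the boundary is actually exercised
})

test_that("a perfectly balanced intercept-only fit gives beta0 = 0, sigma = 0", {
  y <- rep(c(0, 1), 30)
  grp <- rep(sprintf("g%d", 1:5), each = 12)   # 50% ones in every group
  fit <- fit_glmm(glmm_spec(y, matrix(1, 60, 1,
                                      dimnames = list(NULL, "(Intercept)")), grp))
  expect_lt(abs(fit$beta[1]), 1e-6)
  expect_equal(fit$sigma, 0)
})

test_that("the Laplace objective agrees with adaptive Gauss-Hermite on toys", {
  for (seed in 1:4) {
    sp <- toy_glmm_data(n_groups = 3 + seed %% 3, per_group = 12,
                        sigma = 0.3, seed = seed)
    fit <- fit_glmm(sp)
    for (sig in c(0.15, 0.3)) {
      lap <- loglik_laplace(sp, fit$beta, sig)
      agq <- loglik_quadrature(sp, fit$beta, sig, 30)
      expect_lt(abs(lap - agq), 5e-3)
    }
  }
})

test_that("the quadrature oracle is exact, stable and locally maximal", {
  sp <- toy_glmm_data(n_groups = 4, per_group = 12, sigma = 0.4, seed = 9)
  fit <- fit_glmm(sp)

  # sigma = 0 degenerates to the Bernoulli log-likelihood
  eta <- sp$X %*% fit$beta
  expect_equal(loglik_quadrature(sp, fit$beta, 0),
               sum(sp$y * eta - log1p(exp(eta))), tolerance = 1e-12)

  # node-count stability
  expect_lt(abs(loglik_quadrature(sp, fit$beta, 0.4, 20) -
                loglik_quadrature(sp, fit$beta, 0.4, 40)), 1e-8)

  expect_error(loglik_quadrature(sp, fit$beta, -0.1), "non-negative")

  # moving beta away from the optimum lowers the objective
  sig <- max(fit$sigma, 0.05)
  base <- loglik_quadrature(sp, fit$beta, sig, 30)
  for (j in seq_along(fit$beta)) {
    for (delta in c(-0.6, 0.6)) {
      b <- fit$beta; b[j] <- b[j] + delta
      expect_lt(loglik_quadrature(sp, b, sig, 30), base + 1e-8)
    }
  }
})

test_that("dispersion ratio is near 1 when the model is well specified", {
  ratios <- vapply(1:20, function(i) {
    withr::with_seed(100 + i, {
      n <- 2000; G <- 40
      grp <- rep(sprintf("g%02d", 1:G), each = n / G)
      x <- rnorm(n)
      u <- rnorm(G, sd = 0.5)
      y <- rbinom(n, 1, plogis(-0.3 + 0.5 * x + u[as.integer(factor(grp))]))
    })
    fit_glmm(glmm_spec(y, cbind(1, x = x), grp))$dispersion
  }, numeric(1))
  expect_gte(mean(ratios > 0.9 & ratios < 1.1), 0.95)
})

test_that("dispersion ratio collapses towards 0 in the saturated limit", {
  y <- rep(c(0, 1), 20)
  fake <- structure(list(eta = ifelse(y == 1, 8, -8), p_fixed = 2),
                    class = "glmm_fit")
  sp <- glmm_spec(y, cbind(1, x = rnorm(40)), rep("a", 40))
  expect_lt(dispersion_ratio(fake, sp), 0.05)
})

test_that("likelihood-ratio tests follow the chi-square reference", {
  sp <- toy_glmm_data(seed = 3)
  fit <- fit_glmm(sp)
  same <- likelihood_ratio_test(fit, fit, df = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  fake_null <- fit; fake_alt <- fit
  fake_alt$loglik <- fit$loglik + 3.84 / 2
  lrt <- likelihood_ratio_test(fake_null, fake_alt, df = 1)
  expect_equal(lrt$p_value, 0.05, tolerance = 2e-3)

  fake_alt$loglik <- fit$loglik - 1
  expect_warning(likelihood_ratio_test(fake_null, fake_alt, df = 1),
                 "below null")
})

test_that("the objective is invariant to zero columns and predictor rescaling", {
  withr::with_seed(13, {
    n <- 600
    x <- rnorm(n); w <- rnorm(n)
    grp <- rep(sprintf("g%02d", 1:12), each = 50)
    u <- rnorm(12, sd = 0.6)
    y <- rbinom(n, 1, plogis(0.2 + 0.6 * x + u[as.integer(factor(grp))]))
  })
  f1 <- fit_glmm(glmm_spec(y, cbind(1, x = x, w = w), grp))
  f2 <- fit_glmm(glmm_spec(y, cbind(1, x = x, w = w, zero = 0), grp))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)

  # affine rescaling of a predictor leaves the LRT unchanged
  null <- fit_glmm(glmm_spec(y, cbind(1, w = w), grp))
  alt_a <- fit_glmm(glmm_spec(y, cbind(1, w = w, x = x), grp))
  alt_b <- fit_glmm(glmm_spec(y, cbind(1, w = w, x = 10 * x + 3), grp))
  sa <- likelihood_ratio_test(null, alt_a, 1)$statistic
  sb <- likelihood_ratio_test(null, alt_b, 1)$statistic
  expect_equal(sa, sb, tolerance = 1e-6)
})

test_that("fits recover injected effects and match lme4 on a shared fixture", {
  est <- vapply(1:5, function(i) {
    withr::with_seed(200 + i, {
      n <- 5000; G <- 50
      grp <- rep(sprintf("g%02d", 1:G), each = n / G)
      zc <- rnorm(G)                 # group-level predictor, 1 SD scale
      x <- zc[as.integer(factor(grp))]
      u <- rnorm(G, sd = 0.5)
      y <- rbinom(n, 1, plogis(-0.2 + 1.0 * x + u[as.integer(factor(grp))]))
    })
    fit_glmm(glmm_spec(y, cbind(1, x = x), grp))$beta["x"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.0), 0.1)

  skip_if_not_installed("lme4")
  withr::with_seed(42, {
    n <- 2000; G <- 40
    grp <- rep(sprintf("g%02d", 1:G), each = n / G)
    x <- rnorm(n)
    u <- rnorm(G, sd = 0.8)
    y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x + u[as.integer(factor(grp))]))
  })
  ours <- fit_glmm(glmm_spec(y, cbind(1, x = x), grp))
  m <- lme4::glmer(y ~ x + (1 | grp), family = binomial,
                   control = lme4::glmerControl(optimizer = "bobyqa"))
  expect_equal(ours$loglik, as.numeric(stats::logLik(m)), tolerance = 0.05)
  expect_equal(ours$sigma, sqrt(unlist(lme4::VarCorr(m))[[1]]), tolerance = 0.05)
  expect_lt(max(abs(ours$beta - lme4::fixef(m))), 0.05)
})

test_that("the BOBYQA polish never lowers the Laplace objective", {
  sp <- toy_glmm_data(n_groups = 5, per_group = 12, sigma = 0.6, seed = 21)
  prof <- fit_glmm(sp, method = "profile")
  bob <- fit_glmm(sp, method = "bobyqa")
  expect_gte(bob$loglik, prof$loglik - 1e-8)
})
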