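test_that("information criteria follow the Akaike/Schwarz forms", {
  ic <- informationCriteria(-100, 3, 100)
  expect_equal(ic$aic, 206)
  expect_equal(ic$bic, 200 + 3 * log(100))
  # ln(1) = 0 edge
  ic2 <- informationCriteria(0, 1, 1)
  expect_equal(ic2$aic, 2)
  expect_equal(ic2$bic, 0)
  expect_error(informationCriteria(0, 0, 10), ">= 1")
  # non-finite log-likelihood propagates to missing criteria
  ic3 <- informationCriteria(NA_real_, 2, 10)
  expect_true(is.na(ic3$aic) && is.na(ic3$bic))
})

test_that("fixed-only ML fits match the OLS closed form", {
  # intercept-only on y = (-1, 1): beta = 0, sigma^2 = 1
  f0 <- fitFixedOnly(parseFormula("Y ~ 1"), data.frame(Y = c(-1, 1)))
  expect_equal(f0$loglik, -(log(2 * pi) + 1), tolerance = 1e-12)
  expect_identical(f0$n_params, 2L)  # intercept + residual variance
  expect_true(f0$converged)
  expect_false(f0$singular)

  # closed form -(N/2)(ln(2 pi sigma2_ML) + 1) on arbitrary designs
  set.seed(5)
  for (i in 1:5) {
    n <- sample(20:60, 1)
    d <- data.frame(Y = rnorm(n), X1 = rnorm(n), X2 = rnorm(n))
    f <- fitFixedOnly(parseFormula("Y ~ X1 + X2"), d)
    res <- stats::lm(Y ~ X1 + X2, d)$residuals
    s2 <- sum(res^2) / n
    expect_equal(f$loglik, -(n / 2) * (log(2 * pi * s2) + 1),
                 tolerance = 1e-10)
    # the stored criteria satisfy the arithmetic identities exactly
    expect_identical(f$aic, -2 * f$loglik + 2 * f$n_params)
    expect_identical(f$bic, -2 * f$loglik + f$n_params * log(f$n_obs))
  }
})

test_that("fixed-only fit recovers generating coefficients at n = 500", {
  set.seed(9)
  n <- 500
  d <- data.frame(X1 = rnorm(n), X2 = rnorm(n))
  beta <- c(1, 0.8, -0.5)
  d$Y <- beta[1] + beta[2] * d$X1 + beta[3] * d$X2 + rnorm(n)
  m <- parseFormula("Y ~ X1 + X2")
  fit <- stats::lm(Y ~ X1 + X2, d)
  est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(est - beta) < 3 * se))
  # and the package fit agrees with lm's likelihood
  expect_equal(fitFixedOnly(m, d)$loglik, as.numeric(stats::logLik(fit)))
})

test_that("fixed-only fit errors are specific", {
  d <- data.frame(Y = rnorm(10), X1 = rnorm(10))
  d$X2 <- d$X1  # collinear
  expect_error(fitFixedOnly(parseFormula("Y ~ X1 + X2"), d), "rank-deficient")
  expect_error(fitFixedOnly(parseFormula("Y ~ X1"), d[1:2, ]),
               "not enough observations")
  d3 <- data.frame(Y = 2 * (1:10), X1 = 1:10)  # perfect fit
  expect_error(fitFixedOnly(parseFormula("Y ~ X1"), d3),
               "zero residual variance")
})

test_that("LMM log-likelihood matches a direct maximization of the marginal likelihood", {
  d <- toyGroupedData()
  # random intercept only (q = 1)
  m1 <- parseFormula("Y ~ X1 + (1 | G)")
  f1 <- fitLMM(m1, d)
  X <- cbind(1, d$X1)
  ll1 <- oracleMarginalLL(d$Y, X, matrix(1, nrow(d), 1), d$G)
  expect_equal(f1$loglik, ll1, tolerance = 1e-4)
  expect_identical(f1$n_params, 2L + 1L + 1L)

  # correlated intercept + slope (q = 2)
  m2 <- parseFormula("Y ~ X1 + (1 + X1 | G)")
  f2 <- fitLMM(m2, d)
  ll2 <- oracleMarginalLL(d$Y, X, X, d$G)
  expect_equal(f2$loglik, ll2, tolerance = 1e-4)
  expect_identical(f2$n_params, 2L + 3L + 1L)
})

test_that("LMM fits agree with the oracle across random toy datasets", {
  for (seed in c(2, 3, 4, 5, 6)) {
    d <- quickGrouped(seed, n_groups = 5, size = 8)
    f <- fitLMM(parseFormula("Y ~ X1 + (1 | G)"), d)
    ll <- oracleMarginalLL(d$Y, cbind(1, d$X1), matrix(1, nrow(d), 1), d$G)
    expect_equal(f$loglik, ll, tolerance = 1e-4, info = paste("seed", seed))
  }
})

test_that("a zero-variance random intercept collapses to the fixed-only fit", {
  set.seed(21)
  n <- 200
  d <- data.frame(X1 = rnorm(n), G = factor(rep(1:10, each = 20)))
  d$Y <- 1 + 0.5 * d$X1 + rnorm(n)  # no group effect at all
  lmm <- fitLMM(parseFormula("Y ~ X1 + (1 | G)"), d)
  ols <- fitFixedOnly(parseFormula("Y ~ X1"), d)
  expect_true(lmm$singular)
  expect_equal(lmm$loglik, ols$loglik, tolerance = 1e-6)
})

test_that("variance components are recovered on strong synthetic data", {
  psi <- matrix(c(1, 0, 0, 0.25), 2, 2,
                dimnames = rep(list(c("(Intercept)", "X1")), 2))
  spec <- simSpec(n_groups = 40, group_sizes = 50,
                  beta = list("(Intercept)" = 0, X1 = 1),
                  psi = psi, sigma = 1, response = "Y", group = "G",
                  seed = 33)
  d <- simulateDataset(spec)
  fit <- lme4::lmer(Y ~ X1 + (1 + X1 | G), data = d, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau0 <- vc$vcov[vc$grp == "G" & vc$var1 == "(Intercept)" & is.na(vc$var2)]
  tau1 <- vc$vcov[vc$grp == "G" & vc$var1 == "X1" & is.na(vc$var2)]
  expect_lt(abs(tau0 - 1) / 1, 0.25)
  expect_lt(abs(tau1 - 0.25) / 0.25, 0.25)
  # and the package's wrapper reports the same maximized likelihood
  f <- fitLMM(parseFormula("Y ~ X1 + (1 + X1 | G)"), d)
  expect_equal(f$loglik, as.numeric(stats::logLik(fit)), tolerance = 1e-8)
})

test_that("likelihoods are invariant to group relabeling and row order", {
  d <- quickGrouped(14, n_groups = 6, size = 10)
  m <- parseFormula("Y ~ X1 + (1 + X1 | G)")
  base <- fitLMM(m, d)
  shuffled <- d[sample(nrow(d)), ]
  relabeled <- shuffled
  relabeled$G <- factor(paste0("z", relabeled$G))
  expect_equal(fitLMM(m, shuffled)$loglik, base$loglik, tolerance = 1e-8)
  expect_equal(fitLMM(m, relabeled)$loglik, base$loglik, tolerance = 1e-8)
})

test_that("adding a predictor never decreases the fixed-only likelihood", {
  set.seed(88)
  d <- data.frame(Y = rnorm(80), X1 = rnorm(80), X2 = rnorm(80),
                  X3 = rnorm(80))
  cs <- enumerateCandidates(parseFormula("Y ~ X1 + X2 + X3"))
  lls <- vapply(cs$candidates, function(m) fitFixedOnly(m, d)$loglik,
                numeric(1))
  terms <- lapply(cs$candidates, function(m) m$term_order)
  for (i in seq_along(terms)) {
    for (j in seq_along(terms)) {
      if (i != j && all(terms[[i]] %in% terms[[j]]))
        expect_gte(lls[j] + 1e-10, lls[i])
    }
  }
})

test_that("BIC prefers the generating slope model over intercept-only under strong slopes", {
  # slope SD = residual SD, 40 groups: BIC of the generating random-slope
  # model should beat the random-intercept-only model in >= 90% of replicates
  wins <- 0L
  for (rep in 1:20) {
    d <- quickGrouped(1000 + rep, n_groups = 40, size = 25,
                      beta1 = 1, tau0 = 1, tau1 = 1, sigma = 1)
    f_slope <- fitLMM(parseFormula("Y ~ X1 + (1 + X1 | G)"), d)
    f_ri <- fitLMM(parseFormula("Y ~ X1 + (1 | G)"), d)
    if (f_slope$bic < f_ri$bic) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("categorical predictors expand to levels - 1 coefficients in the count", {
  set.seed(71)
  n <- 120
  d <- data.frame(X1 = rnorm(n),
                  edu = sample(c("low", "mid", "high"), n, replace = TRUE),
                  G = factor(rep(1:6, each = 20)))
  d$Y <- 0.3 * d$X1 + (d$edu == "mid") * 0.5 + rnorm(n) +
    rnorm(6)[as.integer(d$G)]
  # edu enters as one term but contributes 2 coefficients
  f <- fitFixedOnly(parseFormula("Y ~ X1 + edu", forced = "edu"), d)
  expect_identical(f$n_params, 1L + 1L + 2L + 1L)
  flmm <- fitLMM(parseFormula("Y ~ X1 + edu + (1 + X1 | G)", forced = "edu"), d)
  expect_identical(flmm$n_params, 4L + 3L + 1L)
  # n_params convention agrees with the fitter's own likelihood df
  ref <- lme4::lmer(Y ~ X1 + edu + (1 + X1 | G), data = d, REML = FALSE)
  expect_identical(flmm$n_params, as.integer(attr(stats::logLik(ref), "df")))
})

test_that("few-observations-per-group and single-group cases are signalled", {
  d <- quickGrouped(3, n_groups = 3, size = 1)
  expect_warning(fitLMM(parseFormula("Y ~ X1 + (1 + X1 | G)"), d),
                 "fewer observations")
  d1 <- data.frame(Y = rnorm(20), X1 = rnorm(20), G = "only")
  expect_error(fitLMM(parseFormula("Y ~ X1 + (1 | G)"), d1),
               "fewer than 2 groups")
})
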