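# one shared small exploration: 13-candidate space on seeded grouped data
psi_x1 <- matrix(c(1, 0.3, 0.3, 1), 2, 2,
                 dimnames = rep(list(c("(Intercept)", "X1")), 2))
spec_small <- simSpec(n_groups = 12, group_sizes = 25,
                      beta = list("(Intercept)" = 0, X1 = 1, X2 = 0, X3 = 0.5),
                      psi = psi_x1, sigma = 1, response = "Y", group = "G",
                      forced = "X3", seed = 202)
data_small <- simulateDataset(spec_small)
full_small <- simFullModel(spec_small)
tab_small <- exploreModels(data_small, full_small, workers = 1)

test_that("exploreModels returns one row per candidate in enumeration order", {
  expect_s3_class(tab_small, "mlm_exploration")
  expect_identical(nrow(tab_small), 13L)
  expect_identical(tab_small$formula,
                   candidateFormulas(enumerateCandidates(full_small)))
  meta <- explorationMeta(tab_small)
  expect_identical(meta$n_candidates, 13L)
  expect_identical(meta$n_obs, 300)
  expect_identical(meta$n_groups, 12L)
  # stored criteria satisfy their identities row-wise
  expect_equal(tab_small$AIC, -2 * tab_small$logLik + 2 * tab_small$n_params,
               tolerance = 1e-12)
  expect_equal(tab_small$BIC,
               -2 * tab_small$logLik + tab_small$n_params * log(meta$n_obs),
               tolerance = 1e-12)
})

test_that("results are identical for any worker count", {
  tab4 <- exploreModels(data_small, full_small, workers = 4)
  meta1 <- explorationMeta(tab_small)
  meta4 <- explorationMeta(tab4)
  expect_identical(meta4$workers, 4L)
  expect_identical(tab4$formula, tab_small$formula)
  for (col in c("logLik", "AIC", "BIC"))
    expect_equal(tab4[[col]], tab_small[[col]], tolerance = 1e-10)
  expect_identical(tab4$converged, tab_small$converged)
  expect_identical(tab4$singular, tab_small$singular)
  expect_identical(meta1$n_obs, meta4$n_obs)
})

test_that("sortResult orders by the chosen criterion with documented tie-breaks", {
  by_bic <- sortResult(tab_small)  # default criterion is BIC
  expect_identical(explorationMeta(by_bic)$sorted_by, "BIC")
  expect_false(is.unsorted(by_bic$BIC))
  by_aic <- sortResult(tab_small, "AIC")
  expect_false(is.unsorted(by_aic$AIC))
  by_ll <- sortResult(tab_small, "LL")
  expect_false(is.unsorted(-by_ll$logLik))
  expect_error(sortResult(tab_small, "R2"), "arg")

  # equal criterion values: fewer parameters first, then formula string
  fake <- tab_small
  fake$BIC <- rep(1, nrow(fake))
  sorted <- sortResult(fake)
  expect_false(is.unsorted(sorted$n_params))

  # failed fits (missing criteria) sort last
  fake2 <- tab_small
  fake2$BIC[1] <- NA
  expect_identical(utils::tail(sortResult(fake2)$formula, 1),
                   tab_small$formula[1])
})

test_that("the full model has the best log-likelihood among nested candidates", {
  by_ll <- sortResult(tab_small, "LL")
  # every other candidate's fixed and random structure nests in the full
  # model's, so ML monotonicity puts the full model first
  expect_identical(by_ll$formula[1], renderFormula(full_small))
})

test_that("bestModels caps k at the table size", {
  b1 <- bestModels(tab_small, 1)
  expect_identical(nrow(b1), 1L)
  expect_identical(b1$BIC, min(tab_small$BIC))
  ball <- bestModels(tab_small, 999)
  expect_identical(nrow(ball), 13L)
})

test_that("missing data are dropped once so all candidates share rows", {
  d <- data_small
  d$X1[c(3, 50)] <- NA
  d$Y[7] <- NA
  tab <- exploreModels(d, full_small, workers = 1)
  expect_identical(explorationMeta(tab)$n_obs, 297)
})

test_that("exploration errors are informative", {
  expect_error(exploreModels(data_small[0, ], full_small), "no complete rows")
  expect_error(exploreModels(data_small[, 1:3], full_small), "not found")
  d1 <- data_small
  d1$G <- "same"
  expect_error(exploreModels(d1, full_small), "constant|2 groups")
  expect_error(exploreModels(data_small, full_small, workers = 0),
               "positive integer")
  expect_warning(exploreModels(data_small, full_small, reml = TRUE),
                 "REML")
})

test_that("exploration tables round-trip through CSV + JSON sidecar", {
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  sorted <- sortResult(tab_small)
  writeExploration(sorted, csv, meta_path = js)
  back <- readExploration(csv, js)
  expect_identical(back$formula, sorted$formula)
  expect_equal(back$BIC, sorted$BIC, tolerance = 1e-6)
  expect_identical(back$n_params, sorted$n_params)
  expect_identical(back$converged, sorted$converged)
  meta <- explorationMeta(back)
  expect_identical(meta$full_formula, explorationMeta(sorted)$full_formula)
  expect_identical(meta$n_obs, 300L)
})
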