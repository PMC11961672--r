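# unit tests for WT normalization, model fitting, BIC selection and
# predictive quantiles

test_that("normalizeToWT divides by the per-batch WT mean", {
  d <- data.frame(batch = "A", replicate = 1:3,
                  x1 = c(1, 1, 0), x2 = c(1, 1, 0),
                  expression = c(2, 4, 1.5))
  out <- normalizeToWT(d)
  expect_equal(out$expression, c(2 / 3, 4 / 3, 0.5))
  expect_equal(out[c("x1", "x2")], d[c("x1", "x2")])

  # identical values normalize to 1
  d2 <- data.frame(batch = "B", replicate = 1:4,
                   x1 = c(1, 1, 0, 0), x2 = c(1, 1, 1, 0),
                   expression = rep(7, 4))
  expect_equal(normalizeToWT(d2)$expression, rep(1, 4))
})

test_that("normalization removes batch scale and is idempotent", {
  base <- data.frame(replicate = 1:4, x1 = c(1, 1, 0, 0), x2 = c(1, 1, 0, 1),
                     expression = c(9, 11, 4, 6))
  d <- rbind(cbind(batch = "b1", base, deparse.level = 0),
             transform(cbind(batch = "b2", base, deparse.level = 0),
                       expression = expression * 10))
  names(d)[1] <- "batch"
  out <- normalizeToWT(d)
  expect_equal(out$expression[d$batch == "b1"], out$expression[d$batch == "b2"])
  expect_equal(normalizeToWT(out)$expression, out$expression)
  # WT grand mean is 1 after normalization
  expect_equal(mean(out$expression[out$x1 == 1 & out$x2 == 1]), 1)
})

test_that("normalization errors on missing or degenerate WT reference", {
  noWt <- data.frame(batch = "A", replicate = 1, x1 = 0, x2 = 1, expression = 2)
  expect_error(normalizeToWT(noWt), "no wild-type")
  zeroWt <- data.frame(batch = "A", replicate = 1:2, x1 = c(1, 0), x2 = c(1, 0),
                       expression = c(0, 2))
  expect_error(normalizeToWT(zeroWt), "not positive")
})

test_that("additive fit equals the closed-form least-squares oracle", {
  for (s in 1:5) {
    d <- normalizeToWT(simulateExpressionData(
      "additive", c(b0 = 0.2, b1 = 0.5, b2 = 0.3), sigma = 0.05, seed = s))
    fit <- fitEnhancerModel(d, "additive", seed = s)
    ols <- lm(expression ~ x1 + x2, data = d)
    expect_equal(unname(coef(fit)[c("b0", "b1", "b2")]), unname(coef(ols)),
                 tolerance = 1e-8)
    # ML sigma uses n, not n - p
    expect_equal(residualSigma(fit), sqrt(sum(ols$residuals^2) / nrow(d)),
                 tolerance = 1e-10)
  }
})

test_that("noiseless constant data give a constant additive fit", {
  d <- data.frame(x1 = c(1, 1, 0, 0), x2 = c(1, 0, 1, 0), expression = 1)
  fit <- fitEnhancerModel(d, "additive")
  expect_equal(unname(coef(fit)), c(1, 0, 0), tolerance = 1e-10)
})

test_that("additive recovery lies within 3 standard errors of truth", {
  truth <- c(b0 = 0.2, b1 = 0.5, b2 = 0.3)
  d <- normalizeToWT(simulateExpressionData("additive", truth, sigma = 0.05,
                                            repsPerGenotype = 6, seed = 11))
  fit <- fitEnhancerModel(d, "additive")
  se <- summary(lm(expression ~ x1 + x2, data = d))$coefficients[, "Std. Error"]
  expect_true(all(abs(coef(fit) - truth) <= 3 * se))
})

test_that("logistic fit beats the truth in likelihood and recovers parameters", {
  truth <- c(b0 = -1, b1 = 2, b2 = 1, g = 2)
  d <- normalizeToWT(simulateExpressionData("logistic", truth, sigma = 0.05,
                                            repsPerGenotype = 12, seed = 3))
  fit <- fitEnhancerModel(d, "logistic", seed = 3)
  # ML optimum cannot be worse than the data-generating parameters
  rssTruth <- sum((d$expression - modelMean("logistic", truth, d$x1, d$x2))^2)
  rssFit <- fit@nObs * residualSigma(fit)^2
  expect_lte(rssFit, rssTruth + 1e-6)
  # brute-force refinement around the optimum finds nothing better
  co <- coef(fit)
  grid <- expand.grid(db = seq(-0.05, 0.05, length.out = 5),
                      d1 = seq(-0.05, 0.05, length.out = 5),
                      d2 = seq(-0.05, 0.05, length.out = 5),
                      dg = seq(-0.02, 0.02, length.out = 5))
  gridRss <- apply(grid, 1, function(dd) {
    cc <- c(b0 = co[["b0"]] + dd[[1]], b1 = co[["b1"]] + dd[[2]],
            b2 = co[["b2"]] + dd[[3]], g = co[["g"]] + dd[[4]])
    sum((d$expression - modelMean("logistic", cc, d$x1, d$x2))^2)
  })
  expect_lte(rssFit, min(gridRss) + 1e-8)
  expect_true(all(abs(coef(fit)[c("b1", "b2")] - truth[c("b1", "b2")]) < 0.5))
})

test_that("exponential fit matches a grid-search oracle on its objective", {
  # fit the raw scale: WT-normalization would shift b0 by -log(WT mean)
  truth <- c(b0 = 0, b1 = 1.2, b2 = 0.8)
  d <- simulateExpressionData("exponential", truth, sigma = 0.05, seed = 7)
  fit <- fitEnhancerModel(d, "exponential", seed = 7)
  rssFit <- fit@nObs * residualSigma(fit)^2
  grid <- expand.grid(b0 = seq(-0.3, 0.3, length.out = 13),
                      b1 = seq(0.8, 1.6, length.out = 17),
                      b2 = seq(0.4, 1.2, length.out = 17))
  gridRss <- apply(grid, 1, function(b)
    sum((d$expression - exp(b[1] + b[2] * d$x1 + b[3] * d$x2))^2))
  expect_lte(rssFit, min(gridRss) + 1e-8)
  expect_true(all(abs(coef(fit) - truth) < 0.3))
})

test_that("noiseless fits attain the generating parameters' likelihood", {
  for (m in c("additive", "exponential", "logistic")) {
    co <- switch(m, additive = c(b0 = 0.2, b1 = 0.5, b2 = 0.3),
                 exponential = c(b0 = 0, b1 = 0.8, b2 = 0.4),
                 logistic = c(b0 = -1, b1 = 2, b2 = 1, g = 2))
    d <- simulateExpressionData(m, co, sigma = 0, repsPerGenotype = 6, seed = 1)
    fit <- fitEnhancerModel(d[, c("x1", "x2", "expression")], m, seed = 1)
    rssTruth <- sum((d$expression - modelMean(m, co, d$x1, d$x2))^2)
    rssFit <- sum((d$expression -
                     modelMean(m, coef(fit), d$x1, d$x2))^2)
    expect_lte(rssFit, rssTruth + 1e-6)
  }
})

test_that("stored BIC matches its definition and swapping enhancers swaps b1/b2", {
  d <- normalizeToWT(simulateExpressionData(
    "additive", c(b0 = 0.1, b1 = 0.6, b2 = 0.2), sigma = 0.05, seed = 5))
  for (m in c("additive", "exponential", "logistic")) {
    fit <- fitEnhancerModel(d, m, seed = 5)
    expect_equal(BIC(fit), fit@nPar * log(fit@nObs) - 2 * logLik(fit))
    swapped <- d
    swapped$x1 <- d$x2; swapped$x2 <- d$x1
    fitSw <- fitEnhancerModel(swapped, m, seed = 5)
    tol <- if (m == "additive") 1e-10 else 1e-5
    expect_equal(coef(fitSw)[["b1"]], coef(fit)[["b2"]], tolerance = tol)
    expect_equal(coef(fitSw)[["b2"]], coef(fit)[["b1"]], tolerance = tol)
  }
})

test_that("fitting preconditions are enforced", {
  tiny <- data.frame(x1 = c(1, 1, 0), x2 = c(1, 0, 0), expression = c(1, 0.5, 0.2))
  expect_error(fitEnhancerModel(tiny, "additive"), "underdetermined")
  twoGeno <- data.frame(x1 = c(1, 1, 0, 0), x2 = c(1, 1, 0, 0),
                        expression = c(1, 1.1, 0.2, 0.3))
  expect_error(fitEnhancerModel(twoGeno, "additive"), "3 distinct genotypes")
})

test_that("BIC selection applies the threshold rule", {
  fits <- list(additive = fitWithBIC("additive", -10),
               exponential = fitWithBIC("exponential", -30),
               logistic = fitWithBIC("logistic", -11))
  sel <- selectEnhancerModels(fits)
  expect_identical(bestModels(sel), "exponential")
  expect_equal(unname(deltaBIC(sel)), c(0, -20, -1))

  near <- list(additive = fitWithBIC("additive", -10),
               exponential = fitWithBIC("exponential", -11),
               logistic = fitWithBIC("logistic", -10.5))
  expect_setequal(bestModels(selectEnhancerModels(near)),
                  c("additive", "exponential", "logistic"))

  mismatched <- list(additive = fitWithBIC("additive", -10, nObs = 24L),
                     exponential = fitWithBIC("exponential", -12, nObs = 20L))
  expect_error(selectEnhancerModels(mismatched), "differing")
})

test_that("predictive quantiles follow the Gaussian predictive law", {
  fit <- fitWithBIC("additive", -10)
  fit@coefficients <- c(b0 = 1, b1 = 0, b2 = 0)
  fit@sigma <- 0.1
  expect_equal(predictQuantiles(fit, 1, 1, 0.5), 1.0)
  expect_equal(predictQuantiles(fit, 0, 1, c(0.1, 0.9)), c(0.8718, 1.1282),
               tolerance = 1e-4)
  expect_error(predictQuantiles(fit, 1, 1, 1.2), "inside")
  # logistic saturation: strong total activation drives the median to g
  lfit <- fitWithBIC("logistic", -10)
  lfit@coefficients <- c(b0 = 20, b1 = 10, b2 = 10, g = 2)
  lfit@sigma <- 0.01
  expect_equal(predictQuantiles(lfit, 1, 1, 0.5), 2, tolerance = 1e-6)
})

test_that("coefficient summary reports ratios and activator/antagonist roles", {
  f <- fitWithBIC("additive", -10)
  f@coefficients <- c(b0 = 0, b1 = 0.4, b2 = 0.4)
  s <- coefficientSummary(f)
  expect_equal(s$ratio, 1)
  expect_identical(s$role1, "activator")
  expect_identical(s$role2, "activator")

  f@coefficients <- c(b0 = 0, b1 = -0.4, b2 = 0.9)
  s <- coefficientSummary(f)
  expect_identical(s$role1, "antagonist")
  expect_lt(s$ratio, 0)

  f@coefficients <- c(b0 = 0, b1 = 0.4, b2 = 0)
  s <- coefficientSummary(f)
  expect_false(s$ratio_defined)
  expect_true(is.na(s$ratio))
})

test_that("antagonist coefficients are recovered with the right sign", {
  hits <- 0L
  for (s in 1:20) {
    d <- normalizeToWT(simulateExpressionData(
      "exponential", c(b0 = 0, b1 = -0.4, b2 = 0.9), sigma = 0.05, seed = s))
    fit <- fitEnhancerModel(d, "exponential", seed = s)
    if (coef(fit)[["b1"]] < 0) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
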