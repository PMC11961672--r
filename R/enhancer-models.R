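## Two-enhancer expression models.
##
## Expression of a target gene is measured over the four genotypes of a
## two-enhancer CRISPR excision design: WT (both enhancers intact), two single
## knockouts and the double knockout. Genotypes are coded x1, x2 in {0,1} with
## 1 = intact, so the DKO is the intercept baseline. Three generative families
## describe how the enhancer pair sets the mean expression mu(x1, x2):
##
##   additive     mu = b0 + b1*x1 + b2*x2          (independent, linear action)
##   exponential  mu = exp(b0 + b1*x1 + b2*x2)     (multiplicative / synergy)
##   logistic     mu = g / (1 + exp(-(b0 + b1*x1 + b2*x2)))
##                                                 (two-state saturation, g =
##                                                  maximum expression level)
##
## Observed expression = mu + eps with eps ~ N(0, sigma^2); sigma is profiled
## by ML and counted as a free BIC parameter.

.MODEL_FAMILIES <- c("additive", "exponential", "logistic")

.sigmaFloor <- 1e-9

.linpred <- function(b, x1, x2) b[1] + b[2] * x1 + b[3] * x2

#' Model mean expression for a genotype
#'
#' Evaluates the mean function mu(x1, x2) of one of the three enhancer
#' interaction families at given coefficients.
#'
#' @param model one of \code{"additive"}, \code{"exponential"},
#'   \code{"logistic"}.
#' @param coefficients named numeric with \code{b0}, \code{b1}, \code{b2}
#'   and, for the logistic family, \code{g}.
#' @param x1,x2 binary enhancer states (1 = intact, 0 = excised); vectorized.
#' @return numeric vector of model means.
#' @examples
#' modelMean("additive", c(b0 = 0.2, b1 = 0.5, b2 = 0.3), 1, 1)
#' @export
modelMean <- function(model, coefficients, x1, x2) {
  model <- match.arg(model, .MODEL_FAMILIES)
  b <- unname(coefficients[c("b0", "b1", "b2")])
  eta <- .linpred(b, x1, x2)
  switch(model,
    additive    = eta,
    exponential = exp(eta),
    logistic    = {
      g <- unname(coefficients[["g"]])
      g / (1 + exp(-eta))
    })
}

#' Normalize expression to the wild-type mean of each batch
#'
#' Divides every raw expression value by the mean expression of the wild-type
#' observations (x1 = 1, x2 = 1) of the same experimental batch, removing
#' batch-scale differences. After normalization the grand mean over all WT
#' observations equals 1.
#'
#' @param observations data.frame with columns \code{batch}, \code{replicate},
#'   \code{x1}, \code{x2}, \code{expression} (raw, non-negative).
#' @return the same data.frame with \code{expression} replaced by fold of the
#'   WT batch mean.
#' @examples
#' d <- data.frame(batch = "A", replicate = 1:3,
#'                 x1 = c(1, 1, 0), x2 = c(1, 1, 0),
#'                 expression = c(2, 4, 1.5))
#' normalizeToWT(d)$expression  # 0.667, 1.333, 0.5
#' @export
normalizeToWT <- function(observations) {
  .checkObsFrame(observations)
  out <- observations
  for (b in unique(observations$batch)) {
    inBatch <- observations$batch == b
    wt <- inBatch & observations$x1 == 1 & observations$x2 == 1
    if (!any(wt))
      stop("batch '", b, "' has no wild-type (x1 = 1, x2 = 1) observation ",
           "to normalize against", call. = FALSE)
    m <- mean(observations$expression[wt])
    if (!is.finite(m) || m <= 0)
      stop("wild-type mean of batch '", b, "' is not positive; ",
           "cannot normalize", call. = FALSE)
    out$expression[inBatch] <- observations$expression[inBatch] / m
  }
  out
}

.checkObsFrame <- function(d) {
  need <- c("batch", "x1", "x2", "expression")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("expression table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(d$x1 %in% c(0, 1)) || !all(d$x2 %in% c(0, 1)))
    stop("x1 and x2 must be binary (0 = excised, 1 = intact)", call. = FALSE)
  invisible(TRUE)
}

.gaussLogLik <- function(rss, n, sigma = NULL) {
  if (is.null(sigma)) sigma <- max(sqrt(rss / n), .sigmaFloor)
  -n / 2 * log(2 * pi * sigma^2) - rss / (2 * sigma^2)
}

.newFit <- function(model, coefs, rss, n, converged) {
  sigma <- max(sqrt(rss / n), .sigmaFloor)
  ll <- .gaussLogLik(rss, n, sigma)
  npar <- if (model == "logistic") 5L else 4L
  new("EnhancerModelFit",
      model = model, coefficients = coefs, sigma = sigma, logLik = ll,
      nObs = as.integer(n), nPar = npar,
      bic = npar * log(n) - 2 * ll, converged = converged)
}

## RSS objectives on unconstrained parameterizations
.rssExponential <- function(par, x1, x2, y) {
  mu <- exp(.linpred(par, x1, x2))
  if (any(!is.finite(mu))) return(.Machine$double.xmax)
  sum((y - mu)^2)
}

.rssLogistic <- function(par, x1, x2, y) {   # par = (b0, b1, b2, log g)
  g <- exp(par[4])
  mu <- g / (1 + exp(-.linpred(par[1:3], x1, x2)))
  if (any(!is.finite(mu))) return(.Machine$double.xmax)
  sum((y - mu)^2)
}

.optimBest <- function(par0, fn, ...) {
  fits <- list()
  o1 <- tryCatch(
    optim(par0, fn, ..., method = "BFGS",
          control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(o1)) fits <- c(fits, list(o1))
  start2 <- if (!is.null(o1)) o1$par else par0
  o2 <- tryCatch(
    optim(start2, fn, ..., method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(o2)) fits <- c(fits, list(o2))
  if (!length(fits)) return(NULL)
  fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
}

#' Fit one enhancer-interaction model family by maximum likelihood
#'
#' Fits the additive, exponential or logistic two-enhancer model to
#' WT-normalized replicate expression data under Gaussian constant-variance
#' noise. The additive family is solved in closed form (ordinary least
#' squares); the exponential and logistic families are fitted by nonlinear
#' least squares (equivalent to Gaussian ML) with deterministic initialization
#' plus seeded random restarts.
#'
#' The exponential fit is initialized from a log-linear regression on the
#' genotype group means when all means are strictly positive, otherwise from
#' random starts only. The logistic fit is initialized with
#' \code{g = 1.05 * max(expression)} and logit-transformed group means.
#'
#' @param data data.frame with columns \code{x1}, \code{x2},
#'   \code{expression} (normalized).
#' @param model model family.
#' @param seed integer; controls the random restarts, making the fit
#'   deterministic given data and seed.
#' @param nRestarts number of random restarts for the nonlinear families.
#' @return an [EnhancerModelFit-class] object.
#' @examples
#' d <- simulateExpressionData(model = "additive",
#'   coefficients = c(b0 = 0.2, b1 = 0.5, b2 = 0.3), sigma = 0.05, seed = 1)
#' fitEnhancerModel(normalizeToWT(d), "additive")
#' @export
fitEnhancerModel <- function(data, model = c("additive", "exponential", "logistic"),
                             seed = 1L, nRestarts = 10L) {
  model <- match.arg(model)
  if (!all(c("x1", "x2", "expression") %in% names(data)))
    stop("data must contain columns x1, x2, expression", call. = FALSE)
  x1 <- as.numeric(data$x1); x2 <- as.numeric(data$x2)
  y <- as.numeric(data$expression)
  n <- length(y)
  minObs <- if (model == "logistic") 5L else 4L
  if (n < minObs)
    stop("underdetermined: ", model, " model needs >= ", minObs,
         " observations, got ", n, call. = FALSE)
  if (length(unique(paste(x1, x2))) < 3L)
    stop("need at least 3 distinct genotypes to fit", call. = FALSE)

  if (model == "additive") {
    fit <- lm(y ~ x1 + x2)
    co <- c(b0 = unname(coef(fit)[1]), b1 = unname(coef(fit)[2]),
            b2 = unname(coef(fit)[3]))
    return(.newFit("additive", co, sum(fit$residuals^2), n, TRUE))
  }

  gm <- tapply(y, paste(x1, x2), mean)
  gx <- do.call(rbind, lapply(strsplit(names(gm), " "), as.numeric))

  starts <- list()
  if (model == "exponential") {
    if (all(gm > 0)) {
      lf <- lm(log(gm) ~ gx[, 1] + gx[, 2])
      starts[[1]] <- unname(coef(lf))
    }
  } else {
    g0 <- 1.05 * max(y)
    p <- pmin(pmax(gm / g0, 1e-3), 1 - 1e-3)
    lf <- lm(log(p / (1 - p)) ~ gx[, 1] + gx[, 2])
    starts[[1]] <- c(unname(coef(lf)), log(g0))
  }
  npar <- if (model == "logistic") 4L else 3L
  restarts <- .withSeed(seed, {
    lapply(seq_len(nRestarts), function(i) rnorm(npar, 0, 2))
  })
  starts <- c(starts, restarts)
  starts <- Filter(function(s) all(is.finite(s)), starts)

  fn <- if (model == "exponential") .rssExponential else .rssLogistic
  best <- NULL
  for (s in starts) {
    o <- .optimBest(s, fn, x1 = x1, x2 = x2, y = y)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    stop("optimizer failed to converge for the ", model, " model after ",
         length(starts), " starts", call. = FALSE)

  if (model == "exponential") {
    co <- c(b0 = best$par[1], b1 = best$par[2], b2 = best$par[3])
  } else {
    co <- c(b0 = best$par[1], b1 = best$par[2], b2 = best$par[3],
            g = exp(best$par[4]))
  }
  .newFit(model, co, best$value, n, TRUE)
}

## evaluate an expression with a temporary RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit and compare all three enhancer-interaction families
#'
#' Fits the additive, exponential and logistic models to the same data and
#' compares them by BIC. BIC differences are reported against the additive
#' reference; all families whose BIC lies within \code{threshold} of the
#' minimum form the best set (differences greater than the threshold indicate
#' a decisively better fit).
#'
#' @inheritParams fitEnhancerModel
#' @param threshold BIC decision threshold (default 2).
#' @return an [EnhancerModelSet-class].
#' @export
compareEnhancerModels <- function(data, threshold = 2, seed = 1L) {
  fits <- lapply(setNames(.MODEL_FAMILIES, .MODEL_FAMILIES),
                 function(m) fitEnhancerModel(data, m, seed = seed))
  selectEnhancerModels(fits, threshold = threshold)
}

#' Select best-fitting families by BIC
#'
#' @param fits named list of [EnhancerModelFit-class] objects fitted on the
#'   identical data set; must include the additive family (the deltaBIC
#'   reference).
#' @param threshold BIC decision threshold.
#' @return an [EnhancerModelSet-class].
#' @export
selectEnhancerModels <- function(fits, threshold = 2) {
  stopifnot(length(fits) >= 1, all(vapply(fits, is, logical(1), "EnhancerModelFit")))
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, modelName, character(1))
  ns <- vapply(fits, function(f) f@nObs, integer(1))
  if (length(unique(ns)) != 1L)
    stop("fits were computed on differing numbers of observations: ",
         paste(ns, collapse = ", "), call. = FALSE)
  bics <- vapply(fits, BIC, numeric(1))
  ref <- if ("additive" %in% names(fits)) bics[["additive"]] else min(bics)
  best <- names(bics)[bics <= min(bics) + threshold]
  new("EnhancerModelSet", fits = fits, deltaBIC = bics - ref,
      bestSet = best, threshold = threshold)
}

#' Predictive quantiles of a fitted model
#'
#' Quantiles of the Gaussian predictive distribution
#' N(mu(x1, x2), sigma^2) of a fitted family, used e.g. for 0.1-0.9 quantile
#' bands around the model mean.
#'
#' @param fit an [EnhancerModelFit-class].
#' @param x1,x2 binary enhancer states.
#' @param quantiles numeric in (0, 1).
#' @return numeric vector of predictive quantiles (one per requested quantile).
#' @export
predictQuantiles <- function(fit, x1, x2, quantiles = c(0.1, 0.5, 0.9)) {
  stopifnot(is(fit, "EnhancerModelFit"))
  if (any(quantiles <= 0 | quantiles >= 1))
    stop("quantiles must lie strictly inside (0, 1)", call. = FALSE)
  mu <- modelMean(fit@model, fit@coefficients, x1, x2)
  qnorm(quantiles, mean = mu, sd = fit@sigma)
}

#' Predictive quantile table over the four genotypes
#'
#' @inheritParams predictQuantiles
#' @return data.frame with one row per genotype and one column per quantile.
#' @export
predictQuantileTable <- function(fit, quantiles = c(0.1, 0.5, 0.9)) {
  geno <- expand.grid(x1 = c(1, 0), x2 = c(1, 0))
  q <- t(vapply(seq_len(nrow(geno)),
                function(i) predictQuantiles(fit, geno$x1[i], geno$x2[i], quantiles),
                numeric(length(quantiles))))
  colnames(q) <- sprintf("q%g", quantiles)
  cbind(geno, as.data.frame(q))
}

#' Summarize enhancer coefficients across fitted families
#'
#' Reports, per model family, the two enhancer coefficients, their ratio
#' b1/b2 (a potency comparison: how much stronger enhancer 1 is than
#' enhancer 2), and a role flag per enhancer: a positive coefficient marks an
#' activator, a negative coefficient an antagonist that dampens expression.
#'
#' @param ... [EnhancerModelFit-class] objects, or a single
#'   [EnhancerModelSet-class].
#' @return data.frame with columns \code{model}, \code{b1}, \code{b2},
#'   \code{ratio}, \code{ratio_defined}, \code{role1}, \code{role2}.
#' @export
coefficientSummary <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is(args[[1]], "EnhancerModelSet"))
    args <- modelFits(args[[1]])
  stopifnot(all(vapply(args, is, logical(1), "EnhancerModelFit")))
  rows <- lapply(args, function(f) {
    b1 <- f@coefficients[["b1"]]; b2 <- f@coefficients[["b2"]]
    defined <- b2 != 0
    data.frame(model = f@model, b1 = b1, b2 = b2,
               ratio = if (defined) b1 / b2 else NA_real_,
               ratio_defined = defined,
               role1 = if (b1 >= 0) "activator" else "antagonist",
               role2 = if (b2 >= 0) "activator" else "antagonist",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
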