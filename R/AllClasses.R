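#' @import methods
#' @importFrom stats coef logLik BIC optim qnorm quantile median rnorm runif
#'   rbinom dnorm lm phyper cor sd setNames
NULL

#' Fitted two-enhancer expression model
#'
#' Holds the maximum-likelihood fit of one model family (additive, exponential
#' or logistic) describing how two enhancers, encoded as binary intact/excised
#' indicators, control normalized gene expression. Expression noise is Gaussian
#' with constant variance; the residual SD is profiled by maximum likelihood
#' and counted as a free parameter in the BIC.
#'
#' @slot model character, one of \code{"additive"}, \code{"exponential"},
#'   \code{"logistic"}.
#' @slot coefficients named numeric: \code{b0}, \code{b1}, \code{b2} and, for
#'   the logistic family only, the maximum-expression term \code{g}.
#' @slot sigma positive numeric, ML residual standard deviation.
#' @slot logLik numeric, Gaussian log-likelihood at the optimum.
#' @slot nObs integer, number of observations fitted.
#' @slot nPar integer, number of free parameters (4, or 5 for logistic).
#' @slot bic numeric, \code{nPar * log(nObs) - 2 * logLik}.
#' @slot converged logical.
#'
#' @seealso [fitEnhancerModel()], [selectEnhancerModels()]
#' @export
setClass("EnhancerModelFit",
  representation(
    model        = "character",
    coefficients = "numeric",
    sigma        = "numeric",
    logLik       = "numeric",
    nObs         = "integer",
    nPar         = "integer",
    bic          = "numeric",
    converged    = "logical"
  )
)

setValidity("EnhancerModelFit", function(object) {
  msg <- character()
  if (!object@model %in% c("additive", "exponential", "logistic"))
    msg <- c(msg, "model must be additive, exponential or logistic")
  need <- c("b0", "b1", "b2")
  if (object@model == "logistic") need <- c(need, "g")
  if (!all(need %in% names(object@coefficients)))
    msg <- c(msg, paste("coefficients must contain", paste(need, collapse = ", ")))
  if (object@model != "logistic" && "g" %in% names(object@coefficients))
    msg <- c(msg, "g is defined only for the logistic model")
  if (length(object@sigma) != 1L || object@sigma <= 0)
    msg <- c(msg, "sigma must be a single positive value")
  expPar <- if (object@model == "logistic") 5L else 4L
  if (object@nPar != expPar)
    msg <- c(msg, sprintf("nPar must be %d for the %s model", expPar, object@model))
  bicExp <- object@nPar * log(object@nObs) - 2 * object@logLik
  if (!isTRUE(all.equal(object@bic, bicExp, tolerance = 1e-10)))
    msg <- c(msg, "bic inconsistent with nPar * log(nObs) - 2 * logLik")
  if (length(msg)) msg else TRUE
})

#' Model comparison across the three enhancer-interaction families
#'
#' Result of comparing additive, exponential and logistic fits of the same
#' data by BIC. The additive family is the reference for \code{deltaBIC};
#' every family whose BIC is within \code{threshold} of the minimum belongs to
#' the best set (a BIC difference greater than the threshold indicates a
#' decisively better fit, so near-ties are reported jointly rather than forcing
#' a single winner).
#'
#' @slot fits named list of [EnhancerModelFit-class] objects.
#' @slot deltaBIC named numeric, BIC of each family minus the additive BIC.
#' @slot bestSet character, families within \code{threshold} of the minimum BIC.
#' @slot threshold numeric decision threshold (default 2).
#'
#' @export
setClass("EnhancerModelSet",
  representation(
    fits      = "list",
    deltaBIC  = "numeric",
    bestSet   = "character",
    threshold = "numeric"
  )
)

setValidity("EnhancerModelSet", function(object) {
  msg <- character()
  if (!all(vapply(object@fits, is, logical(1), "EnhancerModelFit")))
    msg <- c(msg, "fits must all be EnhancerModelFit objects")
  if (length(object@bestSet) == 0L)
    msg <- c(msg, "bestSet must be nonempty")
  bics <- vapply(object@fits, function(f) f@bic, numeric(1))
  if (length(bics) && !names(which.min(bics)) %in% object@bestSet)
    msg <- c(msg, "family with minimal BIC must be in bestSet")
  if (length(msg)) msg else TRUE
})

#' Three-channel confocal image stack
#'
#' A z-stack of confocal microscopy images with a nuclear stain (DAPI), a
#' DNA-FISH channel and an immunofluorescence marker channel (e.g. BRD4).
#' Channels are stored as \code{H x W x Z} arrays with intensities in [0, 1].
#'
#' @slot dapi,fish,marker numeric arrays, identical \code{H x W x Z} dims.
#'
#' @seealso [simulateImageStack()], [runColocalization()]
#' @export
setClass("ChannelStack",
  representation(dapi = "array", fish = "array", marker = "array")
)

setValidity("ChannelStack", function(object) {
  d <- dim(object@dapi)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "channels must be 3-dimensional (H x W x Z) arrays")
  if (!identical(d, dim(object@fish)) || !identical(d, dim(object@marker)))
    msg <- c(msg, "all three channels must share identical dimensions")
  rng <- range(object@dapi, object@fish, object@marker)
  if (any(!is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "intensities must be finite and scaled to [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Positionwise marker enrichment around FISH spots
#'
#' 11x11 maps of the median marker (IF) intensity at each position relative to
#' genuine DNA-FISH spot centers and to randomly allocated in-nucleus centers,
#' and their elementwise ratio. Ratio values above 1 at the center indicate
#' marker enrichment at the locus beyond nuclear background.
#'
#' @slot spotMedian,randomMedian,ratio numeric matrices (window x window).
#' @slot nSpots,nRandom integer counts of aggregated windows.
#'
#' @seealso [aggregateEnrichment()]
#' @export
setClass("EnrichmentMap",
  representation(
    spotMedian   = "matrix",
    randomMedian = "matrix",
    ratio        = "matrix",
    nSpots       = "integer",
    nRandom      = "integer"
  )
)

setValidity("EnrichmentMap", function(object) {
  msg <- character()
  d <- dim(object@spotMedian)
  if (!identical(d, dim(object@randomMedian)) || !identical(d, dim(object@ratio)))
    msg <- c(msg, "all three maps must share dimensions")
  if (length(msg)) msg else TRUE
})
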