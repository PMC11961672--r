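#' @describeIn EnhancerModelFit-class model family name
#' @export
setMethod("modelName", "EnhancerModelFit", function(object) object@model)

#' @describeIn EnhancerModelFit-class named coefficient vector
#' @param ... ignored
#' @export
setMethod("coef", "EnhancerModelFit", function(object, ...) object@coefficients)

#' @describeIn EnhancerModelFit-class Gaussian log-likelihood at the optimum
#' @export
setMethod("logLik", "EnhancerModelFit", function(object, ...) object@logLik)

#' @describeIn EnhancerModelFit-class Bayesian Information Criterion
#' @export
setMethod("BIC", "EnhancerModelFit", function(object, ...) object@bic)

#' @describeIn EnhancerModelFit-class residual standard deviation
#' @export
residualSigma <- function(object) {
  stopifnot(is(object, "EnhancerModelFit"))
  object@sigma
}

setMethod("show", "EnhancerModelFit", function(object) {
  cat(sprintf("EnhancerModelFit (%s family)\n", object@model))
  co <- object@coefficients
  cat("  coefficients:",
      paste(sprintf("%s = %.4g", names(co), co), collapse = ", "), "\n")
  cat(sprintf("  sigma = %.4g, logLik = %.4f\n", object@sigma, object@logLik))
  cat(sprintf("  n = %d obs, %d parameters, BIC = %.3f%s\n",
              object@nObs, object@nPar, object@bic,
              if (object@converged) "" else "  [NOT CONVERGED]"))
  invisible(object)
})

#' @describeIn EnhancerModelSet-class list of per-family fits
#' @export
modelFits <- function(object) {
  stopifnot(is(object, "EnhancerModelSet"))
  object@fits
}

#' @describeIn EnhancerModelSet-class families within the BIC threshold of the best
#' @export
setMethod("bestModels", "EnhancerModelSet", function(object) object@bestSet)

#' @describeIn EnhancerModelSet-class BIC differences relative to the additive fit
#' @export
setMethod("deltaBIC", "EnhancerModelSet", function(object) object@deltaBIC)

setMethod("show", "EnhancerModelSet", function(object) {
  cat("EnhancerModelSet of", length(object@fits), "fits\n")
  bics <- vapply(object@fits, BIC, numeric(1))
  for (nm in names(object@fits)) {
    cat(sprintf("  %-12s BIC = %8.3f   dBIC(vs additive) = %+8.3f%s\n",
                nm, bics[[nm]], object@deltaBIC[[nm]],
                if (nm %in% object@bestSet) "  *" else ""))
  }
  cat(sprintf("  best set (threshold %.3g): %s\n", object@threshold,
              paste(object@bestSet, collapse = ", ")))
  invisible(object)
})

#' @describeIn ChannelStack-class DAPI (nuclear stain) volume
#' @export
setMethod("dapi", "ChannelStack", function(object) object@dapi)

#' @describeIn ChannelStack-class DNA-FISH channel volume
#' @export
setMethod("fish", "ChannelStack", function(object) object@fish)

#' @describeIn ChannelStack-class immunofluorescence marker volume
#' @export
setMethod("marker", "ChannelStack", function(object) object@marker)

#' @describeIn ChannelStack-class stack dimensions (H, W, Z)
#' @export
setMethod("dim", "ChannelStack", function(x) dim(x@dapi))

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@dapi)
  cat(sprintf("ChannelStack: %d x %d pixels, %d z-slices, 3 channels (DAPI/FISH/marker)\n",
              d[1], d[2], d[3]))
  invisible(object)
})

#' @describeIn EnrichmentMap-class elementwise spot/random ratio map
#' @export
setMethod("enrichmentRatio", "EnrichmentMap", function(object) object@ratio)

#' @describeIn EnrichmentMap-class median marker map over genuine spots
#' @export
setMethod("spotMedianMap", "EnrichmentMap", function(object) object@spotMedian)

#' @describeIn EnrichmentMap-class median marker map over random centers
#' @export
setMethod("randomMedianMap", "EnrichmentMap", function(object) object@randomMedian)

setMethod("show", "EnrichmentMap", function(object) {
  d <- dim(object@ratio)
  ctr <- (d[1] + 1) %/% 2
  cat(sprintf("EnrichmentMap %dx%d (%d spots vs %d random centers)\n",
              d[1], d[2], object@nSpots, object@nRandom))
  cat(sprintf("  central ratio: %.3f\n", object@ratio[ctr, ctr]))
  invisible(object)
})
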