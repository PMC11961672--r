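# fixtures built in code: small geometric images and hand-made model fits

# filled disk(s) on a background
diskImage <- function(dim = c(128L, 128L), centers, radii, value = 0.8,
                      background = 0.05) {
  img <- matrix(background, dim[1], dim[2])
  rowIdx <- matrix(seq_len(dim[1]), dim[1], dim[2])
  colIdx <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  for (k in seq_len(nrow(centers))) {
    inside <- (rowIdx - centers[k, 1])^2 + (colIdx - centers[k, 2])^2 <= radii[k]^2
    img[inside] <- value
  }
  img
}

# isotropic 2D Gaussian bump added to an image
addGaussianSpot <- function(img, center, amplitude, sigma) {
  rowIdx <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  colIdx <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  img + amplitude * exp(-((rowIdx - center[1])^2 + (colIdx - center[2])^2) /
                          (2 * sigma^2))
}

# build an EnhancerModelFit with a prescribed BIC (logLik back-solved)
fitWithBIC <- function(model, bic, nObs = 24L) {
  nPar <- if (model == "logistic") 5L else 4L
  co <- c(b0 = 0, b1 = 0, b2 = 0)
  if (model == "logistic") co <- c(co, g = 1)
  ll <- (nPar * log(nObs) - bic) / 2
  new("EnhancerModelFit", model = model, coefficients = co, sigma = 1,
      logLik = ll, nObs = nObs, nPar = nPar, bic = bic, converged = TRUE)
}
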