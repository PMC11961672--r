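## Seeded synthetic-data generators. Every analysis stage in the package can
## be exercised without any external download: replicate expression tables
## drawn from the three generative enhancer models with batch structure,
## three-channel image stacks with ellipsoidal nuclei / FISH spots / tunable
## marker colocalization, and a toy genome with planted category structure,
## SNP densities, TF-target bias and focal-tissue expression shifts. All
## generators return ground truth sufficient to score the downstream stage.

#' Simulate replicate expression data from an enhancer model
#'
#' Draws replicate raw expression values for the four genotypes of a
#' two-enhancer design from one of the three generative families. Within each
#' batch, values are \code{mu(x1, x2) * batchScale + N(0, sigma * batchScale)}:
#' noise scales with the batch factor, so per-batch WT normalization exactly
#' removes batch structure.
#'
#' Defaults give a WT mean of 1 with residual SD 5\% of the WT mean and 6
#' replicates per genotype — the reference simulation conditions used
#' throughout the package's tests.
#'
#' @param model family (\code{"additive"}, \code{"exponential"},
#'   \code{"logistic"}).
#' @param coefficients named numeric (\code{b0}, \code{b1}, \code{b2}, plus
#'   \code{g} for logistic).
#' @param sigma residual SD on the normalized scale (>= 0).
#' @param repsPerGenotype either a single count applied to all four genotypes
#'   or a named vector keyed by \code{"x1x2"} strings
#'   (e.g. \code{c("11" = 12, "10" = 5, "01" = 7, "00" = 5)}).
#' @param batchScales numeric vector of per-batch scale factors (one batch per
#'   entry).
#' @param seed integer.
#' @return data.frame with columns \code{batch}, \code{replicate}, \code{x1},
#'   \code{x2}, \code{expression} (raw scale).
#' @export
simulateExpressionData <- function(model = "additive",
                                   coefficients = c(b0 = 0.2, b1 = 0.5, b2 = 0.3),
                                   sigma = 0.05,
                                   repsPerGenotype = 6L,
                                   batchScales = 1,
                                   seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  geno <- data.frame(x1 = c(1, 1, 0, 0), x2 = c(1, 0, 1, 0))
  key <- paste0(geno$x1, geno$x2)
  reps <- if (length(repsPerGenotype) == 1L)
    setNames(rep(repsPerGenotype, 4), key) else repsPerGenotype[key]
  .withSeed(seed, {
    rows <- list()
    for (b in seq_along(batchScales)) {
      sc <- batchScales[b]
      for (gi in seq_len(4)) {
        mu <- modelMean(model, coefficients, geno$x1[gi], geno$x2[gi])
        n <- as.integer(reps[[key[gi]]])
        if (n == 0L) next
        y <- mu * sc + rnorm(n, 0, sigma * sc)
        rows[[length(rows) + 1L]] <- data.frame(
          batch = paste0("batch", b), replicate = seq_len(n),
          x1 = geno$x1[gi], x2 = geno$x2[gi], expression = y)
      }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
}

#' Simulate a three-channel confocal stack with ground truth
#'
#' Builds a DAPI channel of ellipsoidal nuclei (intensity plateau plus noise),
#' a FISH channel of compact Gaussian spots placed inside nuclei and spanning
#' 2-4 z-slices, and a marker (IF) channel of uniform background plus,
#' optionally, Gaussian intensity bumps colocalized with the spot centers.
#' Additive Gaussian noise is clipped to [0, 1].
#'
#' @param dims integer \code{c(H, W, Z)}.
#' @param nNuclei nuclei to place (non-overlapping in-plane; placement fails
#'   after bounded retries when packing is impossible).
#' @param nucleusRadius in-plane radius range (pixels), sampled per nucleus.
#' @param nucleusZRadius half-extent of nuclei in z (slices); the default
#'   \code{0.75 * Z} keeps nuclear signal in every slice, as in stacks focused
#'   within the nuclei.
#' @param spotsPerNucleus FISH spots per nucleus.
#' @param spotMinSep minimum in-plane distance (pixels) between spot centers
#'   of the same nucleus, so planted spots stay resolvable after smoothing.
#' @param spotAmplitude peak FISH intensity of a spot.
#' @param spotSigma in-plane Gaussian SD of a spot (pixels).
#' @param spotZExtent integer vector of possible z-extents (slices per spot).
#' @param colocAmplitude peak marker intensity added at spot centers (0 =
#'   marker independent of spots).
#' @param colocSigma in-plane SD of the marker bump.
#' @param dapiLevel nucleus plateau intensity in the DAPI channel.
#' @param background marker channel background level.
#' @param noiseSd additive Gaussian noise SD (all channels).
#' @param seed integer.
#' @return list: \code{stack} ([ChannelStack-class]), \code{nucleusLabels}
#'   (integer \code{H x W x Z} ground-truth label array), \code{spots}
#'   (data.frame: nucleus, spot, z, row, col of every planted center slice;
#'   \code{zc, rowc, colc} give the 3D spot center).
#' @export
simulateImageStack <- function(dims = c(192L, 192L, 8L),
                               nNuclei = 6L,
                               nucleusRadius = c(20, 26),
                               nucleusZRadius = NULL,
                               spotsPerNucleus = 2L,
                               spotMinSep = 16,
                               spotAmplitude = 0.7,
                               spotSigma = 1.6,
                               spotZExtent = 2:4,
                               colocAmplitude = 0,
                               colocSigma = 2.5,
                               dapiLevel = 0.75,
                               background = 0.15,
                               noiseSd = 0.02,
                               seed = 1L) {
  H <- dims[1]; W <- dims[2]; Z <- dims[3]
  if (is.null(nucleusZRadius)) nucleusZRadius <- 0.75 * Z
  .withSeed(seed, {
    dapiA <- array(0, dims); fishA <- array(0, dims); markA <- array(background, dims)
    nucLab <- array(0L, dims)
    rowIdx <- matrix(seq_len(H), H, W)
    colIdx <- matrix(seq_len(W), H, W, byrow = TRUE)

    centers <- matrix(numeric(0), 0, 3)   # row, col, radius
    for (k in seq_len(nNuclei)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        r <- runif(1, nucleusRadius[1], nucleusRadius[2])
        cy <- runif(1, r + 2, H - r - 2)
        cx <- runif(1, r + 2, W - r - 2)
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
                centers[, 3] + r + 12)) {
          centers <- rbind(centers, c(cy, cx, r))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", nNuclei, " non-overlapping nuclei in a ",
             H, "x", W, " field", call. = FALSE)
    }

    zc0 <- (Z + 1) / 2
    for (k in seq_len(nrow(centers))) {
      cy <- centers[k, 1]; cx <- centers[k, 2]; r <- centers[k, 3]
      for (z in seq_len(Z)) {
        dz <- (z - zc0) / nucleusZRadius
        if (abs(dz) >= 1) next
        rz <- r * sqrt(1 - dz^2)
        inside <- (rowIdx - cy)^2 + (colIdx - cx)^2 <= rz^2
        sl <- nucLab[, , z]; sl[inside] <- k; nucLab[, , z] <- sl
        dsl <- dapiA[, , z]; dsl[inside] <- dapiLevel; dapiA[, , z] <- dsl
      }
    }

    spotRows <- list()
    spotId <- 0L
    for (k in seq_len(nrow(centers))) {
      ## spots sit on an evenly rotated ring well inside the nucleus, so
      ## sibling spots stay >= spotMinSep apart and resolvable after smoothing
      r <- centers[k, 3]
      rot <- runif(1, 0, 2 * pi)
      for (s in seq_len(spotsPerNucleus)) {
        spotId <- spotId + 1L
        if (spotsPerNucleus == 1L) {
          ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 0.5 * r)
        } else {
          ang <- rot + 2 * pi * (s - 1) / spotsPerNucleus + runif(1, -0.15, 0.15)
          rad <- runif(1, 0.42 * r, 0.5 * r)
          minNeeded <- spotMinSep / (2 * sin(pi / spotsPerNucleus))
          rad <- max(rad, min(minNeeded, 0.5 * r))
        }
        ry <- round(centers[k, 1] + rad * sin(ang))
        rx <- round(centers[k, 2] + rad * cos(ang))
        ext <- sample(spotZExtent, 1)
        z0 <- sample(seq(max(1, floor(zc0) - 1), min(Z - ext + 1, ceiling(zc0))), 1)
        zs <- z0:(z0 + ext - 1)
        zcSpot <- mean(zs)
        for (z in zs) {
          zfall <- exp(-((z - zcSpot)^2) / (2 * (ext / 2.5)^2))
          g <- spotAmplitude * zfall *
            exp(-((rowIdx - ry)^2 + (colIdx - rx)^2) / (2 * spotSigma^2))
          fishA[, , z] <- fishA[, , z] + g
          if (colocAmplitude > 0) {
            m <- colocAmplitude * zfall *
              exp(-((rowIdx - ry)^2 + (colIdx - rx)^2) / (2 * colocSigma^2))
            markA[, , z] <- markA[, , z] + m
          }
          spotRows[[length(spotRows) + 1L]] <- data.frame(
            nucleus = k, spot = spotId, z = z, row = ry, col = rx,
            zc = zcSpot, rowc = ry, colc = rx)
        }
      }
    }

    clip <- function(a) pmin(pmax(a + rnorm(length(a), 0, noiseSd), 0), 1)
    stack <- ChannelStack(array(clip(dapiA), dims),
                          array(clip(fishA), dims),
                          array(clip(markA), dims))
    list(stack = stack, nucleusLabels = nucLab,
         spots = if (length(spotRows)) do.call(rbind, spotRows) else
           data.frame())
  })
}

#' Simulate a toy genome fixture with planted structure
#'
#' Tiles a small multi-chromosome genome into segments whose categories are
#' drawn from mixing proportions (defaults follow realistic genome fractions:
#' PTC 5.5\%, very active 2.5\%, moderately active 17.8\%, inactive 74.2\%),
#' with (p, log2fc, hub) triples consistent with each category's defining
#' rule. Plants SNPs at a configurable density ratio inside one category
#' versus the rest, genes assigned to the segment that contains them, a
#' TF-target network with optional bias toward a category, and a gene x tissue
#' expression table in which a chosen gene subset is shifted upward in the
#' focal tissue.
#'
#' @param chromLengths named numeric (default three 10-Mb chromosomes).
#' @param nSegments total segments tiling the genome.
#' @param mixing named category proportions (must sum to 1).
#' @param nSnps SNP count.
#' @param snpDensityRatio per-bp SNP density inside \code{snpCategory}
#'   relative to outside (1 = uniform).
#' @param snpCategory category receiving the planted density.
#' @param nGenes gene count (placed uniformly; category = host segment's).
#' @param nTf,targetsPerTf TF network size.
#' @param tfBiasCategory optional category toward which TF targets are biased.
#' @param tfBiasStrength sampling-weight multiplier for genes of the biased
#'   category.
#' @param nTissues tissue count (first tissue is the focal one, "blood").
#' @param focalShift additive expression shift (in SDs of the base expression)
#'   applied to the focal gene subset in the focal tissue.
#' @param nFocalGenes size of the shifted gene subset.
#' @param seed integer.
#' @return list: \code{segments} (chrom, start, end, p, log2fc, hub,
#'   category), \code{snps} (chrom, pos, planted flag), \code{genes} (gene,
#'   chrom, start, end, category), \code{network} (list TF -> targets),
#'   \code{geneCategory} (named vector), \code{tissueExpr} (genes x tissues),
#'   \code{focalGenes}, \code{genome} (chrom lengths).
#' @export
simulateGenomeFixture <- function(chromLengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                                  nSegments = 200L,
                                  mixing = c(PTC = 0.055, very_active = 0.025,
                                             moderately_active = 0.178,
                                             inactive = 0.742),
                                  nSnps = 1000L,
                                  snpDensityRatio = 1,
                                  snpCategory = "PTC",
                                  nGenes = 1000L,
                                  nTf = 20L,
                                  targetsPerTf = 50L,
                                  tfBiasCategory = NULL,
                                  tfBiasStrength = 1,
                                  nTissues = 8L,
                                  focalShift = 0,
                                  nFocalGenes = 100L,
                                  seed = 1L) {
  if (abs(sum(mixing) - 1) > 1e-8)
    stop("mixing proportions must sum to 1", call. = FALSE)
  if (snpDensityRatio < 0) stop("snpDensityRatio must be >= 0", call. = FALSE)
  .withSeed(seed, {
    ## tile chromosomes into segments proportional to length
    segPerChrom <- setNames(
      pmax(1L, round(nSegments * chromLengths / sum(chromLengths))),
      names(chromLengths))
    segs <- list()
    for (ch in names(chromLengths)) {
      k <- segPerChrom[[ch]]
      bounds <- round(seq(0, chromLengths[[ch]], length.out = k + 1))
      segs[[ch]] <- data.frame(chrom = ch, start = bounds[-(k + 1)],
                               end = bounds[-1], stringsAsFactors = FALSE)
    }
    segments <- do.call(rbind, c(segs, make.row.names = FALSE))
    n <- nrow(segments)
    cat <- sample(names(mixing), n, replace = TRUE, prob = mixing)
    p <- numeric(n); lfc <- numeric(n); hub <- integer(n)
    for (i in seq_len(n)) {
      switch(cat[i],
        PTC = { p[i] <- runif(1, 0, 0.05); lfc[i] <- abs(rnorm(1, 1, 0.5)); hub[i] <- 1L },
        very_active = { p[i] <- runif(1, 0, 0.05); lfc[i] <- abs(rnorm(1, 1, 0.5)); hub[i] <- 0L },
        moderately_active = { p[i] <- runif(1, 0.051, 1); lfc[i] <- abs(rnorm(1, 0.3, 0.2)); hub[i] <- 0L },
        inactive = { p[i] <- runif(1, 0.051, 1); lfc[i] <- -abs(rnorm(1, 0.5, 0.3)); hub[i] <- 0L })
    }
    segments$p <- p; segments$log2fc <- lfc; segments$hub <- hub
    segments$category <- cat

    ## SNPs: density ratio r inside snpCategory vs outside
    inCat <- segments$category == snpCategory
    lenIn <- sum(segments$end[inCat] - segments$start[inCat])
    ## a SNP lands in the category with probability r * coverage, so the
    ## planted ground-truth overlap enrichment versus shuffled background
    ## equals snpDensityRatio exactly (in expectation)
    pIn <- min(snpDensityRatio * lenIn / sum(chromLengths), 1)
    placeUniform <- function(m, frame) {
      if (m == 0L || nrow(frame) == 0L)
        return(data.frame(chrom = character(0), pos = numeric(0)))
      w <- frame$end - frame$start
      pick <- sample.int(nrow(frame), m, replace = TRUE, prob = w)
      data.frame(chrom = frame$chrom[pick],
                 pos = floor(frame$start[pick] + runif(m) * w[pick]),
                 stringsAsFactors = FALSE)
    }
    nIn <- rbinom(1, nSnps, pIn)
    snps <- rbind(
      cbind(placeUniform(nIn, segments[inCat, , drop = FALSE]), planted = TRUE),
      cbind(placeUniform(nSnps - nIn, segments[!inCat, , drop = FALSE]), planted = FALSE))

    ## genes: uniform placement, category inherited from host segment
    glen <- 2000L
    gframe <- placeUniform(nGenes, transform(segments, end = end - glen))
    genes <- data.frame(gene = sprintf("g%04d", seq_len(nGenes)),
                        chrom = gframe$chrom, start = gframe$pos,
                        end = gframe$pos + glen, stringsAsFactors = FALSE)
    ov <- findOverlaps(.asGRanges0(genes), .asGRanges0(segments), select = "first")
    genes$category <- segments$category[ov]
    geneCategory <- setNames(genes$category, genes$gene)

    ## TF network with optional category bias
    w <- rep(1, nGenes)
    if (!is.null(tfBiasCategory))
      w[genes$category == tfBiasCategory] <- tfBiasStrength
    network <- lapply(setNames(seq_len(nTf), sprintf("TF%02d", seq_len(nTf))),
                      function(i) sample(genes$gene, targetsPerTf, prob = w))

    ## tissue expression with focal-tissue shift for a gene subset
    tissues <- c("blood", sprintf("tissue%d", seq_len(nTissues - 1L)))
    expr <- matrix(rnorm(nGenes * nTissues, 5, 1), nGenes, nTissues,
                   dimnames = list(genes$gene, tissues))
    focalGenes <- sample(genes$gene, min(nFocalGenes, nGenes))
    expr[focalGenes, "blood"] <- expr[focalGenes, "blood"] + focalShift

    list(segments = segments, snps = snps, genes = genes, network = network,
         geneCategory = geneCategory, tissueExpr = expr,
         focalGenes = focalGenes, genome = chromLengths)
  })
}
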