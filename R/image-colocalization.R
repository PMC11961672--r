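## DNA-FISH + immunofluorescence colocalization pipeline.
##
## Confocal z-stacks carry three channels: DAPI (nuclei), a FISH probe marking
## a genomic locus, and an IF marker (e.g. BRD4). Per slice, nuclei are
## segmented (Gaussian smooth, Otsu, fill holes) and FISH spots detected
## (Gaussian smooth, fixed threshold, in-nucleus filter). Per-slice objects
## are stitched in 3D by footprint overlap between adjacent slices, so one
## physical spot spanning several slices is counted once. Marker intensity is
## read out in an 11x11 window around each spot center on every slice the spot
## occupies, with out-of-nucleus / out-of-bounds entries flagged invalid; a
## per-nucleus null is built from 50 randomly allocated in-nucleus centers.
## Positionwise medians over spots and over random centers give the
## enrichment-ratio map; pooled (FISH, marker) pixel pairs give the
## percentile-binned intensity profile and its rank correlation.

#' @importFrom EBImage makeBrush filter2 otsu fillHull bwlabel Image imageData
NULL

#' Construct a three-channel image stack
#'
#' @param dapi,fish,marker numeric \code{H x W x Z} arrays (a matrix is
#'   treated as a single-slice stack) with intensities in [0, 1].
#' @return a [ChannelStack-class].
#' @export
ChannelStack <- function(dapi, fish, marker) {
  as3d <- function(a) {
    if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
    a
  }
  new("ChannelStack", dapi = as3d(dapi), fish = as3d(fish), marker = as3d(marker))
}

.gaussSmooth <- function(slice, size, sigma) {
  brush <- makeBrush(size, shape = "Gaussian", sigma = sigma)
  brush <- brush / sum(brush)
  as.matrix(imageData(filter2(Image(slice), brush)))
}

#' Segment nuclei on one DAPI slice
#'
#' Gaussian-smooths the DAPI slice (31x31 brush, sigma 5 by default),
#' thresholds it with Otsu's method, binarizes and fills holes.
#'
#' @param dapiSlice numeric matrix, intensities in [0, 1].
#' @param brushSize,brushSigma Gaussian brush parameters.
#' @param minContrast minimum foreground-background intensity contrast (after
#'   smoothing) for the Otsu split to be trusted; below it the slice is
#'   treated as empty (Otsu always splits even pure noise).
#' @return logical matrix nucleus mask.
#' @export
segmentNucleiSlice <- function(dapiSlice, brushSize = 31L, brushSigma = 5,
                               minContrast = 0.1) {
  stopifnot(is.matrix(dapiSlice), length(dapiSlice) > 0)
  if (diff(range(dapiSlice)) == 0) {
    warning("constant DAPI slice: Otsu threshold undefined, returning empty mask")
    return(matrix(FALSE, nrow(dapiSlice), ncol(dapiSlice)))
  }
  sm <- .gaussSmooth(dapiSlice, brushSize, brushSigma)
  sm <- pmin(pmax(sm, 0), 1)
  th <- otsu(Image(sm))
  mask <- sm > th
  if (!any(mask) || !any(!mask) ||
      mean(sm[mask]) - mean(sm[!mask]) < minContrast) {
    warning("DAPI slice has no usable foreground contrast, returning empty mask")
    return(matrix(FALSE, nrow(dapiSlice), ncol(dapiSlice)))
  }
  filled <- imageData(fillHull(Image(mask * 1)))
  matrix(filled > 0, nrow(dapiSlice), ncol(dapiSlice))
}

#' Detect FISH spots on one slice
#'
#' Gaussian-smooths the FISH slice (9x9 brush, sigma 5 by default), applies a
#' fixed intensity threshold and labels connected components. Components with
#' any pixel outside the nucleus mask are discarded (spots must lie fully
#' within nuclei).
#'
#' @param fishSlice numeric matrix in [0, 1].
#' @param threshold absolute intensity cutoff in (0, 1]; see
#'   [defaultSpotThreshold()] for the default heuristic.
#' @param nucleusMask logical matrix, same shape.
#' @param brushSize,brushSigma Gaussian brush parameters.
#' @return integer label matrix (0 = background), labels renumbered 1..k, with
#'   attribute \code{smoothed} carrying the smoothed slice.
#' @export
detectSpotsSlice <- function(fishSlice, threshold, nucleusMask,
                             brushSize = 9L, brushSigma = 5) {
  stopifnot(is.matrix(fishSlice), identical(dim(fishSlice), dim(nucleusMask)))
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be a single value in (0, 1]", call. = FALSE)
  sm <- .gaussSmooth(fishSlice, brushSize, brushSigma)
  lab <- imageData(bwlabel(Image(sm > threshold)))
  lab <- matrix(as.integer(lab), nrow(fishSlice))
  keep <- integer(0)
  for (l in setdiff(unique(as.vector(lab)), 0L)) {
    if (all(nucleusMask[lab == l])) keep <- c(keep, l)
  }
  out <- matrix(0L, nrow(fishSlice), ncol(fishSlice))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  attr(out, "smoothed") <- sm
  out
}

#' Default per-stack spot-detection threshold
#'
#' Heuristic standing in for a manually picked stringent cutoff: mean plus
#' \code{k} standard deviations of the smoothed FISH channel over the whole
#' stack.
#'
#' @param fishStack numeric \code{H x W x Z} array.
#' @param k multiplier on the SD (default 6).
#' @param brushSize,brushSigma smoothing parameters matched to detection.
#' @return scalar threshold, clamped to (0, 1].
#' @export
defaultSpotThreshold <- function(fishStack, k = 6, brushSize = 9L, brushSigma = 5) {
  if (is.matrix(fishStack)) fishStack <- array(fishStack, c(dim(fishStack), 1L))
  sm <- vapply(seq_len(dim(fishStack)[3]),
               function(z) .gaussSmooth(fishStack[, , z], brushSize, brushSigma),
               matrix(0, dim(fishStack)[1], dim(fishStack)[2]))
  min(max(mean(sm) + k * sd(sm), 1e-6), 1)
}

#' Refine a spot center to the brightest pixel
#'
#' Computes the moment centroid of a spot region, then shifts the center to
#' the brightest pixel of the intensity image within the region. Ties are
#' broken by the lexicographically smallest (row, col).
#'
#' @param region logical matrix marking the spot's pixels.
#' @param intensitySlice numeric matrix of the FISH channel (same shape).
#' @return integer vector \code{c(row, col)}.
#' @export
refineSpotCenter <- function(region, intensitySlice) {
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty spot region", call. = FALSE)
  vals <- intensitySlice[idx]
  mx <- max(vals)
  cand <- idx[vals == mx, , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  c(row = cand[1, 1], col = cand[1, 2])
}

## Union-find over (z, label) nodes: objects on adjacent slices are merged
## when their 2D footprints overlap by >= 1 pixel.
.stitch3d <- function(labArray) {
  d <- dim(labArray)
  nodes <- character(0)
  parent <- integer(0)
  key <- function(z, l) paste0(z, ":", l)
  addNode <- function(k) {
    if (!k %in% nodes) {
      nodes <<- c(nodes, k)
      parent <<- c(parent, length(nodes))
    }
    match(k, nodes)
  }
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (z in seq_len(d[3])) {
    for (l in setdiff(unique(as.vector(labArray[, , z])), 0L))
      addNode(key(z, l))
  }
  if (d[3] > 1) {
    for (z in seq_len(d[3] - 1)) {
      a <- labArray[, , z]; b <- labArray[, , z + 1]
      both <- a > 0 & b > 0
      if (!any(both)) next
      pairs <- unique(cbind(a[both], b[both]))
      for (r in seq_len(nrow(pairs)))
        union(addNode(key(z, pairs[r, 1])), addNode(key(z + 1, pairs[r, 2])))
    }
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  out <- array(0L, d)
  for (i in seq_along(nodes)) {
    zl <- strsplit(nodes[i], ":", fixed = TRUE)[[1]]
    z <- as.integer(zl[1]); l <- as.integer(zl[2])
    sl <- out[, , z]
    sl[labArray[, , z] == l] <- ids[i]
    out[, , z] <- sl
  }
  out
}

#' Stitch per-slice objects into 3D volumes
#'
#' Merges labeled 2D objects on adjacent z-slices into single 3D objects
#' whenever their footprints overlap by at least one pixel, assigning one id
#' per physical object (nucleus volume or FISH spot). Objects separated by a
#' gap slice stay distinct.
#'
#' @param labelSlices list of integer label matrices ordered by z, or an
#'   integer \code{H x W x Z} array.
#' @return integer \code{H x W x Z} array of stitched 3D labels.
#' @export
stitchVolumes <- function(labelSlices) {
  if (is.list(labelSlices)) {
    d <- dim(labelSlices[[1]])
    labelSlices <- array(unlist(labelSlices), c(d, length(labelSlices)))
  }
  storage.mode(labelSlices) <- "integer"
  .stitch3d(labelSlices)
}

#' Randomly allocate centers within a nucleus volume
#'
#' Samples \code{n} voxels uniformly with replacement from a nucleus's voxel
#' set, to measure the background marker signal expected anywhere in that
#' nucleus. Reproducible given the seed.
#'
#' @param voxels integer matrix with columns \code{z}, \code{row}, \code{col}
#'   listing the nucleus's voxels.
#' @param n number of centers (default 50).
#' @param seed integer.
#' @return integer matrix \code{n x 3} (z, row, col).
#' @export
allocateRandomCenters <- function(voxels, n = 50L, seed = 1L) {
  voxels <- as.matrix(voxels)
  if (nrow(voxels) == 0L) stop("empty nucleus: no voxels to sample", call. = FALSE)
  idx <- .withSeed(seed, sample.int(nrow(voxels), n, replace = TRUE))
  out <- voxels[idx, , drop = FALSE]
  colnames(out) <- c("z", "row", "col")
  out
}

#' Extract an 11x11 marker window around a center
#'
#' Copies marker intensities in a square window centered on a spot center.
#' Positions outside the image bounds or outside the nuclear volume on that
#' slice are set to 0 and flagged invalid so they drop out of downstream
#' aggregation.
#'
#' @param markerSlice numeric matrix (IF channel, one slice).
#' @param center integer \code{c(row, col)}.
#' @param nucleusMask logical matrix: the spot's nucleus on this slice.
#' @param size odd window edge length (default 11).
#' @return list with \code{values} (numeric size x size) and \code{valid}
#'   (logical size x size).
#' @export
extractWindow <- function(markerSlice, center, nucleusMask, size = 11L) {
  stopifnot(size %% 2 == 1)
  h <- (size - 1L) %/% 2L
  vals <- matrix(0, size, size)
  valid <- matrix(FALSE, size, size)
  for (i in seq_len(size)) {
    r <- center[1] + i - 1L - h
    for (j in seq_len(size)) {
      cc <- center[2] + j - 1L - h
      if (r >= 1 && r <= nrow(markerSlice) && cc >= 1 && cc <= ncol(markerSlice) &&
          nucleusMask[r, cc]) {
        vals[i, j] <- markerSlice[r, cc]
        valid[i, j] <- TRUE
      }
    }
  }
  list(values = vals, valid = valid)
}

## valid-aware mean of a list of windows (one per slice a spot occupies)
.averageWindows <- function(windows) {
  size <- nrow(windows[[1]]$values)
  num <- matrix(0, size, size); cnt <- matrix(0, size, size)
  for (w in windows) {
    num <- num + w$values * w$valid
    cnt <- cnt + w$valid
  }
  list(values = ifelse(cnt > 0, num / pmax(cnt, 1), 0), valid = cnt > 0)
}

#' Aggregate spot and random-center windows into an enrichment map
#'
#' Each genuine spot contributes one window (already averaged over the slices
#' it spans, over valid entries only); the positionwise median over spots
#' gives the spot map, the same over random centers the background map, and
#' their elementwise ratio the enrichment map. Positions with no valid
#' observation are NA.
#'
#' @param spotWindows,randomWindows lists of \code{list(values, valid)}.
#' @return an [EnrichmentMap-class].
#' @export
aggregateEnrichment <- function(spotWindows, randomWindows) {
  if (!length(spotWindows) || !length(randomWindows))
    stop("need at least one spot window and one random window", call. = FALSE)
  posMedian <- function(ws) {
    size <- nrow(ws[[1]]$values)
    out <- matrix(NA_real_, size, size)
    for (i in seq_len(size)) for (j in seq_len(size)) {
      v <- vapply(ws, function(w) if (w$valid[i, j]) w$values[i, j] else NA_real_,
                  numeric(1))
      v <- v[!is.na(v)]
      if (length(v)) out[i, j] <- median(v)
    }
    out
  }
  sp <- posMedian(spotWindows)
  rd <- posMedian(randomWindows)
  new("EnrichmentMap", spotMedian = sp, randomMedian = rd, ratio = sp / rd,
      nSpots = length(spotWindows), nRandom = length(randomWindows))
}

#' Percentile-binned marker-vs-FISH intensity profile
#'
#' Pools paired (FISH, marker) pixel intensities from the spot windows, bins
#' the FISH intensities into \code{nBins} quantile bins (5\% percentiles by
#' default) and reports the median marker intensity per bin. Association is
#' the Spearman rank correlation of the (bin index, bin median) pairs, with a
#' permutation p-value obtained by shuffling the marker values relative to the
#' FISH values.
#'
#' @param fishValues,markerValues paired numeric vectors.
#' @param nBins number of quantile bins (default 20).
#' @param nPerm permutation count for the p-value (default 10000).
#' @param seed integer.
#' @return list with \code{binMedians} (length \code{nBins}, NA for empty
#'   bins), \code{rho} (Spearman), \code{pValue}.
#' @export
binnedIntensityProfile <- function(fishValues, markerValues, nBins = 20L,
                                   nPerm = 10000L, seed = 1L) {
  stopifnot(length(fishValues) == length(markerValues))
  keep <- is.finite(fishValues) & is.finite(markerValues)
  fishValues <- fishValues[keep]; markerValues <- markerValues[keep]
  if (length(fishValues) < nBins)
    stop("need at least nBins paired values", call. = FALSE)
  if (diff(range(fishValues)) == 0)
    stop("degenerate input: all FISH values identical, cannot bin", call. = FALSE)
  breaks <- quantile(fishValues, probs = seq(0, 1, length.out = nBins + 1L))
  breaks <- unique(breaks)
  bins <- cut(fishValues, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  groups <- split(seq_along(markerValues), bins)
  medFor <- function(vals) vapply(groups, function(ix) median(vals[ix]), numeric(1))
  binMed <- medFor(markerValues)
  usedBins <- as.integer(names(groups))
  rho <- cor(usedBins, binMed, method = "spearman")
  perm <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      pm <- medFor(markerValues[sample.int(length(markerValues))])
      cor(usedBins, pm, method = "spearman")
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(rho))) / (nPerm + 1)
  full <- rep(NA_real_, nBins)
  full[usedBins] <- binMed
  list(binMedians = full, rho = rho, pValue = p)
}

#' Run the full DNA-FISH / marker colocalization pipeline
#'
#' Executes nucleus segmentation, spot detection, center refinement, 3D
#' stitching, the random-center null, window extraction and aggregation, and
#' the binned intensity profile on a three-channel stack.
#'
#' @param stack a [ChannelStack-class].
#' @param threshold FISH detection threshold; \code{NULL} uses
#'   [defaultSpotThreshold()].
#' @param nRandom random centers per nucleus (default 50).
#' @param windowSize odd window edge (default 11).
#' @param seed integer, drives the random-center null and the permutation
#'   p-value.
#' @param nPermProfile permutations for the profile p-value.
#' @return list with elements \code{spots} (data.frame: spot id, nucleus id,
#'   z range, per-spot center rows), \code{nNuclei}, \code{enrichment}
#'   ([EnrichmentMap-class]), \code{profile}, \code{threshold}, \code{seed}.
#' @export
runColocalization <- function(stack, threshold = NULL, nRandom = 50L,
                              windowSize = 11L, seed = 1L, nPermProfile = 2000L) {
  stopifnot(is(stack, "ChannelStack"))
  d <- dim(stack)
  Z <- d[3]
  if (is.null(threshold)) threshold <- defaultSpotThreshold(fish(stack))

  nucMasks <- vector("list", Z)
  nucLab <- array(0L, d)
  spotLab <- array(0L, d)
  fishSmooth <- array(0, d)
  for (z in seq_len(Z)) {
    nucMasks[[z]] <- suppressWarnings(segmentNucleiSlice(dapi(stack)[, , z]))
    nucLab[, , z] <- matrix(as.integer(imageData(bwlabel(Image(nucMasks[[z]] * 1)))), d[1])
    sl <- detectSpotsSlice(fish(stack)[, , z], threshold, nucMasks[[z]])
    fishSmooth[, , z] <- attr(sl, "smoothed")
    attr(sl, "smoothed") <- NULL
    spotLab[, , z] <- sl
  }
  nuc3d <- stitchVolumes(nucLab)
  spot3d <- stitchVolumes(spotLab)

  spotIds <- setdiff(unique(as.vector(spot3d)), 0L)
  if (!length(spotIds))
    return(list(spots = data.frame(), nNuclei = 0L, enrichment = NULL,
                profile = NULL, threshold = threshold, seed = seed))

  ## per (spot, z): refined center; nucleus id from the 3D nucleus labels
  centers <- list()
  for (sid in spotIds) {
    for (z in seq_len(Z)) {
      reg <- spot3d[, , z] == sid
      if (!any(reg)) next
      ctr <- refineSpotCenter(reg, fishSmooth[, , z])
      nid <- nuc3d[, , z][ctr[1], ctr[2]]
      if (nid == 0L) {  # center on boundary artifact: take region's modal nucleus
        nid <- as.integer(names(which.max(table(nuc3d[, , z][reg]))))
      }
      centers[[length(centers) + 1L]] <-
        data.frame(spot = sid, nucleus = nid, z = z,
                   row = unname(ctr[1]), col = unname(ctr[2]))
    }
  }
  spots <- do.call(rbind, centers)
  keptNuclei <- sort(unique(spots$nucleus))

  ## marker windows per spot (averaged over slices) against its own nucleus mask
  spotWins <- lapply(split(spots, spots$spot), function(ss) {
    ws <- lapply(seq_len(nrow(ss)), function(i) {
      nmask <- nuc3d[, , ss$z[i]] == ss$nucleus[i]
      extractWindow(marker(stack)[, , ss$z[i]], c(ss$row[i], ss$col[i]),
                    nmask, windowSize)
    })
    .averageWindows(ws)
  })

  ## random-center windows within spot-bearing nuclei
  randWins <- list()
  for (k in seq_along(keptNuclei)) {
    nid <- keptNuclei[k]
    vox <- which(nuc3d == nid, arr.ind = TRUE)        # (row, col, z)
    vox <- cbind(z = vox[, 3], row = vox[, 1], col = vox[, 2])
    ctrs <- allocateRandomCenters(vox, n = nRandom, seed = seed + k)
    for (i in seq_len(nrow(ctrs))) {
      nmask <- nuc3d[, , ctrs[i, "z"]] == nid
      randWins[[length(randWins) + 1L]] <-
        extractWindow(marker(stack)[, , ctrs[i, "z"]],
                      c(ctrs[i, "row"], ctrs[i, "col"]), nmask, windowSize)
    }
  }

  enr <- aggregateEnrichment(spotWins, randWins)

  ## paired FISH / marker pixels from every valid window entry of every slice
  fishVals <- numeric(0); markVals <- numeric(0)
  for (i in seq_len(nrow(spots))) {
    nmask <- nuc3d[, , spots$z[i]] == spots$nucleus[i]
    wM <- extractWindow(marker(stack)[, , spots$z[i]],
                        c(spots$row[i], spots$col[i]), nmask, windowSize)
    wF <- extractWindow(fish(stack)[, , spots$z[i]],
                        c(spots$row[i], spots$col[i]), nmask, windowSize)
    ok <- wM$valid & wF$valid
    fishVals <- c(fishVals, wF$values[ok])
    markVals <- c(markVals, wM$values[ok])
  }
  profile <- tryCatch(
    binnedIntensityProfile(fishVals, markVals, nPerm = nPermProfile, seed = seed),
    error = function(e) NULL)

  zr <- do.call(rbind, lapply(split(spots, spots$spot), function(ss)
    data.frame(spot = ss$spot[1], nucleus = ss$nucleus[1],
               zmin = min(ss$z), zmax = max(ss$z))))
  list(spots = spots, spotSummary = zr, nNuclei = length(keptNuclei),
       enrichment = enr, profile = profile, threshold = threshold, seed = seed)
}

#' Central enrichment ratio
#'
#' Median of the central \code{k x k} block of the enrichment-ratio map — the
#' headline colocalization statistic (values above 1 mean the marker is
#' enriched at the locus relative to nuclear background).
#'
#' @param map an [EnrichmentMap-class].
#' @param k central block edge (default 3).
#' @return scalar.
#' @export
centralEnrichment <- function(map, k = 3L) {
  stopifnot(is(map, "EnrichmentMap"))
  d <- dim(map@ratio)
  ctr <- (d[1] + 1L) %/% 2L
  h <- (k - 1L) %/% 2L
  median(map@ratio[(ctr - h):(ctr + h), (ctr - h):(ctr + h)], na.rm = TRUE)
}
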