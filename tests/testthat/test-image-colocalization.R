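# unit tests for the DNA-FISH / marker colocalization pipeline stages

test_that("nucleus segmentation recovers planted disks and fills holes", {
  # all-zero slice -> empty mask with warning
  expect_warning(m0 <- segmentNucleiSlice(matrix(0, 64, 64)), "constant")
  expect_false(any(m0))

  # single disk with an annular hole: one filled component, area ~ disk area
  img <- diskImage(c(192L, 192L), centers = rbind(c(96, 96)), radii = 60)
  hole <- diskImage(c(192L, 192L), centers = rbind(c(96, 96)), radii = 10,
                    value = 1, background = 0)
  img[hole == 1] <- 0.05
  mask <- segmentNucleiSlice(img)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  expect_equal(max(lab), 1)
  expect_true(all(mask[86:106, 86:106]))         # hole filled
  expect_lt(abs(sum(mask) - pi * 60^2) / (pi * 60^2), 0.1)

  # two disjoint disks -> two components
  img2 <- diskImage(c(192L, 192L), centers = rbind(c(60, 60), c(140, 140)),
                    radii = c(30, 30))
  expect_equal(max(EBImage::bwlabel(EBImage::Image(
    segmentNucleiSlice(img2) * 1))), 2)
})

test_that("spot detection keeps only spots fully inside nuclei", {
  dim <- c(160L, 160L)
  nucleus <- diskImage(dim, centers = rbind(c(80, 80)), radii = 50,
                       value = 1, background = 0) > 0
  img <- matrix(0.01, dim[1], dim[2])
  inside <- rbind(c(60, 70), c(95, 95), c(80, 55), c(70, 100), c(100, 70))
  outside <- rbind(c(20, 20), c(150, 140))
  for (i in seq_len(nrow(inside))) img <- addGaussianSpot(img, inside[i, ], 0.9, 1.5)
  for (i in seq_len(nrow(outside))) img <- addGaussianSpot(img, outside[i, ], 0.9, 1.5)
  lab <- detectSpotsSlice(img, threshold = 0.05, nucleusMask = nucleus)
  expect_equal(max(lab), nrow(inside))
  # all detected pixels inside the nucleus
  expect_true(all(nucleus[lab > 0]))

  # threshold above the global max -> nothing
  expect_equal(max(detectSpotsSlice(img, threshold = 1, nucleusMask = nucleus)), 0)

  # spot straddling the nucleus boundary is discarded
  img3 <- addGaussianSpot(matrix(0.01, dim[1], dim[2]), c(80, 129), 0.9, 1.5)
  lab3 <- detectSpotsSlice(img3, threshold = 0.05, nucleusMask = nucleus)
  expect_equal(max(lab3), 0)

  expect_error(detectSpotsSlice(img, threshold = 0, nucleusMask = nucleus),
               "threshold")
})

test_that("center refinement returns the brightest in-region pixel", {
  img <- matrix(0, 21, 21)
  region <- matrix(FALSE, 21, 21)
  region[8:14, 8:14] <- TRUE
  # asymmetric intensity: hottest pixel off the centroid
  img[8:14, 8:14] <- 0.2
  img[9, 13] <- 0.9
  expect_equal(unname(refineSpotCenter(region, img)), c(9, 13))
  # exhaustive argmax oracle
  idx <- which(region, arr.ind = TRUE)
  expect_equal(unname(refineSpotCenter(region, img)),
               unname(idx[which.max(img[idx]), ]))
  # uniform region: lexicographically smallest pixel
  expect_equal(unname(refineSpotCenter(region, matrix(1, 21, 21))), c(8, 8))
})

test_that("3D stitching follows the adjacent-slice overlap rule", {
  disk <- (diskImage(c(40L, 40L), rbind(c(20, 20)), 8, value = 1,
                     background = 0) > 0) * 1L
  empty <- matrix(0L, 40, 40)
  # same footprint on slices 1-3: one object
  st <- stitchVolumes(list(disk, disk, disk))
  expect_equal(length(setdiff(unique(as.vector(st)), 0L)), 1L)
  # gap at slice 2: two objects
  st2 <- stitchVolumes(list(disk, empty, disk))
  expect_equal(length(setdiff(unique(as.vector(st2)), 0L)), 2L)
  # two disjoint per-slice objects stay distinct
  two <- matrix(0L, 40, 40); two[5:10, 5:10] <- 1L; two[25:30, 25:30] <- 2L
  st3 <- stitchVolumes(list(two, two))
  expect_equal(length(setdiff(unique(as.vector(st3)), 0L)), 2L)
})

test_that("random center allocation is uniform, seeded and with replacement", {
  one <- cbind(z = 1L, row = 5L, col = 7L)
  ctrs <- allocateRandomCenters(one, n = 50, seed = 1)
  expect_equal(nrow(ctrs), 50L)
  expect_true(all(ctrs[, "row"] == 5L & ctrs[, "col"] == 7L))

  vox <- as.matrix(expand.grid(z = 1:2, row = 1:10, col = 1:5))
  a <- allocateRandomCenters(vox, n = 100, seed = 42)
  b <- allocateRandomCenters(vox, n = 100, seed = 42)
  c2 <- allocateRandomCenters(vox, n = 100, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c2))
  expect_error(allocateRandomCenters(vox[0, ], n = 5), "empty")

  # goodness of fit to the uniform law over voxels
  draws <- allocateRandomCenters(vox, n = 10000, seed = 7)
  key <- paste(draws[, 1], draws[, 2], draws[, 3])
  all <- paste(vox[, 1], vox[, 2], vox[, 3])
  counts <- table(factor(key, levels = all))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("window extraction flags out-of-nucleus and out-of-bounds entries", {
  marker <- matrix(0.5, 40, 40)
  nucleus <- matrix(TRUE, 40, 40)
  w <- extractWindow(marker, c(20, 20), nucleus)
  expect_true(all(w$valid))
  expect_true(all(w$values == 0.5))

  # rectangular nucleus, center 2 px from its right edge: brute-force oracle
  nucleus2 <- matrix(FALSE, 40, 40); nucleus2[10:30, 10:22] <- TRUE
  ctr <- c(20, 20)
  w2 <- extractWindow(marker, ctr, nucleus2)
  oracle <- matrix(FALSE, 11, 11)
  for (i in 1:11) for (j in 1:11) {
    r <- ctr[1] + i - 6; cc <- ctr[2] + j - 6
    oracle[i, j] <- r >= 10 && r <= 30 && cc >= 10 && cc <= 22
  }
  expect_identical(w2$valid, oracle)
  expect_true(all(w2$values[!w2$valid] == 0))

  # image-boundary clipping
  w3 <- extractWindow(marker, c(2, 20), nucleus)
  expect_false(any(w3$valid[1:3, ]))
  expect_true(w3$valid[6, 6])
})

test_that("enrichment aggregation handles identity and planted signal", {
  const <- list(values = matrix(0.3, 11, 11), valid = matrix(TRUE, 11, 11))
  m <- aggregateEnrichment(list(const), list(const))
  expect_true(all(enrichmentRatio(m) == 1))

  # planted Gaussian at the center of each spot window, flat random windows
  g <- matrix(0, 11, 11)
  for (i in 1:11) for (j in 1:11)
    g[i, j] <- 0.2 + 0.4 * exp(-((i - 6)^2 + (j - 6)^2) / (2 * 2^2))
  spotW <- replicate(30, list(values = g, valid = matrix(TRUE, 11, 11)),
                     simplify = FALSE)
  randW <- replicate(30, list(values = matrix(0.2, 11, 11),
                              valid = matrix(TRUE, 11, 11)), simplify = FALSE)
  m2 <- aggregateEnrichment(spotW, randW)
  expect_gte(enrichmentRatio(m2)[6, 6], 1.5)
  expect_gt(enrichmentRatio(m2)[6, 6], enrichmentRatio(m2)[1, 1])
})

test_that("binned intensity profile recovers coupling sign and strength", {
  set.seed(1)
  f <- runif(4000)
  p1 <- binnedIntensityProfile(f, f, nPerm = 200, seed = 1)
  expect_equal(p1$rho, 1)
  expect_true(all(diff(p1$binMedians) > 0))

  p2 <- binnedIntensityProfile(f, -f, nPerm = 200, seed = 1)
  expect_equal(p2$rho, -1)

  expect_error(binnedIntensityProfile(rep(0.5, 100), runif(100), nPerm = 10),
               "identical")
})

test_that("independent marker values give a null profile correlation", {
  nonsig <- 0L
  for (s in 1:10) {
    set.seed(s)
    f <- runif(2000); m <- runif(2000)
    p <- binnedIntensityProfile(f, m, nPerm = 400, seed = s)
    if (p$pValue > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 9L)
})

test_that("pipeline output is invariant under joint FISH/threshold rescaling", {
  sim <- simulateImageStack(dims = c(160L, 160L, 6L), nNuclei = 3, seed = 21)
  thr <- defaultSpotThreshold(fish(sim$stack))
  res1 <- runColocalization(sim$stack, threshold = thr, seed = 5,
                            nPermProfile = 50)
  half <- ChannelStack(dapi(sim$stack), fish(sim$stack) / 2, marker(sim$stack))
  res2 <- runColocalization(half, threshold = thr / 2, seed = 5,
                            nPermProfile = 50)
  expect_identical(res1$spots[c("spot", "nucleus", "z", "row", "col")],
                   res2$spots[c("spot", "nucleus", "z", "row", "col")])
  expect_equal(enrichmentRatio(res1$enrichment),
               enrichmentRatio(res2$enrichment))
})

test_that("spot centers lie inside stitched nuclei and ids are unique", {
  sim <- simulateImageStack(dims = c(192L, 192L, 8L), nNuclei = 4, seed = 31)
  res <- runColocalization(sim$stack, seed = 9, nPermProfile = 50)
  expect_gt(nrow(res$spots), 0)
  # one nucleus id per spot id
  perSpot <- tapply(res$spots$nucleus, res$spots$spot,
                    function(x) length(unique(x)))
  expect_true(all(perSpot == 1))
  # each spot contributes exactly one aggregated window
  expect_equal(res$enrichment@nSpots, length(unique(res$spots$spot)))
})
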