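# LA quantification: wall derivation, thresholding, fibrosis %, EAT, BSA.

test_that("wall derivation subtracts overlapping structures", {
  dm <- c(10L, 10L, 4L)
  la <- array(FALSE, dm); la[1:5, 1:5, 1:4] <- TRUE # 100 voxels
  mv <- array(FALSE, dm); mv[1:5, 1, 1:2] <- TRUE # 10 overlap
  off <- array(FALSE, dm)
  masks <- StructureMasks(la, off, mv, exclusions = list(), eat = off)
  wall <- deriveWallMask(masks, quiet = TRUE)
  expect_identical(sum(wall), 90L)

  # no overlap: wall identical to the intramural tracing
  mv2 <- array(FALSE, dm); mv2[8, 8, 1] <- TRUE
  wall2 <- deriveWallMask(StructureMasks(la, off, mv2), quiet = TRUE)
  expect_identical(wall2, la)

  # everything excluded errors
  expect_error(
    deriveWallMask(StructureMasks(la, off, la), quiet = TRUE),
    "wall fully excluded"
  )

  # phantom: derived wall equals the independently constructed wall label
  gt <- generatePhantom(smallSpec(seed = 41L))
  expect_identical(deriveWallMask(structureMasks(gt), quiet = TRUE), gt@wall)
})

test_that("meanSI averages inside the mask and rejects empty masks", {
  dm <- c(4L, 4L, 2L)
  img <- array(7, dm)
  m <- array(FALSE, dm); m[1:2, 1, 1] <- TRUE
  expect_identical(meanSI(img, m), 7)
  img2 <- array(0, dm); img2[1, 1, 1] <- 0; img2[2, 1, 1] <- 10
  expect_identical(meanSI(img2, m), 5)
  expect_error(meanSI(img, array(FALSE, dm), "blood_pool"), "blood_pool")
})

test_that("scar threshold is the blood/MV midpoint for all inputs", {
  expect_identical(scarThreshold(100, 200), 150)
  expect_identical(scarThreshold(0, 0), 0)
  expect_identical(scarThreshold(40, 100), 70)
  set.seed(61)
  for (i in 1:50) {
    b <- runif(1, -1e3, 1e3); m <- runif(1, -1e3, 1e3)
    expect_equal(suppressWarnings(scarThreshold(b, m)), (b + m) / 2)
  }
  expect_warning(scarThreshold(10, 5), "inverted contrast")
})

test_that("fibrosis percentage matches brute-force counting on random scenes", {
  img <- array(1, c(2, 2, 2)); img[c(1, 8)] <- 9
  wall <- array(TRUE, c(2, 2, 2))
  expect_equal(fibrosisPct(fibrosisPercentage(img, wall, 5)), 25)
  expect_equal(fibrosisPct(fibrosisPercentage(img, wall, 10)), 0)

  set.seed(62)
  for (i in 1:50) {
    dm <- c(sample(3:6, 1), sample(3:6, 1), sample(2:4, 1))
    img <- array(rnorm(prod(dm)), dm)
    wall <- array(runif(prod(dm)) < 0.5, dm)
    if (!any(wall)) wall[1, 1, 1] <- TRUE
    thr <- rnorm(1)
    got <- fibrosisPct(fibrosisPercentage(img, wall, thr))
    expect_equal(got, fibrosisBruteForce(img, wall, thr))
  }
})

test_that("fibrosis percentage is non-increasing in the threshold", {
  set.seed(63)
  img <- array(rnorm(200), c(10, 10, 2))
  wall <- array(TRUE, c(10, 10, 2))
  thrs <- sort(rnorm(15))
  pcts <- sapply(thrs, function(t) fibrosisPct(fibrosisPercentage(img, wall, t)))
  expect_true(all(diff(pcts) <= 0))
  # strict inequality at the threshold: ties are non-fibrotic
  tied <- array(5, c(2, 2, 2))
  expect_equal(fibrosisPct(fibrosisPercentage(tied, wall = array(TRUE, c(2, 2, 2)), 5)), 0)
})

test_that("quantification is invariant under axis permutation", {
  gt <- generatePhantom(smallSpec(seed = 42L))
  acq <- AcquisitionParams()
  ech <- simulateEchoes(gt, acq, noiseSigma = 0)
  wf <- separateWaterFat(ech$echo1, ech$echo2, gt@fieldMap, acq)
  fib <- quantifyFibrosis(waterImage(wf), structureMasks(gt), quiet = TRUE)
  eat <- eatVolume(structureMasks(gt))

  p <- c(3, 1, 2)
  m <- structureMasks(gt)
  permMasks <- StructureMasks(
    laIntramural = aperm(m@laIntramural, p), bloodPool = aperm(m@bloodPool, p),
    mitralValve = aperm(m@mitralValve, p),
    exclusions = lapply(m@exclusions, aperm, perm = p),
    eat = aperm(m@eat, p), spacing = m@spacing[p]
  )
  wPerm <- ImageVolume(aperm(imgData(wf@water), p), m@spacing[p])
  fibP <- quantifyFibrosis(wPerm, permMasks, quiet = TRUE)
  eatP <- eatVolume(permMasks)
  expect_equal(fibrosisPct(fibP), fibrosisPct(fib))
  expect_equal(volumeMl(eatP), volumeMl(eat))
})

test_that("EAT volumetry is exact voxel arithmetic", {
  dm <- c(16L, 16L, 4L)
  eat <- array(FALSE, dm); eat[1:8, 1:8, 1:4] <- TRUE # 256 voxels
  off <- array(FALSE, dm)
  la <- array(FALSE, dm); la[16, 16, 4] <- TRUE
  masks <- StructureMasks(la, off, off, eat = eat, spacing = c(1.25, 1.25, 2.5))
  res <- eatVolume(masks)
  expect_identical(res@eatVoxels, 256L)
  expect_identical(volumeMl(res), 1) # 256 x 3.90625 mm^3 = 1000 mm^3

  empty <- eatVolume(StructureMasks(la, off, off, eat = off))
  expect_identical(empty@eatVoxels, 0L)
  expect_identical(volumeMl(empty), 0)

  # indexed volume: 13 mL at BSA 2 m^2 -> 6.5 mL/m^2
  res2 <- eatVolume(masks, heightM = 0.36, weightKg = 400) # BSA = 2 exactly
  expect_equal(res2@bsaM2, 2)
  expect_equal(res2@volumeIndexed, volumeMl(res2) / 2)

  # EAT overlapping the blood pool is impossible
  expect_error(
    eatVolume(StructureMasks(la, bloodPool = eat, mitralValve = off, eat = eat)),
    "blood pool"
  )
})

test_that("BSA formulas evaluate their closed forms", {
  expect_equal(bsa(1.80, 72), sqrt(180 * 72 / 3600))
  expect_equal(bsa(0.36, 100), 1)
  both <- bsa(1.80, 72, "both")
  expect_named(both, c("mosteller", "dubois"))
  expect_equal(both[["dubois"]], 0.007184 * 180^0.725 * 72^0.425)
  expect_false(isTRUE(all.equal(both[["mosteller"]], both[["dubois"]])))
  expect_error(bsa(-1, 70), "positive")
  expect_error(bsa(1.7, 0), "positive")
})

test_that("pipeline recovers the designed scar fraction end to end", {
  gt <- generatePhantom(smallSpec(scarFraction = 0.30, seed = 43L))
  acq <- AcquisitionParams()
  ech <- simulateEchoes(gt, acq, noiseSigma = 0)
  fm <- estimateFieldMap(ech$echo1, ech$echo2, acq)
  wf <- separateWaterFat(ech$echo1, ech$echo2, fm, acq)
  fib <- quantifyFibrosis(waterImage(wf), structureMasks(gt), quiet = TRUE)
  expect_lte(abs(fibrosisPct(fib) - 30), 2)
})
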