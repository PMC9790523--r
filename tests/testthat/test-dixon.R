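# Two-point Dixon: field-map estimation, separation exactness, swap diagnostics.

acqStd <- AcquisitionParams()

test_that("field map is recovered for constant off-resonance", {
  # psi = 0: nothing to explain
  gt0 <- generatePhantom(smallSpec(seed = 31L))
  e0 <- simulateEchoes(gt0, acqStd, noiseSigma = 0)
  fm0 <- estimateFieldMap(e0$echo1, e0$echo2, acqStd)
  expect_lt(max(abs(imgData(fm0))), 1e-6)

  # psi = 50 Hz, inside the unambiguous range for dTE = 2.6 ms
  gt50 <- generatePhantom(smallSpec(fieldMapAmplitude = 50, seed = 31L))
  e50 <- simulateEchoes(gt50, acqStd, noiseSigma = 0)
  fm50 <- estimateFieldMap(e50$echo1, e50$echo2, acqStd)
  expect_lt(max(abs(imgData(fm50) - 50)), 1e-3)
})

test_that("smooth field gradients unwrap without swaps", {
  gt <- generatePhantom(smallSpec(
    fieldMapType = "linear-gradient", fieldMapAmplitude = 60, seed = 32L
  ))
  ech <- simulateEchoes(gt, acqStd, noiseSigma = 0)
  fm <- estimateFieldMap(ech$echo1, ech$echo2, acqStd)
  expect_lt(fieldErrForeground(fm, gt, ech), 0.5)
  wf <- separateWaterFat(ech$echo1, ech$echo2, fm, acqStd)
  expect_identical(swapRate(wf, gt, acqStd), 0)
})

test_that("all-zero input has no seed voxel", {
  z <- ImageVolume(array(0 + 0i, c(8, 8, 4)))
  expect_error(estimateFieldMap(z, z, acqStd), "no seed voxel")
})

test_that("separation is exact in the noiseless limit", {
  # pure water and pure fat uniform scenes
  for (wf_pair in list(c(1, 0), c(0, 1))) {
    gt <- uniformScene(W = wf_pair[1], F = wf_pair[2], t1 = 100, psi = 30)
    ech <- simulateEchoes(gt, acqStd, noiseSigma = 0)
    wf <- separateWaterFat(ech$echo1, ech$echo2, gt@fieldMap, acqStd)
    sig <- groundTruthSignal(gt, acqStd)
    expect_lt(max(abs(imgData(wf@water) - sig$water)), 1e-6)
    expect_lt(max(abs(imgData(wf@fat) - sig$fat)), 1e-6)
  }

  # whole phantom against ground truth: voxelwise relative error < 1e-6
  gt <- generatePhantom(smallSpec(
    fieldMapType = "smooth-bump", fieldMapAmplitude = 60, seed = 33L
  ))
  ech <- simulateEchoes(gt, acqStd, noiseSigma = 0)
  wf <- separateWaterFat(ech$echo1, ech$echo2, gt@fieldMap, acqStd)
  sig <- groundTruthSignal(gt, acqStd)
  scale <- pmax(sig$water + sig$fat, max(sig$water) * 1e-3)
  expect_lt(max(abs(imgData(wf@water) - sig$water) / scale), 1e-6)
  expect_lt(max(abs(imgData(wf@fat) - sig$fat) / scale), 1e-6)
  # self-consistency: in-phase bounds out-of-phase pointwise
  expect_true(all(imgData(wf@inPhase) >= imgData(wf@outPhase) - 1e-12))
})

test_that("near-singular echo spacing is rejected before voxel work", {
  # fat phase difference across echoes ~ 0 (dTE one full fat cycle)
  acqBad <- AcquisitionParams(te1 = 2.2, te2 = 2.2 + 1000 / 217.147, fatShift = -217.147)
  gt <- uniformScene(W = 1, F = 0.5, t1 = 100)
  ech <- simulateEchoes(gt, acqBad, noiseSigma = 0)
  expect_error(
    separateWaterFat(ech$echo1, ech$echo2, gt@fieldMap, acqBad),
    "near-singular"
  )
})

test_that("swap rate is 0 for perfect separation and 1 for exchanged outputs", {
  gt <- generatePhantom(smallSpec(seed = 34L))
  ech <- simulateEchoes(gt, acqStd, noiseSigma = 0)
  wf <- separateWaterFat(ech$echo1, ech$echo2, gt@fieldMap, acqStd)
  expect_identical(swapRate(wf, gt, acqStd), 0)

  swapped <- new("WaterFatResult",
    water = wf@fat, fat = wf@water, fieldMap = wf@fieldMap,
    inPhase = wf@inPhase, outPhase = wf@outPhase, swapMask = wf@swapMask
  )
  expect_identical(swapRate(swapped, gt, acqStd), 1)

  # empty foreground errors
  gtEq <- uniformScene(W = 0.5, F = 0.5, t1 = 100)
  echEq <- simulateEchoes(gtEq, acqStd, noiseSigma = 0)
  wfEq <- separateWaterFat(echEq$echo1, echEq$echo2, gtEq@fieldMap, acqStd)
  expect_error(swapRate(wfEq, gtEq, acqStd), "foreground")
})

test_that("noise robustness: no median swaps at 5% and RMSE grows with sigma", {
  spec <- smallSpec(fieldMapType = "linear-gradient", fieldMapAmplitude = 60)
  gt <- generatePhantom(spec)
  sig <- groundTruthSignal(gt, acqStd)

  swaps <- sapply(1:20, function(s) {
    ech <- simulateEchoes(gt, acqStd, noiseSigma = 0.05, seed = 100L + s)
    fm <- estimateFieldMap(ech$echo1, ech$echo2, acqStd)
    wf <- separateWaterFat(ech$echo1, ech$echo2, fm, acqStd)
    swapRate(wf, gt, acqStd)
  })
  expect_identical(median(swaps), 0)

  rmse <- sapply(c(0.02, 0.05, 0.10), function(sg) {
    vals <- sapply(1:3, function(s) {
      ech <- simulateEchoes(gt, acqStd, noiseSigma = sg, seed = 200L + s)
      fm <- estimateFieldMap(ech$echo1, ech$echo2, acqStd)
      wf <- separateWaterFat(ech$echo1, ech$echo2, fm, acqStd)
      sqrt(mean((imgData(wf@water) - sig$water)^2))
    })
    mean(vals)
  })
  expect_true(all(diff(rmse) > 0))
})
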