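# Digital phantom: geometry, determinism, scar placement, signal model.

test_that("phantom generation is deterministic and respects mask algebra", {
  spec <- smallSpec(seed = 11L)
  gt1 <- generatePhantom(spec)
  gt2 <- generatePhantom(spec)
  expect_identical(gt1@labels, gt2@labels)
  expect_identical(gt1@scar, gt2@scar)
  expect_identical(gt1@fieldMap, gt2@fieldMap)

  m <- structureMasks(gt1)
  expect_false(any(m@laIntramural & m@bloodPool))
  expect_false(any(m@eat & gt1@wall))
  expect_true(all(gt1@scar[gt1@wall] | !gt1@scar[gt1@wall])) # scar subset of wall
  expect_false(any(gt1@scar & !gt1@wall))
  # exclusion structures are confined to the shell, hence disjoint from EAT
  for (ex in m@exclusions) expect_false(any(ex & m@eat))
  # EAT sits immediately outside the wall: some EAT voxel touches the shell
  expect_gt(sum(m@eat), 0)
})

test_that("realized scar fraction tracks the requested fraction", {
  gt0 <- generatePhantom(smallSpec(scarFraction = 0, seed = 3L))
  expect_identical(sum(gt0@scar), 0L)

  for (f in c(0.10, 0.30, 0.55)) {
    gt <- generatePhantom(smallSpec(scarFraction = f, seed = 5L))
    realized <- sum(gt@scar) / sum(gt@wall) # brute-force voxel count
    expect_lte(abs(realized - f), 0.02)
  }
})

test_that("infeasible geometry is rejected with a named constraint", {
  expect_error(
    smallSpec(wallThickness = 0.5),
    "thinner than one in-plane voxel"
  )
  expect_error(
    smallSpec(bloodRadius = 30),
    "exceed the grid"
  )
  expect_error(smallSpec(scarFraction = 1.2), "scarFraction")
})

test_that("dual-echo signal model matches its closed forms", {
  acq <- AcquisitionParams()
  # pure water, no off-resonance: magnitude independent of TE
  gt <- uniformScene(W = 1, F = 0, t1 = 100, psi = 0)
  ech <- simulateEchoes(gt, acq, noiseSigma = 0)
  expect_equal(abs(imgData(ech$echo1)), abs(imgData(ech$echo2)), tolerance = 1e-12)
  # and the phase of every voxel is zero at both echoes
  expect_lt(max(abs(Arg(imgData(ech$echo1)))), 1e-12)
  expect_lt(max(abs(Arg(imgData(ech$echo2)))), 1e-12)

  # W = F with the fat phase at exactly pi: out-of-phase cancellation
  acqPi <- AcquisitionParams(te1 = 1, te2 = 2, tr = 7.1, fatShift = -250)
  gtWF <- uniformScene(W = 1, F = 1, t1 = 100, psi = 0)
  echPi <- simulateEchoes(gtWF, acqPi, noiseSigma = 0)
  expect_lt(max(abs(imgData(echPi$echo2))), 1e-12)

  # inversion-recovery null: A(TI/ln 2, TI) = 0, signal vanishes pre-noise
  expect_equal(inversionWeight(340 / log(2), 340), 0, tolerance = 1e-12)
  gtNull <- uniformScene(W = 1, F = 0, t1 = 340 / log(2), psi = 0)
  echNull <- simulateEchoes(gtNull, AcquisitionParams(ti = 340), noiseSigma = 0)
  expect_lt(max(abs(imgData(echNull$echo1))), 1e-12)

  # linearity: doubling densities doubles every noiseless magnitude
  gt2 <- uniformScene(W = 2, F = 0, t1 = 100, psi = 0)
  ech2 <- simulateEchoes(gt2, acq, noiseSigma = 0)
  expect_equal(abs(imgData(ech2$echo1)), 2 * abs(imgData(ech$echo1)),
    tolerance = 1e-12
  )
})

test_that("noise is seeded, reproducible and rejected when negative", {
  gt <- generatePhantom(smallSpec(seed = 2L))
  acq <- AcquisitionParams()
  e1 <- simulateEchoes(gt, acq, noiseSigma = 0.05, seed = 9L)
  e2 <- simulateEchoes(gt, acq, noiseSigma = 0.05, seed = 9L)
  e3 <- simulateEchoes(gt, acq, noiseSigma = 0.05, seed = 10L)
  expect_identical(imgData(e1$echo1), imgData(e2$echo1))
  expect_false(identical(imgData(e1$echo1), imgData(e3$echo1)))
  expect_error(simulateEchoes(gt, acq, noiseSigma = -0.1), "non-negative")
})
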