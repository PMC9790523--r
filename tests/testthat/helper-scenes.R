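# Shared fixtures: small phantom specs and hand-built single-tissue scenes.

# compact scene that still has every structure; runs in well under a second
smallSpec <- function(...) {
  args <- utils::modifyList(
    list(
      gridDim = c(32L, 32L, 16L), bloodRadius = 12, wallThickness = 3,
      eatThickness = 3, eatCoverage = 0.3, pvRadius = 5, appendageRadius = 4,
      fieldMapType = "constant", fieldMapAmplitude = 0, noiseSigma = 0
    ),
    list(...)
  )
  do.call(PhantomSpec, args)
}

# single-tissue cube scene with uniform water/fat densities, T1 and field;
# used to probe the signal model at analytically known operating points
uniformScene <- function(W, F, t1 = 100, psi = 0, gridDim = c(6L, 6L, 4L),
                         spacing = c(1.25, 1.25, 2.5)) {
  dm <- gridDim
  on <- array(TRUE, dm)
  off <- array(FALSE, dm)
  masks <- StructureMasks(
    laIntramural = on, bloodPool = off, mitralValve = off,
    exclusions = list(), eat = off, spacing = spacing
  )
  new("GroundTruth",
    water = array(W, dm), fat = array(F, dm), t1 = array(t1, dm),
    fieldMap = array(psi, dm), masks = masks,
    scar = off, wall = on, labels = array(0L, dm),
    spec = PhantomSpec(gridDim = c(16L, 16L, 8L), bloodRadius = 3,
      wallThickness = 1.5, eatThickness = 1, noiseSigma = 0, seed = 1L
    )
  )
}

# independent ICC(A,1) oracle: mean squares from stats::aov, formula applied
# directly to them (separate route from the package's own decomposition)
iccOracleAov <- function(tab) {
  n <- nrow(tab)
  k <- ncol(tab)
  df <- data.frame(
    y = as.vector(tab),
    subj = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# brute-force fibrosis percentage: explicit triple loop over the grid
fibrosisBruteForce <- function(img, wall, thr) {
  dm <- dim(img)
  nScar <- 0L
  nWall <- 0L
  for (i in seq_len(dm[1])) {
    for (j in seq_len(dm[2])) {
      for (kk in seq_len(dm[3])) {
        if (wall[i, j, kk]) {
          nWall <- nWall + 1L
          if (img[i, j, kk] > thr) nScar <- nScar + 1L
        }
      }
    }
  }
  100 * nScar / nWall
}

fieldErrForeground <- function(fm, gt, echoes, rel = 0.05) {
  mag <- (abs(imgData(echoes$echo1)) + abs(imgData(echoes$echo2))) / 2
  fg <- mag >= rel * max(mag)
  max(abs(imgData(fm)[fg] - gt@fieldMap[fg]))
}
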