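# Digital LA phantom: analytic shell geometry, scar patch placement,
# dual-echo inversion-recovery acquisition simulation.

# voxel-centre coordinates (mm) relative to the grid centre, one vector per axis
.gridCoords <- function(gridDim, spacing) {
  lapply(1:3, function(a) {
    (seq_len(gridDim[a]) - 1 - (gridDim[a] - 1) / 2) * spacing[a]
  })
}

# full coordinate arrays in column-major layout
.coordArrays <- function(gridDim, spacing) {
  cc <- .gridCoords(gridDim, spacing)
  nx <- gridDim[1]; ny <- gridDim[2]; nz <- gridDim[3]
  list(
    x = array(rep(cc[[1]], times = ny * nz), gridDim),
    y = array(rep(rep(cc[[2]], each = nx), times = nz), gridDim),
    z = array(rep(cc[[3]], each = nx * ny), gridDim)
  )
}

.fieldMapArray <- function(type, amplitude, gridDim, spacing) {
  co <- .coordArrays(gridDim, spacing)
  ext <- gridDim * spacing
  switch(type,
    "constant" = array(amplitude, gridDim),
    "linear-gradient" = amplitude * (2 * co$x / ext[1]), # spans about -amp..+amp over x
    "smooth-bump" = {
      w <- min(ext) / 4
      amplitude * exp(-(co$x^2 + co$y^2 + co$z^2) / (2 * w^2))
    },
    ldStop(sprintf("unknown field-map type '%s'", type))
  )
}

#' Generate a synthetic left-atrium scene
#'
#' Builds the analytic phantom described by a [PhantomSpec-class]: a
#' spherical blood pool inside a wall shell, a polar-cap epicardial fat
#' shell immediately outside the wall, a mitral-valve disc at the inferior
#' pole, two pulmonary-vein antra and an appendage stub cut into the
#' shell, and bright scar patches grown around seeded directions on the
#' wall until the target scar fraction is met (the realized fraction is
#' within one voxel of `round(fraction * wall voxels)`). Tissue maps
#' (water/fat density, T1) are filled from the spec's tissue table and the
#' B0 field map from its field-map model. Deterministic for a fixed seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [GroundTruth-class] scene.
#' @examples
#' gt <- generatePhantom(PhantomSpec(gridDim = c(32, 32, 16), bloodRadius = 12,
#'   eatThickness = 3, scarFraction = 0.2))
#' gt
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  gd <- spec@gridDim
  sp <- spec@spacing
  co <- .coordArrays(gd, sp)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)

  rIn <- spec@bloodRadius
  rOut <- rIn + spec@wallThickness
  rEat <- rOut + spec@eatThickness

  blood <- r < rIn
  shell <- r >= rIn & r < rOut
  if (!any(shell)) ldStop("infeasible geometry: wall shell contains no voxels")

  rs <- pmax(r, .Machine$double.eps)
  # EAT: polar cap of solid-angle fraction eatCoverage, outside the wall
  eat <- r >= rOut & r < rEat & (co$z / rs > 1 - 2 * spec@eatCoverage)

  # exclusion structures are confined to the shell so they stay disjoint from EAT
  mv <- shell & (-co$z / rs >= cos(spec@mvAngleDeg * pi / 180))
  rMid <- (rIn + rOut) / 2
  pvDir <- list(
    left_pv = c(-0.80, 0.40, 0.45),
    right_pv = c(0.80, 0.40, 0.45)
  )
  sphereAt <- function(dir, radius) {
    dir <- dir / sqrt(sum(dir^2))
    ctr <- dir * rMid
    shell & ((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2 < radius^2)
  }
  pvl <- sphereAt(pvDir$left_pv, spec@pvRadius)
  pvr <- sphereAt(pvDir$right_pv, spec@pvRadius)
  app <- sphereAt(c(-0.25, -0.90, 0.35), spec@appendageRadius)

  wall <- shell & !(mv | pvl | pvr | app)
  nWall <- sum(wall)
  if (nWall == 0L) ldStop("infeasible geometry: exclusions removed the entire wall")

  # scar patches: grow around seeded directions by angular distance
  scar <- array(FALSE, gd)
  target <- round(spec@scarFraction * nWall)
  if (target > nWall) {
    ldStop("infeasible geometry: scar patches exceed the available wall")
  }
  if (target > 0L) {
    idx <- which(wall)
    ux <- co$x[idx] / rs[idx]; uy <- co$y[idx] / rs[idx]; uz <- co$z[idx] / rs[idx]
    nP <- max(1L, spec@scarPatches)
    counts <- diff(round(seq(0, target, length.out = nP + 1)))
    taken <- logical(length(idx))
    withSeed(spec@seed, {
      for (p in seq_len(nP)) {
        if (counts[p] <= 0) next
        zs <- runif(1, -0.6, 0.95) # keep seeds away from the MV pole
        ph <- runif(1, 0, 2 * pi)
        sd <- c(sqrt(1 - zs^2) * cos(ph), sqrt(1 - zs^2) * sin(ph), zs)
        ang <- acos(pmin(1, pmax(-1, ux * sd[1] + uy * sd[2] + uz * sd[3])))
        ord <- order(ang, seq_along(ang)) # deterministic tie-break
        free <- ord[!taken[ord]]
        pick <- head(free, counts[p])
        taken[pick] <- TRUE
      }
    })
    scar[idx[taken]] <- TRUE
  }

  labels <- array(0L, gd)
  labels[blood] <- 1L
  labels[wall] <- 2L
  labels[mv] <- 4L
  labels[pvl] <- 5L
  labels[pvr] <- 6L
  labels[app] <- 7L
  labels[eat] <- 8L
  labels[scar] <- 3L

  tt <- spec@tissueTable
  lut <- function(col) {
    v <- numeric(max(tt$label) + 1L)
    v[tt$label + 1L] <- tt[[col]]
    array(v[labels + 1L], gd)
  }
  water <- lut("waterDensity")
  fat <- lut("fatDensity")
  t1 <- lut("t1")

  psi <- .fieldMapArray(spec@fieldMapType, spec@fieldMapAmplitude, gd, sp)

  masks <- StructureMasks(
    laIntramural = shell, bloodPool = blood, mitralValve = mv,
    exclusions = list(left_pv = pvl, right_pv = pvr, appendage = app),
    eat = eat, spacing = sp
  )
  new("GroundTruth",
    water = water, fat = fat, t1 = t1, fieldMap = psi, masks = masks,
    scar = scar, wall = wall, labels = labels, spec = spec
  )
}

# noiseless complex signal of one echo; te in ms, fieldMap in Hz
.echoSignal <- function(gt, acq, te) {
  A <- inversionWeight(gt@t1, acq@ti)
  teS <- te * 1e-3
  fatPhase <- exp(1i * 2 * pi * acq@fatShiftHz * teS)
  A * (gt@water + gt@fat * fatPhase) * exp(1i * 2 * pi * gt@fieldMap * teS)
}

#' Blood-pool reference signal of a scene
#'
#' Mean noiseless signal magnitude over the blood pool at the first echo;
#' the unit in which noise levels and the swap-rate foreground floor are
#' expressed.
#'
#' @param gt a [GroundTruth-class].
#' @param acq an [AcquisitionParams-class].
#' @return Scalar reference magnitude.
#' @export
bloodSignalRef <- function(gt, acq) {
  s1 <- .echoSignal(gt, acq, acq@te1)
  bp <- gt@masks@bloodPool
  ldAssert(any(bp), "scene has an empty blood pool")
  mean(abs(s1[bp]))
}

#' Expected water/fat signal magnitudes of a scene
#'
#' The inversion-weighted magnitudes `|A(T1, TI)| * density` that a perfect
#' separation recovers; used as the oracle in forward-inverse tests and as
#' the foreground reference for [swapRate()].
#'
#' @param gt a [GroundTruth-class].
#' @param acq an [AcquisitionParams-class].
#' @return List with numeric arrays `water` and `fat`.
#' @export
groundTruthSignal <- function(gt, acq) {
  A <- abs(inversionWeight(gt@t1, acq@ti))
  list(water = A * gt@water, fat = A * gt@fat)
}

#' Simulate the dual-echo LGE-Dixon acquisition
#'
#' Forward model, per voxel and echo time TE:
#' `S(TE) = A(T1, TI) * (W + F * exp(i 2 pi f_fat TE)) * exp(i 2 pi psi TE)`
#' plus i.i.d. complex Gaussian noise, where `A = 1 - 2 exp(-TI/T1)` is the
#' inversion-recovery weighting, `f_fat` the fat chemical shift (Hz) and
#' `psi` the B0 field map (Hz). The noise SD per real/imaginary channel is
#' `noiseSigma` times the noiseless blood-pool signal magnitude, so
#' magnitude images are Rician. Seeded and reproducible.
#'
#' @param gt a [GroundTruth-class] scene.
#' @param acq an [AcquisitionParams-class].
#' @param noiseSigma noise SD as a fraction of blood-pool signal; defaults
#'   to the phantom spec's value.
#' @param seed RNG seed for the noise; defaults to the phantom spec's seed.
#' @return List with complex [ImageVolume-class] elements `echo1`, `echo2`.
#' @examples
#' gt <- generatePhantom(PhantomSpec(gridDim = c(32, 32, 16), bloodRadius = 12,
#'   eatThickness = 3))
#' ech <- simulateEchoes(gt, AcquisitionParams(), noiseSigma = 0)
#' @export
simulateEchoes <- function(gt, acq, noiseSigma = gt@spec@noiseSigma,
                           seed = gt@spec@seed) {
  ldAssert(is(gt, "GroundTruth"), "gt must be a GroundTruth")
  ldAssert(is(acq, "AcquisitionParams"), "acq must be AcquisitionParams")
  ldAssert(noiseSigma >= 0, "noiseSigma must be non-negative",
    class = "lgeDixon_value_error"
  )
  s1 <- .echoSignal(gt, acq, acq@te1)
  s2 <- .echoSignal(gt, acq, acq@te2)
  if (noiseSigma > 0) {
    sig <- noiseSigma * bloodSignalRef(gt, acq)
    n <- length(s1)
    withSeed(seed, {
      s1 <- s1 + complex(real = rnorm(n, 0, sig), imaginary = rnorm(n, 0, sig))
      s2 <- s2 + complex(real = rnorm(n, 0, sig), imaginary = rnorm(n, 0, sig))
    })
    dim(s1) <- dim(gt@water)
    dim(s2) <- dim(gt@water)
  }
  sp <- voxelSpacing(gt)
  list(echo1 = ImageVolume(s1, sp), echo2 = ImageVolume(s2, sp))
}
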