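# LA quantification: wall-mask derivation, mitral-valve-referenced scar
# threshold, voxel-count fibrosis percentage, EAT volumetry, BSA.

#' Derive the LA wall mask by structure subtraction
#'
#' The wall is the LA intramural tracing minus the union of the mitral
#' valve, the exclusion structures (pulmonary-vein antra, appendage) and
#' the blood pool. The voxels removed per structure are reported via
#' `message()`.
#'
#' @param masks a [StructureMasks-class].
#' @param quiet suppress the per-structure removal log.
#' @return Logical 3D wall mask.
#' @examples
#' gt <- generatePhantom(PhantomSpec(gridDim = c(32, 32, 16), bloodRadius = 12,
#'   eatThickness = 3))
#' wall <- deriveWallMask(structureMasks(gt), quiet = TRUE)
#' identical(wall, gt@wall)
#' @export
deriveWallMask <- function(masks, quiet = FALSE) {
  ldAssert(is(masks, "StructureMasks"), "masks must be a StructureMasks")
  wall <- masks@laIntramural
  subtract <- c(
    list(mitral_valve = masks@mitralValve, blood_pool = masks@bloodPool),
    masks@exclusions
  )
  for (nm in names(subtract)) {
    removed <- sum(wall & subtract[[nm]])
    if (!quiet) message(sprintf("wall derivation: removed %d voxels overlapping %s", removed, nm))
    wall <- wall & !subtract[[nm]]
  }
  if (!any(wall)) ldStop("wall fully excluded: no voxels remain after subtraction")
  wall
}

#' Mean signal intensity inside a mask
#'
#' @param image an [ImageVolume-class] (or numeric array).
#' @param mask logical array of the same shape.
#' @param structure name used in the error message for an empty mask.
#' @return Arithmetic mean of the image values inside the mask.
#' @export
meanSI <- function(image, mask, structure = "structure") {
  img <- if (is(image, "ImageVolume")) image@data else image
  ldAssert(identical(dim(img), dim(mask)), "image and mask must share one grid")
  if (!any(mask)) {
    ldStop(sprintf("empty mask for %s: cannot compute mean SI", structure))
  }
  mean(img[mask])
}

#' Mitral-valve-referenced scar threshold
#'
#' The patient-specific threshold is the mean blood-pool signal plus half
#' the difference between the mean mitral-valve and mean blood-pool
#' signal, i.e. the midpoint `(blood + mv) / 2`. If the mitral-valve mean
#' falls below the blood mean (inverted contrast) a warning is emitted but
#' the midpoint is still returned.
#'
#' @param meanBloodSI mean LA blood-pool signal intensity.
#' @param meanMvSI mean mitral-valve signal intensity.
#' @return Threshold in signal units.
#' @examples
#' scarThreshold(100, 200) # 150
#' @export
scarThreshold <- function(meanBloodSI, meanMvSI) {
  ldAssert(
    is.finite(meanBloodSI) && is.finite(meanMvSI),
    "both mean signal intensities must be finite"
  )
  if (meanMvSI < meanBloodSI) {
    warning("inverted contrast: mitral-valve SI below blood-pool SI",
      call. = FALSE
    )
  }
  meanBloodSI + (meanMvSI - meanBloodSI) / 2
}

#' Voxel-count fibrosis percentage of the LA wall
#'
#' Scar voxels are wall voxels with signal intensity strictly greater than
#' the threshold (ties classify as non-fibrotic); the fibrosis percentage
#' is `100 * scar voxels / wall voxels`.
#'
#' @param water the water (LGE) [ImageVolume-class] or numeric array.
#' @param wall logical wall mask.
#' @param threshold scar threshold in signal units.
#' @param meanBloodSI,meanMvSI optional means recorded in the result (for
#'   provenance when the threshold was derived elsewhere).
#' @return A [FibrosisResult-class].
#' @examples
#' img <- array(c(rep(1, 6), 9, 9), c(2, 2, 2))
#' wall <- array(TRUE, c(2, 2, 2))
#' fibrosisPercentage(img, wall, 5) # 25%
#' @export
fibrosisPercentage <- function(water, wall, threshold,
                               meanBloodSI = NA_real_, meanMvSI = NA_real_) {
  img <- if (is(water, "ImageVolume")) water@data else water
  ldAssert(identical(dim(img), dim(wall)), "water image and wall mask must share one grid")
  if (!any(wall)) ldStop("empty wall mask")
  nWall <- sum(wall)
  nScar <- sum(img[wall] > threshold)
  new("FibrosisResult",
    meanBloodSI = if (is.na(meanBloodSI)) -Inf else meanBloodSI,
    meanMvSI = if (is.na(meanMvSI)) -Inf else meanMvSI,
    threshold = threshold, scarVoxels = as.integer(nScar),
    wallVoxels = as.integer(nWall),
    fibrosisPct = 100 * nScar / nWall, definition = "voxel_fraction"
  )
}

#' Quantify LA fibrosis from water image and structure masks
#'
#' Convenience wrapper running the full quantification chain: derive the
#' wall mask, measure blood-pool and mitral-valve mean SI on the water
#' image, form the midpoint threshold, and classify wall voxels.
#'
#' @param water water [ImageVolume-class].
#' @param masks a [StructureMasks-class].
#' @param quiet suppress the wall-derivation log.
#' @return A [FibrosisResult-class].
#' @export
quantifyFibrosis <- function(water, masks, quiet = FALSE) {
  wall <- deriveWallMask(masks, quiet = quiet)
  b <- meanSI(water, masks@bloodPool, "blood_pool")
  m <- meanSI(water, masks@mitralValve, "mitral_valve")
  thr <- scarThreshold(b, m)
  fibrosisPercentage(water, wall, thr, meanBloodSI = b, meanMvSI = m)
}

#' Body surface area
#'
#' Mosteller (default): `sqrt(height_cm * weight_kg / 3600)`.
#' Du Bois: `0.007184 * height_cm^0.725 * weight_kg^0.425`.
#'
#' @param heightM height in metres.
#' @param weightKg weight in kg.
#' @param formula `"mosteller"`, `"dubois"`, or `"both"` (named vector).
#' @return BSA in m^2; for `"both"` a named length-2 vector.
#' @examples
#' bsa(1.80, 72) # sqrt(3.6) ~ 1.897
#' bsa(1.80, 72, "both")
#' @export
bsa <- function(heightM, weightKg, formula = c("mosteller", "dubois", "both")) {
  formula <- match.arg(formula)
  ldAssert(is.finite(heightM) && heightM > 0, "height must be positive",
    class = "lgeDixon_value_error"
  )
  ldAssert(is.finite(weightKg) && weightKg > 0, "weight must be positive",
    class = "lgeDixon_value_error"
  )
  hCm <- heightM * 100
  mosteller <- sqrt(hCm * weightKg / 3600)
  dubois <- 0.007184 * hCm^0.725 * weightKg^0.425
  switch(formula,
    mosteller = mosteller,
    dubois = dubois,
    both = c(mosteller = mosteller, dubois = dubois)
  )
}

#' Epicardial adipose tissue volumetry
#'
#' Counts every voxel of the EAT segmentation (no signal threshold inside
#' the traced border by default) and converts to millilitres via the voxel
#' volume: `volume_ml = voxels * prod(spacing mm) / 1000`. With height and
#' weight given, the BSA-indexed volume `volume_ml / bsa_m2` is added. An
#' optional fat-fraction gate restricts the count to voxels with
#' `fat / (water + fat) > fatFractionGate` when the separated images are
#' supplied.
#'
#' @param masks a [StructureMasks-class] whose `eat` slot is the EAT mask.
#' @param heightM,weightKg optional subject height (m) and weight (kg).
#' @param bsaFormula `"mosteller"` (default) or `"dubois"`.
#' @param fatFractionGate optional fraction in (0, 1); off by default.
#' @param water,fat optional [ImageVolume-class] images, required only by
#'   the fat-fraction gate.
#' @return An [EatResult-class].
#' @examples
#' m <- array(FALSE, c(8, 8, 4)); m[1:4, 1:8, 1:4] <- TRUE # 128 voxels
#' sm <- StructureMasks(
#'   laIntramural = array(TRUE, c(8, 8, 4)),
#'   bloodPool = array(FALSE, c(8, 8, 4)),
#'   mitralValve = array(FALSE, c(8, 8, 4)), eat = m
#' )
#' volumeMl(eatVolume(sm)) # 0.5 mL at 1.25 x 1.25 x 2.5 mm voxels
#' @export
eatVolume <- function(masks, heightM = NULL, weightKg = NULL,
                      bsaFormula = c("mosteller", "dubois"),
                      fatFractionGate = NULL, water = NULL, fat = NULL) {
  ldAssert(is(masks, "StructureMasks"), "masks must be a StructureMasks")
  bsaFormula <- match.arg(bsaFormula)
  eat <- masks@eat
  if (any(eat & masks@bloodPool)) {
    ldStop("EAT mask overlaps the blood pool: topologically impossible")
  }
  if (!is.null(fatFractionGate)) {
    ldAssert(!is.null(water) && !is.null(fat),
      "fat-fraction gating needs the separated water and fat images"
    )
    w <- if (is(water, "ImageVolume")) water@data else water
    f <- if (is(fat, "ImageVolume")) fat@data else fat
    ff <- f / pmax(w + f, .Machine$double.eps)
    eat <- eat & ff > fatFractionGate
  }
  nVox <- sum(eat)
  volMl <- nVox * prod(masks@spacing) / 1000
  if (!is.null(heightM) && !is.null(weightKg)) {
    b <- bsa(heightM, weightKg, bsaFormula)
    new("EatResult",
      eatVoxels = as.integer(nVox), volumeMl = volMl, bsaM2 = b,
      volumeIndexed = volMl / b, bsaFormula = bsaFormula
    )
  } else {
    new("EatResult",
      eatVoxels = as.integer(nVox), volumeMl = volMl, bsaM2 = NA_real_,
      volumeIndexed = NA_real_, bsaFormula = NA_character_
    )
  }
}
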