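# S4 classes for the LGE-Dixon quantification pipeline.

#' ImageVolume: a 3D image with voxel spacing
#'
#' The universal image currency of the package: a 3D array (double or
#' complex) plus the voxel spacing in mm along (x, y, z). Voxel indices are
#' interpreted 0-based in a single canonical axis order; the spacing is the
#' only geometric metadata carried.
#'
#' @slot data 3D array, double or complex.
#' @slot spacing numeric length-3, voxel edge lengths in mm.
#' @export
setClass("ImageVolume",
  slots = c(data = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) {
      return("data must be a 3D array")
    }
    if (!(is.numeric(object@data) || is.complex(object@data))) {
      return("data must be numeric or complex")
    }
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
      return("spacing must be 3 positive finite values (mm)")
    }
    TRUE
  }
)

#' Construct an ImageVolume
#'
#' @param data 3D array (double or complex).
#' @param spacing voxel spacing in mm, length 3. Default is the acquisition
#'   voxel size 1.25 x 1.25 x 2.5 mm.
#' @return An [ImageVolume-class] object.
#' @examples
#' v <- ImageVolume(array(0, c(4, 4, 2)))
#' voxelSpacing(v)
#' @export
ImageVolume <- function(data, spacing = c(1.25, 1.25, 2.5)) {
  new("ImageVolume", data = data, spacing = as.numeric(spacing))
}

#' AcquisitionParams: dual-echo inversion-recovery sequence parameters
#'
#' Echo/repetition/inversion times of the dual-echo spoiled gradient echo
#' LGE-Dixon readout. The default values are the protocol settings
#' TR/TE1/TE2 = 7.1/2.2/4.8 ms at 1.5 T with a 20 degree flip angle. The
#' fat--water chemical shift defaults to the single-peak -3.4 ppm offset
#' derived from the field strength (about -217 Hz at 1.5 T).
#'
#' @slot te1,te2 echo times, ms (`te1 < te2`).
#' @slot tr repetition time, ms.
#' @slot flip flip angle, degrees.
#' @slot ti inversion time, ms.
#' @slot fieldStrength main field, Tesla.
#' @slot fatShiftHz fat--water frequency offset, Hz (negative).
#' @export
setClass("AcquisitionParams",
  slots = c(
    te1 = "numeric", te2 = "numeric", tr = "numeric", flip = "numeric",
    ti = "numeric", fieldStrength = "numeric", fatShiftHz = "numeric"
  ),
  validity = function(object) {
    for (s in c("te1", "te2", "tr", "flip", "ti", "fieldStrength", "fatShiftHz")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v)) {
        return(sprintf("%s must be a finite scalar", s))
      }
    }
    if (!(object@te1 < object@te2 && object@te2 < object@tr)) {
      return("echo/repetition times must satisfy te1 < te2 < tr")
    }
    if (object@ti <= 0) return("ti must be positive")
    if (object@fieldStrength <= 0) return("fieldStrength must be positive")
    TRUE
  }
)

#' Construct acquisition parameters
#'
#' @param te1,te2 echo times in ms.
#' @param tr repetition time in ms.
#' @param flip flip angle in degrees.
#' @param ti inversion time in ms; the default 340 ms sits at the top of the
#'   220--340 ms protocol range and near-nulls tissue with post-contrast
#'   T1 of 500 ms.
#' @param fieldStrength Tesla.
#' @param fatShift fat--water offset in Hz; `NA` derives it from
#'   `fieldStrength` via [fatShiftHz()].
#' @return An [AcquisitionParams-class] object.
#' @examples
#' acq <- AcquisitionParams()
#' acq@fatShiftHz
#' @export
AcquisitionParams <- function(te1 = 2.2, te2 = 4.8, tr = 7.1, flip = 20,
                              ti = 340, fieldStrength = 1.5, fatShift = NA) {
  if (is.na(fatShift)) fatShift <- fatShiftHz(fieldStrength)
  new("AcquisitionParams",
    te1 = te1, te2 = te2, tr = tr, flip = flip, ti = ti,
    fieldStrength = fieldStrength, fatShiftHz = fatShift
  )
}

#' StructureMasks: co-registered segmentation masks of the LA scene
#'
#' Binary masks for the structures the analysis needs: the LA intramural
#' tracing (the wall, before exclusions are subtracted), the blood pool,
#' the mitral valve, the exclusion structures (pulmonary-vein antra and
#' appendage), and the EAT segmentation. All masks share one grid and one
#' voxel spacing.
#'
#' @slot laIntramural,bloodPool,mitralValve,eat logical 3D arrays.
#' @slot exclusions named list of logical 3D arrays (PV antra, appendage).
#' @slot spacing voxel spacing, mm.
#' @export
setClass("StructureMasks",
  slots = c(
    laIntramural = "array", bloodPool = "array", mitralValve = "array",
    exclusions = "list", eat = "array", spacing = "numeric"
  ),
  validity = function(object) {
    dm <- dim(object@laIntramural)
    if (length(dm) != 3L) return("masks must be 3D arrays")
    allm <- c(
      list(
        laIntramural = object@laIntramural, bloodPool = object@bloodPool,
        mitralValve = object@mitralValve, eat = object@eat
      ),
      object@exclusions
    )
    for (nm in names(allm)) {
      m <- allm[[nm]]
      if (!is.logical(m)) return(sprintf("mask '%s' must be logical", nm))
      if (!identical(dim(m), dm)) return(sprintf("mask '%s' has mismatched shape", nm))
    }
    if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
      return("spacing must be 3 positive values")
    }
    if (!any(object@laIntramural)) return("la_intramural mask is empty")
    TRUE
  }
)

#' Construct a StructureMasks object
#'
#' @param laIntramural,bloodPool,mitralValve,eat logical 3D arrays.
#' @param exclusions named list of logical arrays (e.g. `left_pv`,
#'   `right_pv`, `appendage`).
#' @param spacing voxel spacing in mm.
#' @return A [StructureMasks-class] object.
#' @export
StructureMasks <- function(laIntramural, bloodPool, mitralValve,
                           exclusions = list(), eat = array(FALSE, dim(laIntramural)),
                           spacing = c(1.25, 1.25, 2.5)) {
  new("StructureMasks",
    laIntramural = laIntramural, bloodPool = bloodPool,
    mitralValve = mitralValve, exclusions = exclusions, eat = eat,
    spacing = as.numeric(spacing)
  )
}

#' PhantomSpec: parameters of the synthetic LA scene
#'
#' Describes the analytic digital phantom: an ellipsoidal (here spherical)
#' blood pool wrapped in a wall shell, an epicardial fat cap outside the
#' wall, exclusion structures (mitral valve disc, two pulmonary-vein antra,
#' an appendage stub) cut into the shell, bright scar patches on the wall,
#' a tissue table mapping each structure to water/fat densities and T1, a
#' smooth B0 field-map model, and the noise level and seed. Defaults
#' reproduce the study conditions: 96 x 96 x 48 grid at
#' 1.25 x 1.25 x 2.5 mm voxels, 30% target scar fraction, an EAT cap of
#' roughly 13 mL, complex noise at 5% of the blood-pool signal.
#'
#' @slot gridDim integer length-3 voxel counts.
#' @slot spacing numeric length-3 voxel size, mm.
#' @slot bloodRadius blood-pool radius, mm.
#' @slot wallThickness wall shell thickness, mm.
#' @slot scarFraction target fraction of wall voxels that are scar, in \[0, 1\].
#' @slot scarPatches number of scar patches.
#' @slot eatThickness,eatCoverage EAT shell thickness (mm) and solid-angle
#'   coverage fraction of the sphere (a polar cap).
#' @slot mvAngleDeg angular radius of the mitral-valve disc about the -z pole.
#' @slot pvRadius,appendageRadius radii (mm) of the PV antra and appendage
#'   spheres cut into the shell.
#' @slot tissueTable data.frame with columns `label`, `name`,
#'   `waterDensity`, `fatDensity`, `t1`.
#' @slot fieldMapType one of `"constant"`, `"linear-gradient"`, `"smooth-bump"`.
#' @slot fieldMapAmplitude field-map amplitude, Hz.
#' @slot noiseSigma complex noise SD as a fraction of the noiseless
#'   blood-pool signal.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  slots = c(
    gridDim = "integer", spacing = "numeric", bloodRadius = "numeric",
    wallThickness = "numeric", scarFraction = "numeric", scarPatches = "integer",
    eatThickness = "numeric", eatCoverage = "numeric", mvAngleDeg = "numeric",
    pvRadius = "numeric", appendageRadius = "numeric", tissueTable = "data.frame",
    fieldMapType = "character", fieldMapAmplitude = "numeric",
    noiseSigma = "numeric", seed = "integer"
  ),
  validity = function(object) {
    if (length(object@gridDim) != 3L || any(object@gridDim < 8L)) {
      return("gridDim must be 3 integers, each at least 8")
    }
    if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
      return("spacing must be 3 positive values (mm)")
    }
    if (object@scarFraction < 0 || object@scarFraction > 1) {
      return("scarFraction must lie in [0, 1]")
    }
    if (object@wallThickness < max(object@spacing[1:2])) {
      return("infeasible geometry: wall thinner than one in-plane voxel")
    }
    ext <- min(object@gridDim * object@spacing) / 2
    if (object@bloodRadius + object@wallThickness + object@eatThickness >= ext) {
      return("infeasible geometry: blood pool + wall + EAT shell exceed the grid")
    }
    if (object@bloodRadius <= 0) return("bloodRadius must be positive")
    if (object@eatCoverage < 0 || object@eatCoverage > 1) {
      return("eatCoverage must lie in [0, 1]")
    }
    if (!object@fieldMapType %in% c("constant", "linear-gradient", "smooth-bump")) {
      return("fieldMapType must be constant, linear-gradient or smooth-bump")
    }
    if (!is.finite(object@fieldMapAmplitude)) {
      return("fieldMapAmplitude must be finite (Hz)")
    }
    if (object@noiseSigma < 0) return("noiseSigma must be non-negative")
    tt <- object@tissueTable
    need <- c("label", "name", "waterDensity", "fatDensity", "t1")
    if (!all(need %in% names(tt))) {
      return("tissueTable must have columns label, name, waterDensity, fatDensity, t1")
    }
    if (any(!is.finite(tt$waterDensity)) || any(tt$waterDensity < 0) ||
      any(!is.finite(tt$fatDensity)) || any(tt$fatDensity < 0)) {
      return("tissue densities must be finite and non-negative")
    }
    if (any(tt$t1 <= 0)) return("tissue t1 values must be positive")
    TRUE
  }
)

#' Default tissue table of the LA phantom
#'
#' Water/fat proton densities (arbitrary units) and post-contrast T1 (ms)
#' for each structure label. Healthy wall keeps the long post-contrast T1
#' of about 500 ms that the inversion pulse targets; scar and the mitral
#' valve retain gadolinium (short T1) and stay bright; fat has T1 = 280 ms,
#' unaffected by contrast; blood-pool T1 is shortened by circulating
#' contrast. EAT carries a small water fraction so separation is exercised
#' on mixed voxels.
#'
#' @return data.frame with columns `label`, `name`, `waterDensity`,
#'   `fatDensity`, `t1`.
#' @examples
#' defaultTissueTable()
#' @export
defaultTissueTable <- function() {
  data.frame(
    label = 0:8,
    name = c(
      "background", "blood_pool", "wall", "scar", "mitral_valve",
      "left_pv", "right_pv", "appendage", "eat"
    ),
    waterDensity = c(0, 1, 1, 1, 1, 1, 1, 1, 0.1),
    fatDensity = c(0, 0, 0, 0, 0, 0, 0, 0, 1),
    t1 = c(1000, 320, 500, 250, 260, 320, 320, 320, 280),
    stringsAsFactors = FALSE
  )
}

#' Construct a phantom specification
#'
#' @param gridDim voxel counts per axis.
#' @param spacing voxel size, mm.
#' @param bloodRadius blood-pool radius, mm.
#' @param wallThickness wall thickness, mm.
#' @param scarFraction target scar fraction of wall voxels.
#' @param scarPatches number of contiguous scar patches.
#' @param eatThickness,eatCoverage EAT shell thickness (mm) and coverage
#'   fraction of the sphere.
#' @param mvAngleDeg mitral-valve disc angular radius, degrees.
#' @param pvRadius,appendageRadius exclusion-structure radii, mm.
#' @param tissueTable see [defaultTissueTable()].
#' @param fieldMapType,fieldMapAmplitude B0 field-map model and amplitude (Hz).
#' @param noiseSigma complex noise SD as a fraction of blood-pool signal.
#' @param seed integer seed controlling scar placement and noise.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- PhantomSpec(gridDim = c(48, 48, 24), bloodRadius = 20)
#' @export
PhantomSpec <- function(gridDim = c(96L, 96L, 48L), spacing = c(1.25, 1.25, 2.5),
                        bloodRadius = 28, wallThickness = 3, scarFraction = 0.30,
                        scarPatches = 3L, eatThickness = 3.5, eatCoverage = 0.28,
                        mvAngleDeg = 25, pvRadius = 8, appendageRadius = 6,
                        tissueTable = defaultTissueTable(),
                        fieldMapType = "smooth-bump", fieldMapAmplitude = 40,
                        noiseSigma = 0.05, seed = 1L) {
  new("PhantomSpec",
    gridDim = as.integer(gridDim), spacing = as.numeric(spacing),
    bloodRadius = bloodRadius, wallThickness = wallThickness,
    scarFraction = scarFraction, scarPatches = as.integer(scarPatches),
    eatThickness = eatThickness, eatCoverage = eatCoverage,
    mvAngleDeg = mvAngleDeg, pvRadius = pvRadius,
    appendageRadius = appendageRadius, tissueTable = tissueTable,
    fieldMapType = fieldMapType, fieldMapAmplitude = fieldMapAmplitude,
    noiseSigma = noiseSigma, seed = as.integer(seed)
  )
}

#' GroundTruth: the realized synthetic scene
#'
#' Source maps and masks produced by [generatePhantom()]: per-voxel water
#' and fat densities, T1, the B0 field map (Hz), the structure masks, the
#' true scar-voxel set, and the phantom's own wall mask (shell minus
#' exclusions) kept separately so wall derivation can be checked against it.
#'
#' @slot water,fat,t1,fieldMap numeric 3D arrays.
#' @slot masks a [StructureMasks-class] object.
#' @slot scar,wall logical 3D arrays.
#' @slot labels integer 3D array of structure label codes.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("GroundTruth",
  slots = c(
    water = "array", fat = "array", t1 = "array", fieldMap = "array",
    masks = "StructureMasks", scar = "array", wall = "array",
    labels = "array", spec = "PhantomSpec"
  ),
  validity = function(object) {
    dm <- dim(object@water)
    for (s in c("fat", "t1", "fieldMap", "scar", "wall", "labels")) {
      if (!identical(dim(slot(object, s)), dm)) {
        return(sprintf("map '%s' has mismatched shape", s))
      }
    }
    if (any(object@scar & !object@wall)) {
      return("true scar voxels must lie inside the wall mask")
    }
    if (any(object@masks@laIntramural & object@masks@bloodPool)) {
      return("wall shell and blood pool must be disjoint")
    }
    if (any(object@masks@eat & object@wall)) {
      return("EAT and wall must be disjoint")
    }
    TRUE
  }
)

#' WaterFatResult: output of two-point Dixon separation
#'
#' Water and fat magnitude images, the field map used (Hz), derived
#' in-phase (`water + fat`) and out-of-phase (`|water - fat|`) images, and
#' a mask flagging voxels where the water/fat assignment was ambiguous
#' (`water` and `fat` tied within tolerance; the tie-break assigns water).
#'
#' @slot water,fat,fieldMap,inPhase,outPhase [ImageVolume-class] objects.
#' @slot swapMask logical 3D array.
#' @export
setClass("WaterFatResult",
  slots = c(
    water = "ImageVolume", fat = "ImageVolume", fieldMap = "ImageVolume",
    inPhase = "ImageVolume", outPhase = "ImageVolume", swapMask = "array"
  ),
  validity = function(object) {
    dm <- dim(object@water@data)
    sp <- object@water@spacing
    for (s in c("fat", "fieldMap", "inPhase", "outPhase")) {
      v <- slot(object, s)
      if (!identical(dim(v@data), dm)) return(sprintf("%s shape mismatch", s))
      if (!isTRUE(all.equal(v@spacing, sp))) return(sprintf("%s spacing mismatch", s))
    }
    if (!identical(dim(object@swapMask), dm)) return("swapMask shape mismatch")
    if (any(object@water@data < 0) || any(object@fat@data < 0)) {
      return("water and fat magnitudes must be non-negative")
    }
    TRUE
  }
)

#' FibrosisResult: scar threshold and voxel-count fibrosis percentage
#'
#' @slot meanBloodSI,meanMvSI mean signal intensity of blood pool and
#'   mitral valve on the water image.
#' @slot threshold scar threshold (midpoint of the two means).
#' @slot scarVoxels,wallVoxels voxel counts.
#' @slot fibrosisPct percent of wall voxels classified as scar.
#' @slot definition character, fixed to `"voxel_fraction"`.
#' @export
setClass("FibrosisResult",
  slots = c(
    meanBloodSI = "numeric", meanMvSI = "numeric", threshold = "numeric",
    scarVoxels = "integer", wallVoxels = "integer", fibrosisPct = "numeric",
    definition = "character"
  ),
  validity = function(object) {
    if (object@fibrosisPct < 0 || object@fibrosisPct > 100) {
      return("fibrosisPct must lie in [0, 100]")
    }
    if (object@scarVoxels > object@wallVoxels) {
      return("scarVoxels cannot exceed wallVoxels")
    }
    if (object@meanMvSI >= object@meanBloodSI &&
      object@threshold < object@meanBloodSI) {
      return("threshold must be at least the blood-pool mean when MV SI >= blood SI")
    }
    TRUE
  }
)

#' EatResult: epicardial adipose tissue volumetry
#'
#' @slot eatVoxels voxel count of the EAT mask.
#' @slot volumeMl EAT volume in mL (`eatVoxels * voxel volume / 1000`).
#' @slot bsaM2 body surface area, m^2 (`NA` when not supplied).
#' @slot volumeIndexed BSA-indexed volume, mL/m^2 (`NA` when no BSA).
#' @slot bsaFormula name of the BSA formula used (`NA` when no BSA).
#' @export
setClass("EatResult",
  slots = c(
    eatVoxels = "integer", volumeMl = "numeric", bsaM2 = "numeric",
    volumeIndexed = "numeric", bsaFormula = "character"
  ),
  validity = function(object) {
    if (object@volumeMl < 0) return("volumeMl must be non-negative")
    if (is.na(object@bsaM2) != is.na(object@volumeIndexed)) {
      return("volumeIndexed must be present exactly when bsaM2 is")
    }
    TRUE
  }
)

#' AgreementResult: ICC and/or Bland-Altman agreement summary
#'
#' Holds the intraclass correlation ICC(A,1) with its 95% confidence
#' interval and/or the Bland-Altman bias, SD of differences and 95% limits
#' of agreement. Slots not produced by a given analysis are `NA`.
#'
#' @slot icc,ciLow,ciHigh ICC point estimate and 95% CI bounds.
#' @slot bias,sdDiff,loaLow,loaHigh Bland-Altman statistics
#'   (`loa = bias +/- 1.96 * sdDiff`).
#' @slot n,k subjects and raters/methods.
#' @slot model character label of the statistical model used.
#' @export
setClass("AgreementResult",
  slots = c(
    icc = "numeric", ciLow = "numeric", ciHigh = "numeric",
    bias = "numeric", sdDiff = "numeric", loaLow = "numeric",
    loaHigh = "numeric", n = "integer", k = "integer", model = "character"
  ),
  validity = function(object) {
    if (!is.na(object@icc)) {
      if (!is.na(object@ciLow) && object@ciLow > object@icc + 1e-12) {
        return("ciLow must not exceed the ICC estimate")
      }
      if (!is.na(object@ciHigh) && object@ciHigh < object@icc - 1e-12) {
        return("ciHigh must not fall below the ICC estimate")
      }
    }
    if (!is.na(object@bias)) {
      if (object@sdDiff < 0) return("sdDiff must be non-negative")
      lo <- object@bias - 1.96 * object@sdDiff
      hi <- object@bias + 1.96 * object@sdDiff
      if (!isTRUE(all.equal(c(lo, hi), c(object@loaLow, object@loaHigh)))) {
        return("limits of agreement must equal bias +/- 1.96 * sdDiff")
      }
    }
    TRUE
  }
)
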