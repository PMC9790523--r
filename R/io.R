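# Scene export/import: NIfTI volumes plus a JSON sidecar carrying spacing,
# acquisition parameters and the generating phantom spec.

.writeVol <- function(arr, spacing, file, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, file, datatype = datatype)
  invisible(file)
}

.readVol <- function(file, spacingExpected, tol = 1e-4) {
  ldAssert(file.exists(file), sprintf("missing scene file: %s", basename(file)))
  img <- RNifti::readNifti(file)
  pd <- RNifti::pixdim(img)[1:3]
  if (max(abs(pd - spacingExpected)) > tol) {
    ldStop(sprintf(
      "spacing mismatch in %s: file %s vs sidecar %s",
      basename(file), paste(signif(pd, 6), collapse = "x"),
      paste(signif(spacingExpected, 6), collapse = "x")
    ), class = "lgeDixon_validation_error")
  }
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  a
}

.maskFiles <- c(
  la_intramural = "mask_la_intramural.nii.gz",
  blood_pool = "mask_blood_pool.nii.gz",
  mitral_valve = "mask_mitral_valve.nii.gz",
  left_pv = "mask_left_pv.nii.gz",
  right_pv = "mask_right_pv.nii.gz",
  appendage = "mask_appendage.nii.gz",
  eat = "mask_eat.nii.gz",
  wall = "mask_wall.nii.gz",
  scar = "mask_scar.nii.gz"
)

.specToList <- function(spec) {
  list(
    gridDim = spec@gridDim, spacing = spec@spacing,
    bloodRadius = spec@bloodRadius, wallThickness = spec@wallThickness,
    scarFraction = spec@scarFraction, scarPatches = spec@scarPatches,
    eatThickness = spec@eatThickness, eatCoverage = spec@eatCoverage,
    mvAngleDeg = spec@mvAngleDeg, pvRadius = spec@pvRadius,
    appendageRadius = spec@appendageRadius,
    tissueTable = spec@tissueTable,
    fieldMapType = spec@fieldMapType,
    fieldMapAmplitude = spec@fieldMapAmplitude,
    noiseSigma = spec@noiseSigma, seed = spec@seed
  )
}

.specFromList <- function(l) {
  PhantomSpec(
    gridDim = l$gridDim, spacing = l$spacing, bloodRadius = l$bloodRadius,
    wallThickness = l$wallThickness, scarFraction = l$scarFraction,
    scarPatches = l$scarPatches, eatThickness = l$eatThickness,
    eatCoverage = l$eatCoverage, mvAngleDeg = l$mvAngleDeg,
    pvRadius = l$pvRadius, appendageRadius = l$appendageRadius,
    tissueTable = as.data.frame(l$tissueTable),
    fieldMapType = l$fieldMapType, fieldMapAmplitude = l$fieldMapAmplitude,
    noiseSigma = l$noiseSigma, seed = l$seed
  )
}

#' Export a simulated scene to NIfTI + JSON sidecar
#'
#' Writes each echo as a real/imaginary NIfTI pair, the ground-truth maps
#' (water, fat, T1, field map) as double-precision volumes, every mask as
#' an unsigned 8-bit volume plus one combined label map, and a
#' `scene.json` sidecar with `spacing_mm`, `te1_ms`, `te2_ms`, `tr_ms`,
#' `ti_ms`, `field_T`, `fat_shift_hz`, `seed`, the label codes and the
#' full phantom spec. The export round-trips losslessly through
#' [importScene()].
#'
#' @param gt a [GroundTruth-class].
#' @param echoes list with complex `echo1`/`echo2` [ImageVolume-class]s, as
#'   returned by [simulateEchoes()].
#' @param acq the [AcquisitionParams-class] used.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
exportScene <- function(gt, echoes, acq, dir) {
  ldAssert(is(gt, "GroundTruth"), "gt must be a GroundTruth")
  sp <- voxelSpacing(gt)
  dm <- dim(gt@water)
  for (nm in c("echo1", "echo2")) {
    e <- echoes[[nm]]
    ldAssert(is(e, "ImageVolume"), sprintf("%s must be an ImageVolume", nm))
    if (!identical(dim(e@data), dm)) {
      ldStop(sprintf("shape mismatch between %s and scene masks", nm),
        class = "lgeDixon_validation_error"
      )
    }
    if (max(abs(e@spacing - sp)) > 1e-9) {
      ldStop(sprintf("spacing mismatch between %s and scene masks", nm),
        class = "lgeDixon_validation_error"
      )
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  files <- character(0)
  wv <- function(arr, file, datatype) {
    p <- file.path(dir, file)
    .writeVol(arr, sp, p, datatype)
    files <<- c(files, p)
  }
  for (nm in c("echo1", "echo2")) {
    e <- echoes[[nm]]@data
    wv(Re(e), sprintf("%s_real.nii.gz", nm), "double")
    wv(Im(e), sprintf("%s_imag.nii.gz", nm), "double")
  }
  wv(gt@water, "gt_water.nii.gz", "double")
  wv(gt@fat, "gt_fat.nii.gz", "double")
  wv(gt@t1, "gt_t1.nii.gz", "double")
  wv(gt@fieldMap, "gt_fieldmap.nii.gz", "double")

  m <- gt@masks
  maskArr <- list(
    la_intramural = m@laIntramural, blood_pool = m@bloodPool,
    mitral_valve = m@mitralValve, left_pv = m@exclusions$left_pv,
    right_pv = m@exclusions$right_pv, appendage = m@exclusions$appendage,
    eat = m@eat, wall = gt@wall, scar = gt@scar
  )
  for (nm in names(maskArr)) {
    if (is.null(maskArr[[nm]])) next
    wv(array(as.integer(maskArr[[nm]]), dm), .maskFiles[[nm]], "uint8")
  }
  wv(gt@labels, "labelmap.nii.gz", "uint8")

  sidecar <- list(
    spacing_mm = sp, te1_ms = acq@te1, te2_ms = acq@te2, tr_ms = acq@tr,
    ti_ms = acq@ti, flip_deg = acq@flip, field_T = acq@fieldStrength,
    fat_shift_hz = acq@fatShiftHz, seed = gt@spec@seed,
    label_codes = list(
      background = 0, blood_pool = 1, wall = 2, scar = 3, mitral_valve = 4,
      left_pv = 5, right_pv = 6, appendage = 7, eat = 8
    ),
    phantom_spec = .specToList(gt@spec)
  )
  scPath <- file.path(dir, "scene.json")
  jsonlite::write_json(sidecar, scPath,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(files, scPath))
}

#' Import a scene exported by [exportScene()]
#'
#' Reads the sidecar, validates that every volume's pixel spacing matches
#' the sidecar's `spacing_mm` (a perturbed sidecar is rejected), and
#' reconstructs the ground truth, echoes and acquisition parameters.
#'
#' @param dir directory written by [exportScene()].
#' @return List with elements `gt` ([GroundTruth-class]), `echoes` (list of
#'   complex [ImageVolume-class]s) and `acq` ([AcquisitionParams-class]).
#' @export
importScene <- function(dir) {
  scPath <- file.path(dir, "scene.json")
  ldAssert(file.exists(scPath), "scene.json sidecar not found")
  sc <- jsonlite::read_json(scPath, simplifyVector = TRUE)
  sp <- as.numeric(sc$spacing_mm)
  ldAssert(length(sp) == 3L && all(sp > 0), "sidecar spacing_mm invalid",
    class = "lgeDixon_validation_error"
  )

  rd <- function(file) .readVol(file.path(dir, file), sp)
  e1 <- complex(real = rd("echo1_real.nii.gz"), imaginary = rd("echo1_imag.nii.gz"))
  e2 <- complex(real = rd("echo2_real.nii.gz"), imaginary = rd("echo2_imag.nii.gz"))
  water <- rd("gt_water.nii.gz")
  dm <- dim(water)
  dim(e1) <- dm; dim(e2) <- dm
  fat <- rd("gt_fat.nii.gz")
  t1 <- rd("gt_t1.nii.gz")
  psi <- rd("gt_fieldmap.nii.gz")
  lm <- function(nm) array(rd(.maskFiles[[nm]]) > 0, dm)

  spec <- .specFromList(sc$phantom_spec)
  masks <- StructureMasks(
    laIntramural = lm("la_intramural"), bloodPool = lm("blood_pool"),
    mitralValve = lm("mitral_valve"),
    exclusions = list(
      left_pv = lm("left_pv"), right_pv = lm("right_pv"),
      appendage = lm("appendage")
    ),
    eat = lm("eat"), spacing = sp
  )
  labels <- rd("labelmap.nii.gz")
  storage.mode(labels) <- "integer"
  gt <- new("GroundTruth",
    water = water, fat = fat, t1 = t1, fieldMap = psi, masks = masks,
    scar = lm("scar"), wall = lm("wall"), labels = labels, spec = spec
  )
  acq <- AcquisitionParams(
    te1 = sc$te1_ms, te2 = sc$te2_ms, tr = sc$tr_ms, flip = sc$flip_deg,
    ti = sc$ti_ms, fieldStrength = sc$field_T, fatShift = sc$fat_shift_hz
  )
  list(
    gt = gt,
    echoes = list(echo1 = ImageVolume(e1, sp), echo2 = ImageVolume(e2, sp)),
    acq = acq
  )
}
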