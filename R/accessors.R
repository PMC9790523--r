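# Accessor generics, methods and show() for the core classes.

#' Extract the voxel array from an image-like object
#' @param x an [ImageVolume-class] or [WaterFatResult-class].
#' @param ... unused.
#' @return The underlying array.
#' @export
setGeneric("imgData", function(x, ...) standardGeneric("imgData"))

#' @rdname imgData
#' @export
setMethod("imgData", "ImageVolume", function(x, ...) x@data)

#' Voxel spacing in mm
#' @param x an object carrying a spacing.
#' @return Numeric length-3 spacing in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "StructureMasks", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "GroundTruth", function(x) x@masks@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "WaterFatResult", function(x) x@water@spacing)

#' Volume of one voxel in mm^3
#' @param x an object with a voxel spacing.
#' @return Scalar voxel volume in mm^3.
#' @examples
#' voxelVolume(ImageVolume(array(0, c(2, 2, 2)))) # 3.90625
#' @export
voxelVolume <- function(x) prod(voxelSpacing(x))

#' @describeIn imgData water magnitude image of a separation result.
#' @export
setMethod("imgData", "WaterFatResult", function(x, ...) x@water@data)

#' Water image of a Dixon separation
#' @param x a [WaterFatResult-class].
#' @return An [ImageVolume-class].
#' @export
setGeneric("waterImage", function(x) standardGeneric("waterImage"))

#' @rdname waterImage
#' @export
setMethod("waterImage", "WaterFatResult", function(x) x@water)

#' Fat image of a Dixon separation
#' @param x a [WaterFatResult-class].
#' @return An [ImageVolume-class].
#' @export
setGeneric("fatImage", function(x) standardGeneric("fatImage"))

#' @rdname fatImage
#' @export
setMethod("fatImage", "WaterFatResult", function(x) x@fat)

#' Field map of a Dixon separation (Hz)
#' @param x a [WaterFatResult-class] or [GroundTruth-class].
#' @return An [ImageVolume-class] (separation result) or array (ground truth).
#' @export
setGeneric("fieldMap", function(x) standardGeneric("fieldMap"))

#' @rdname fieldMap
#' @export
setMethod("fieldMap", "WaterFatResult", function(x) x@fieldMap)

#' @rdname fieldMap
#' @export
setMethod("fieldMap", "GroundTruth", function(x) x@fieldMap)

#' Structure masks of a ground-truth scene
#' @param x a [GroundTruth-class].
#' @return A [StructureMasks-class].
#' @export
setGeneric("structureMasks", function(x) standardGeneric("structureMasks"))

#' @rdname structureMasks
#' @export
setMethod("structureMasks", "GroundTruth", function(x) x@masks)

#' Fibrosis percentage of a quantification result
#' @param x a [FibrosisResult-class].
#' @return Scalar percentage in \[0, 100\].
#' @export
setGeneric("fibrosisPct", function(x) standardGeneric("fibrosisPct"))

#' @rdname fibrosisPct
#' @export
setMethod("fibrosisPct", "FibrosisResult", function(x) x@fibrosisPct)

#' EAT volume in mL
#' @param x an [EatResult-class].
#' @return Scalar volume in mL.
#' @export
setGeneric("volumeMl", function(x) standardGeneric("volumeMl"))

#' @rdname volumeMl
#' @export
setMethod("volumeMl", "EatResult", function(x) x@volumeMl)

setMethod("show", "ImageVolume", function(object) {
  dm <- dim(object@data)
  cat(sprintf(
    "ImageVolume %d x %d x %d (%s), spacing %.4g x %.4g x %.4g mm\n",
    dm[1], dm[2], dm[3], typeof(object@data),
    object@spacing[1], object@spacing[2], object@spacing[3]
  ))
})

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf(
    "AcquisitionParams: TR/TE1/TE2 = %.3g/%.3g/%.3g ms, TI = %.3g ms, flip %.3g deg, %.3g T, fat shift %.5g Hz\n",
    object@tr, object@te1, object@te2, object@ti, object@flip,
    object@fieldStrength, object@fatShiftHz
  ))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: grid %s at %s mm, blood %.3g mm / wall %.3g mm / EAT %.3g mm (coverage %.3g),\n  scar fraction %.3g in %d patches, field map %s (%.3g Hz), noise sigma %.3g, seed %d\n",
    paste(object@gridDim, collapse = "x"),
    paste(signif(object@spacing, 4), collapse = "x"),
    object@bloodRadius, object@wallThickness, object@eatThickness,
    object@eatCoverage, object@scarFraction, object@scarPatches,
    object@fieldMapType, object@fieldMapAmplitude, object@noiseSigma,
    object@seed
  ))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth scene %s: %d wall voxels (%d scar, %.1f%%), %d EAT voxels\n",
    paste(dim(object@water), collapse = "x"),
    sum(object@wall), sum(object@scar),
    if (sum(object@wall) > 0) 100 * sum(object@scar) / sum(object@wall) else 0,
    sum(object@masks@eat)
  ))
})

setMethod("show", "WaterFatResult", function(object) {
  cat(sprintf(
    "WaterFatResult %s: water mean %.4g, fat mean %.4g, %d ambiguous voxels\n",
    paste(dim(object@water@data), collapse = "x"),
    mean(object@water@data), mean(object@fat@data), sum(object@swapMask)
  ))
})

setMethod("show", "FibrosisResult", function(object) {
  cat(sprintf(
    "FibrosisResult: %d / %d wall voxels above threshold %.5g -> %.2f%% (blood SI %.5g, MV SI %.5g; %s)\n",
    object@scarVoxels, object@wallVoxels, object@threshold,
    object@fibrosisPct, object@meanBloodSI, object@meanMvSI, object@definition
  ))
})

setMethod("show", "EatResult", function(object) {
  cat(sprintf("EatResult: %d voxels = %.4g mL", object@eatVoxels, object@volumeMl))
  if (!is.na(object@bsaM2)) {
    cat(sprintf(
      " (BSA %.4g m^2 [%s] -> %.4g mL/m^2)",
      object@bsaM2, object@bsaFormula, object@volumeIndexed
    ))
  }
  cat("\n")
})

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("AgreementResult (%s), n = %d, k = %d\n", object@model, object@n, object@k))
  if (!is.na(object@icc)) {
    cat(sprintf(
      "  ICC = %.4g (95%% CI %.4g-%.4g)\n",
      object@icc, object@ciLow, object@ciHigh
    ))
  }
  if (!is.na(object@bias)) {
    cat(sprintf(
      "  bias = %.4g, SD = %.4g, LOA [%.4g, %.4g]\n",
      object@bias, object@sdDiff, object@loaLow, object@loaHigh
    ))
  }
})
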