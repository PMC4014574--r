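#' Grid and container accessors
#'
#' Small accessor generics shared by the volume classes: \code{volData}
#' returns the raw array, \code{voxelSpacing} the voxel size in mm,
#' \code{gridDim} the grid shape, \code{channel} one contrast of a
#' \linkS4class{MultiContrastImage}, and \code{labelSet} the non-background
#' labels present in a \linkS4class{LabelMap}.
#'
#' @param x the object.
#' @param name channel name, one of fa, md, evx, evy, evz.
#' @return \code{volData}: an array; \code{voxelSpacing}, \code{gridDim}:
#'   numeric(3); \code{channel}: a \linkS4class{ScalarVolume};
#'   \code{labelSet}: sorted integer vector.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setGeneric("channel", function(x, name) standardGeneric("channel"))

#' @rdname accessors
#' @export
setGeneric("labelSet", function(x) standardGeneric("labelSet"))

#' @rdname accessors
#' @export
setMethod("volData", "ScalarVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("volData", "LabelMap", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("volData", "TensorVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ScalarVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LabelMap", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "TensorVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "MultiContrastImage",
          function(x) x@channels$fa@spacing)

#' @rdname accessors
#' @export
setMethod("gridDim", "ScalarVolume", function(x) dim(x@data))
#' @rdname accessors
#' @export
setMethod("gridDim", "LabelMap", function(x) dim(x@data))
#' @rdname accessors
#' @export
setMethod("gridDim", "TensorVolume", function(x) dim(x@data)[1:3])
#' @rdname accessors
#' @export
setMethod("gridDim", "MultiContrastImage", function(x) dim(x@channels$fa@data))

#' @rdname accessors
#' @export
setMethod("channel", "MultiContrastImage", function(x, name) {
  name <- match.arg(name, .mciChannels)
  x@channels[[name]]
})

#' @rdname accessors
#' @export
setMethod("labelSet", "LabelMap", function(x) {
  u <- sort(unique(as.integer(x@data)))
  u[u != 0L]
})

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ScalarVolume %dx%dx%d, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 3), collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "MultiContrastImage", function(object) {
  d <- gridDim(object)
  cat(sprintf("MultiContrastImage %dx%dx%d (fa, md, evx, evy, evz), spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(voxelSpacing(object), 3), collapse = "x")))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  ls <- labelSet(object)
  cat(sprintf("LabelMap %dx%dx%d, %d structures%s\n", d[1], d[2], d[3],
              length(ls),
              if (length(object@excluded))
                sprintf(" (%d excluded)", length(object@excluded)) else ""))
})

setMethod("show", "StructureIntensityModel", function(object) {
  cat(sprintf("StructureIntensityModel, K = %d\n", length(object@weights)))
  print(data.frame(weight = object@weights, mean = object@means,
                   variance = object@variances))
})

setMethod("show", "AtlasSignature", function(object) {
  cat(sprintf("AtlasSignature '%s': %d structures x 5 channels\n",
              object@atlasId, length(object@models)))
})

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@disp)
  mx <- sqrt(max(rowSums(matrix(object@disp, ncol = 3)^2)))
  cat(sprintf("DeformationField %dx%dx%d, max |u| = %.3g vox, geodesic proxy %.3g\n",
              d[1], d[2], d[3], mx, object@geodesic))
})

setMethod("show", "FusionState", function(object) {
  cat(sprintf("FusionState: iteration %d, %d atlases, %d labels\n",
              object@iteration, length(object@fields), length(object@labels)))
  if (nrow(object@history)) print(object@history)
})
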