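#' @import methods
#' @importFrom stats dnorm kmeans optim runif rnorm sd setNames
#' @importFrom utils head write.csv read.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib dtifusion, .registration = TRUE
NULL

#' ScalarVolume: a single 3D image on a regular grid
#'
#' Stores one scalar contrast (e.g. FA) as a 3D array together with the
#' voxel size in mm and the world-space position of the first voxel.
#' Voxel coordinates are 1-based and voxel-centred throughout the package.
#'
#' @slot data 3D numeric array.
#' @slot spacing numeric(3), voxel size per axis in mm; strictly positive.
#' @slot origin numeric(3), world coordinate of voxel (1,1,1) in mm.
#' @exportClass ScalarVolume
setClass("ScalarVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("ScalarVolume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 strictly positive values")
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

#' MultiContrastImage: the five DTI-derived contrasts on one grid
#'
#' An ordered 5-tuple of \linkS4class{ScalarVolume} channels: FA, MD
#' (mm^2/s), and the absolute components of the primary eigenvector
#' (|EVx|, |EVy|, |EVz|). All channels share one grid. FA and the EV
#' components lie in [0, 1], MD is non-negative, and the EV triple has unit
#' norm (within 1e-3) wherever FA > 0.
#'
#' @slot channels named list of five ScalarVolume objects
#'   (fa, md, evx, evy, evz).
#' @exportClass MultiContrastImage
setClass("MultiContrastImage", representation(channels = "list"))

.mciChannels <- c("fa", "md", "evx", "evy", "evz")

setValidity("MultiContrastImage", function(object) {
  ch <- object@channels
  if (!identical(names(ch), .mciChannels))
    return("channels must be named fa, md, evx, evy, evz in that order")
  if (!all(vapply(ch, is, logical(1), "ScalarVolume")))
    return("all channels must be ScalarVolume objects")
  d <- dim(ch$fa@data)
  for (nm in .mciChannels) {
    if (!identical(dim(ch[[nm]]@data), d))
      return(sprintf("channel '%s' grid differs in shape", nm))
    if (!isTRUE(all.equal(ch[[nm]]@spacing, ch$fa@spacing, tolerance = 1e-8)))
      return(sprintf("channel '%s' grid differs in spacing", nm))
  }
  tol <- 1e-6
  fa <- ch$fa@data
  if (any(fa < -tol | fa > 1 + tol, na.rm = TRUE)) return("FA outside [0, 1]")
  if (any(ch$md@data < -tol, na.rm = TRUE)) return("MD negative")
  for (nm in c("evx", "evy", "evz"))
    if (any(ch[[nm]]@data < -tol | ch[[nm]]@data > 1 + tol, na.rm = TRUE))
      return(sprintf("%s outside [0, 1]", nm))
  nrm <- ch$evx@data^2 + ch$evy@data^2 + ch$evz@data^2
  bad <- fa > 0 & abs(nrm - 1) > 1e-3
  if (any(bad, na.rm = TRUE))
    return(sprintf("%d voxels with FA > 0 have non-unit eigenvector norm",
                   sum(bad, na.rm = TRUE)))
  TRUE
})

#' LabelMap: an integer parcellation volume
#'
#' Label 0 is reserved for the unlabeled background; labels 1..L index
#' anatomical structures. The \code{excluded} slot lists sublabels flagged
#' as excluded from downstream analysis (e.g. CSF compartments produced by
#' \code{\link{decomposePeripheral}}).
#'
#' @slot data 3D integer array of non-negative labels.
#' @slot spacing numeric(3), voxel size in mm.
#' @slot origin numeric(3).
#' @slot excluded integer vector of label ids excluded from analysis.
#' @exportClass LabelMap
setClass("LabelMap",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 excluded = "integer"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), excluded = integer(0)))

setValidity("LabelMap", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (any(object@data < 0, na.rm = TRUE)) return("labels must be non-negative")
  if (any(object@data != round(object@data), na.rm = TRUE))
    return("labels must be integers")
  if (any(object@spacing <= 0)) return("spacing must be strictly positive")
  TRUE
})

#' TensorVolume: the six unique diffusion tensor components per voxel
#'
#' Component ordering follows the upper triangle in row order:
#' Dxx, Dxy, Dxz, Dyy, Dyz, Dzz, all in mm^2/s.
#'
#' @slot data 4D numeric array (nx, ny, nz, 6).
#' @slot spacing numeric(3).
#' @slot origin numeric(3).
#' @exportClass TensorVolume
setClass("TensorVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("TensorVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L || d[4] != 6L) return("data must be (nx, ny, nz, 6)")
  if (any(object@spacing <= 0)) return("spacing must be strictly positive")
  TRUE
})

#' StructureIntensityModel: a 1D Gaussian mixture intensity signature
#'
#' Models the intensity histogram of one contrast within one structure of
#' one atlas as a K-component Gaussian mixture.
#'
#' @slot weights mixing coefficients, non-negative, summing to 1.
#' @slot means component means in channel units.
#' @slot variances component variances in channel units squared.
#' @slot logLik final fitted log-likelihood (NA when set by hand).
#' @exportClass StructureIntensityModel
setClass("StructureIntensityModel",
  representation(weights = "numeric", means = "numeric",
                 variances = "numeric", logLik = "numeric"),
  prototype(logLik = NA_real_))

setValidity("StructureIntensityModel", function(object) {
  K <- length(object@weights)
  if (K < 1L) return("at least one component required")
  if (length(object@means) != K || length(object@variances) != K)
    return("weights, means, variances must have equal length")
  if (any(object@weights < 0)) return("weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
  if (any(object@variances <= 0)) return("variances must be positive")
  TRUE
})

#' AtlasSignature: all intensity models of one atlas
#'
#' Maps (structure, channel) to a \linkS4class{StructureIntensityModel};
#' also records structure volumes in mm^3. The background (label 0) is
#' modeled like any structure.
#'
#' @slot atlasId identifier of the atlas the models were fitted from.
#' @slot models nested list: \code{models[[label]][[channel]]} where label is
#'   the structure id as character and channel one of fa, md, evx, evy, evz.
#' @slot volumes named numeric, structure volumes in mm^3.
#' @exportClass AtlasSignature
setClass("AtlasSignature",
  representation(atlasId = "character", models = "list", volumes = "numeric"))

setValidity("AtlasSignature", function(object) {
  for (lab in names(object@models)) {
    m <- object@models[[lab]]
    if (!identical(sort(names(m)), sort(.mciChannels)))
      return(sprintf("structure %s lacks the 5 channel models", lab))
  }
  TRUE
})

#' DeformationField: dense displacement from subject to atlas coordinates
#'
#' The map is x -> x + disp(x) in 1-based voxel coordinates of the shared
#' grid (pull-back convention: atlas volumes are sampled at the mapped
#' coordinates). The geodesic slot carries a deformation-magnitude proxy
#' (accumulated norm of the smoothed greedy updates) used by
#' \code{\link{diffeoPrior}}.
#'
#' @slot disp 4D numeric array (nx, ny, nz, 3), displacement in voxels.
#' @slot geodesic accumulated deformation-magnitude proxy; 0 for identity.
#' @exportClass DeformationField
setClass("DeformationField",
  representation(disp = "array", geodesic = "numeric"),
  prototype(geodesic = 0))

setValidity("DeformationField", function(object) {
  d <- dim(object@disp)
  if (length(d) != 4L || d[4] != 3L) return("disp must be (nx, ny, nz, 3)")
  if (length(object@geodesic) != 1L || object@geodesic < 0)
    return("geodesic must be a single non-negative value")
  TRUE
})

#' AffineTransform12: a local 12-parameter affine refinement
#'
#' Parameters 1..9 are the row-order deviation of the linear part from the
#' identity matrix; parameters 10..12 are translations in voxels. The
#' transform acts about \code{center} (a structure centroid), so that the
#' zero vector is the identity map.
#'
#' @slot params numeric(12).
#' @slot center numeric(3), fixed point of the linear part, voxel coords.
#' @exportClass AffineTransform12
setClass("AffineTransform12",
  representation(params = "numeric", center = "numeric"),
  prototype(params = rep(0, 12), center = c(0, 0, 0)))

setValidity("AffineTransform12", function(object) {
  if (length(object@params) != 12L) return("params must have length 12")
  if (length(object@center) != 3L) return("center must have length 3")
  A <- diag(3) + matrix(object@params[1:9], 3, 3, byrow = TRUE)
  if (abs(det(A)) <= 1e-6) return("linear part is (near) singular")
  TRUE
})

#' AffinePrior: zero-mean diagonal Gaussian prior on affine parameters
#'
#' Defaults follow the usual small-deviation assumption for the linear
#' block (variance 0.01 for each of the 9 matrix parameters) and a weak
#' constraint on translations (variance 100, voxel units squared).
#'
#' @slot variances numeric(12), strictly positive.
#' @exportClass AffinePrior
setClass("AffinePrior", representation(variances = "numeric"),
  prototype(variances = c(rep(0.01, 9), rep(100, 3))))

setValidity("AffinePrior", function(object) {
  if (length(object@variances) != 12L || any(object@variances <= 0))
    return("variances must be 12 strictly positive values")
  TRUE
})

#' AtlasPair: a multi-contrast image with its label map
#'
#' @slot id atlas identifier.
#' @slot image the \linkS4class{MultiContrastImage}.
#' @slot labels the \linkS4class{LabelMap} on the same grid.
#' @exportClass AtlasPair
setClass("AtlasPair",
  representation(id = "character", image = "MultiContrastImage",
                 labels = "LabelMap"))

setValidity("AtlasPair", function(object) {
  if (!identical(dim(object@labels@data), dim(object@image@channels$fa@data)))
    return("image and labels must share one grid")
  TRUE
})

#' FusionConfig: settings of the EM/MAP fusion loop
#'
#' @slot maxIterations iteration cap (default 30).
#' @slot stopTolerance stop when the changed-voxel fraction drops below
#'   this value (default 1e-4).
#' @slot channelMask logical(5), which contrasts enter the likelihood
#'   (fa, md, evx, evy, evz); enables single-contrast ablations.
#' @slot initAtlas "vote" for majority-vote initialization across all
#'   propagated atlases, or the index of a designated atlas.
#' @slot verbose print per-iteration progress.
#' @exportClass FusionConfig
setClass("FusionConfig",
  representation(maxIterations = "numeric", stopTolerance = "numeric",
                 channelMask = "logical", initAtlas = "ANY",
                 verbose = "logical"),
  prototype(maxIterations = 30, stopTolerance = 1e-4,
            channelMask = rep(TRUE, 5), initAtlas = "vote", verbose = FALSE))

setValidity("FusionConfig", function(object) {
  if (object@maxIterations < 1) return("maxIterations must be >= 1")
  if (length(object@channelMask) != 5L || !any(object@channelMask))
    return("channelMask must be logical(5) with at least one TRUE")
  if (object@stopTolerance < 0) return("stopTolerance must be >= 0")
  TRUE
})

#' FusionState: the evolving state of the fusion loop
#'
#' @slot parcellation current LabelMap estimate.
#' @slot labels integer vector of candidate labels (background 0 first).
#' @slot transforms list per atlas of per-structure
#'   \linkS4class{AffineTransform12} refinements (names are label ids).
#' @slot fields list of per-atlas global \linkS4class{DeformationField}s.
#' @slot labelProbs list per atlas: voxels x labels matrix of deformed
#'   trilinear label probabilities.
#' @slot selector voxels x atlases matrix of atlas-selector weights.
#' @slot diceFactor atlases x labels matrix of structure-level overlap
#'   factors (constant within a structure).
#' @slot geodesic per-atlas deformation-magnitude proxies.
#' @slot iteration completed EM iterations.
#' @slot history per-iteration data.frame (changed fraction, surrogate
#'   objective, selector fallback count).
#' @slot flags character vector of recorded warnings (e.g. divergence).
#' @exportClass FusionState
setClass("FusionState",
  representation(parcellation = "LabelMap", labels = "integer",
                 transforms = "list", fields = "list", labelProbs = "list",
                 selector = "matrix", diceFactor = "matrix",
                 geodesic = "numeric", iteration = "integer",
                 history = "data.frame", flags = "character"),
  prototype(iteration = 0L, flags = character(0)))

#' PhantomSpec: recipe for the synthetic multi-atlas DTI phantom
#'
#' @slot dim grid shape (3 integers).
#' @slot spacing voxel size in mm.
#' @slot structures list of structure descriptors; each has \code{label},
#'   \code{name}, \code{geometry} (type + parameters in voxel units) and
#'   \code{mixtures}, a named list per channel of \code{list(weights,
#'   means, variances)} generating mixtures. EV channel means are
#'   interpreted jointly and renormalized to unit-norm triples.
#' @slot background the channel mixtures of the unlabeled background.
#' @slot deformMagnitude RMS displacement (voxels) of random atlas warps.
#' @slot deformSmoothness smoothing sigma (mm) of the random warps.
#' @slot seed base random seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(dim = "integer", spacing = "numeric", structures = "list",
                 background = "list", deformMagnitude = "numeric",
                 deformSmoothness = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 4L))
    return("dim must be 3 integers >= 4")
  if (any(object@spacing <= 0)) return("spacing must be strictly positive")
  if (object@deformMagnitude < 0) return("deformMagnitude must be >= 0")
  TRUE
})
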