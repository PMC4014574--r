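# NIfTI-1 I/O. Volumes are stored with a diagonal sform built from the
# voxel spacing and origin; label volumes are written as unsigned integers.

.volXform <- function(spacing, origin) {
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  m
}

#' Read and write single volumes as NIfTI
#'
#' \code{readScalarVolume} / \code{writeScalarVolume} handle floating-point
#' contrasts; \code{readLabelMapNifti} / \code{writeLabelMapNifti} handle
#' integer parcellation volumes. Spacing and origin are carried in the
#' NIfTI header (pixdim + sform) and round-trip exactly for the supported
#' dialect (axis-aligned grids).
#'
#' @param path file path (.nii or .nii.gz).
#' @param vol,labels the volume to write.
#' @return The read object, or (invisibly) \code{path} for the writers.
#' @name volumeIO
#' @rdname volumeIO
#' @export
readScalarVolume <- function(path) {
  .stopIf(!file.exists(path), "file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  .stopIf(length(d) != 3L, "expected a 3D volume in %s (got %dD)", path, length(d))
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  scalarVolume(array(as.numeric(img), d),
               spacing = RNifti::pixdim(img), origin = origin)
}

#' @rdname volumeIO
#' @export
writeScalarVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::qform(img) <- structure(.volXform(vol@spacing, vol@origin), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname volumeIO
#' @export
readLabelMapNifti <- function(path) {
  .stopIf(!file.exists(path), "file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  .stopIf(length(d) != 3L, "expected a 3D label volume in %s", path)
  v <- as.numeric(img)
  .stopIf(any(v < 0) || any(v != round(v)),
          "label volume %s contains negative or non-integer values", path)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  labelMap(array(as.integer(v), d), spacing = RNifti::pixdim(img),
           origin = origin)
}

#' @rdname volumeIO
#' @export
writeLabelMapNifti <- function(labels, path) {
  img <- RNifti::asNifti(labels@data)
  RNifti::pixdim(img) <- labels@spacing
  RNifti::qform(img) <- structure(.volXform(labels@spacing, labels@origin),
                                  code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint16")
  invisible(path)
}

#' Read a multi-contrast image from a set of NIfTI files
#'
#' The default layout expects files \code{<stem>_fa.nii.gz},
#' \code{<stem>_md.nii.gz}, \code{<stem>_evx/evy/evz.nii.gz} (and, for
#' \code{readAtlasPair}, \code{<stem>_labels.nii.gz}); a bare \code{.nii}
#' extension is also accepted. Alternatively pass a named list/vector of
#' five explicit paths.
#'
#' @param stem path stem, or a named character vector with entries fa, md,
#'   evx, evy, evz (and labels for \code{readAtlasPair}).
#' @param clamp,naAction passed to \code{\link{multiContrastImage}}.
#' @param id atlas identifier for \code{readAtlasPair}.
#' @return A \linkS4class{MultiContrastImage} or \linkS4class{AtlasPair}.
#'   Grids must agree across channels; a shape or spacing mismatch is an
#'   error.
#' @rdname readMultiContrast
#' @export
readMultiContrast <- function(stem, clamp = FALSE,
                              naAction = c("reject", "mask")) {
  paths <- .channelPaths(stem, .mciChannels)
  vols <- lapply(paths, readScalarVolume)
  multiContrastImage(vols$fa, vols$md, vols$evx, vols$evy, vols$evz,
                     clamp = clamp, naAction = naAction)
}

#' @rdname readMultiContrast
#' @export
readAtlasPair <- function(stem, id = basename(stem), clamp = FALSE) {
  img <- readMultiContrast(stem, clamp = clamp)
  lab <- readLabelMapNifti(.channelPaths(stem, "labels")[[1]])
  .stopIf(!identical(gridDim(img), dim(lab@data)),
          "label grid does not match the channel grids for %s", stem[1])
  atlasPair(id, img, lab)
}

#' Write a multi-contrast image (and optionally labels) as NIfTI files
#'
#' @param img a \linkS4class{MultiContrastImage}.
#' @param stem output path stem; files \code{<stem>_<channel>.nii.gz} are
#'   written.
#' @param labels optional \linkS4class{LabelMap} written as
#'   \code{<stem>_labels.nii.gz}.
#' @return Invisibly, the written paths.
#' @export
writeMultiContrast <- function(img, stem, labels = NULL) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in .mciChannels) {
    p <- sprintf("%s_%s.nii.gz", stem, nm)
    writeScalarVolume(img@channels[[nm]], p)
    paths <- c(paths, p)
  }
  if (!is.null(labels)) {
    p <- sprintf("%s_labels.nii.gz", stem)
    writeLabelMapNifti(labels, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

.channelPaths <- function(stem, channels) {
  if (length(stem) > 1L || !is.null(names(stem))) {
    .stopIf(!all(channels %in% names(stem)),
            "explicit paths must be named: %s", paste(channels, collapse = ", "))
    return(as.list(stem[channels]))
  }
  out <- list()
  for (nm in channels) {
    cand <- sprintf("%s_%s%s", stem, nm, c(".nii.gz", ".nii"))
    hit <- cand[file.exists(cand)]
    .stopIf(length(hit) == 0L, "missing channel file: %s_%s.nii[.gz]", stem, nm)
    out[[nm]] <- hit[1]
  }
  out
}
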