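# Derivation of the five fusion contrasts from a diffusion tensor volume,
# and the threshold-based peripheral tissue decomposition.

#' Compute FA, MD and primary-eigenvector contrasts from a tensor volume
#'
#' Per voxel the symmetric tensor is eigen-decomposed; negative eigenvalues
#' (noise) are clamped to zero before computing MD (mean eigenvalue) and
#' FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||. The EV channels are the
#' componentwise absolute values of the unit eigenvector of the largest
#' eigenvalue; the sign degeneracy of eigenvectors is resolved by the
#' absolute value, at the documented cost of some orientation information.
#' All-zero tensors yield FA = 0, MD = 0 and EV = (0, 0, 0); such voxels
#' are exempt from the unit-norm invariant because their FA is 0.
#'
#' @param t a \linkS4class{TensorVolume}.
#' @return A \linkS4class{MultiContrastImage} on the same grid. The number
#'   of voxels with clamped negative eigenvalues is reported via a message.
#' @export
tensorToContrasts <- function(t) {
  d <- dim(t@data)[1:3]
  nvox <- prod(d)
  d6 <- matrix(t@data, nrow = nvox, ncol = 6)
  eg <- .cpp_tensor_eig(d6)
  lam <- eg$values
  nClamped <- sum(rowSums(lam < 0) > 0)
  if (nClamped > 0)
    message(sprintf("tensorToContrasts: clamped negative eigenvalues in %d voxels",
                    nClamped))
  lam[lam < 0] <- 0
  md <- rowMeans(lam)
  nrm <- sqrt(rowSums(lam^2))
  dev <- sqrt(rowSums((lam - md)^2))
  fa <- ifelse(nrm > 0, sqrt(1.5) * dev / nrm, 0)
  fa <- pmin(pmax(fa, 0), 1)
  ev <- abs(eg$vector)
  zero <- nrm == 0
  ev[zero, ] <- 0
  md[zero] <- 0
  toVol <- function(v) scalarVolume(array(v, d), t@spacing, t@origin)
  multiContrastImage(toVol(fa), toVol(md), toVol(ev[, 1]), toVol(ev[, 2]),
                     toVol(ev[, 3]))
}

#' Split peripheral structures into CSF, cortex and peripheral white matter
#'
#' Each voxel of a peripheral structure is reassigned by the standard DTI
#' tissue thresholds: MD >= \code{mdCsfThreshold} (default 0.0015 mm^2/s)
#' marks CSF; otherwise FA > \code{faWmThreshold} (default 0.2) marks
#' peripheral white matter; the remainder is cortex. CSF sublabels are
#' recorded in the \code{excluded} slot, since CSF compartments are
#' excluded from ROI analysis. Threshold boundaries: MD exactly at the
#' threshold goes to CSF, FA exactly at the threshold goes to cortex.
#'
#' Sublabel numbering is deterministic: structure \code{s} maps to
#' \code{1000*s + 1} (CSF), \code{1000*s + 2} (cortex), \code{1000*s + 3}
#' (peripheral WM). Non-peripheral labels are unchanged.
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param img the \linkS4class{MultiContrastImage} on the same grid.
#' @param peripheralIds structure ids to decompose.
#' @param mdCsfThreshold MD threshold separating CSF from tissue (mm^2/s).
#' @param faWmThreshold FA threshold separating white matter from cortex.
#' @return A new \linkS4class{LabelMap}; every peripheral structure is
#'   exactly partitioned into its sublabels. Ids absent from the volume are
#'   skipped with a warning.
#' @export
decomposePeripheral <- function(labels, img, peripheralIds,
                                mdCsfThreshold = 0.0015,
                                faWmThreshold = 0.2) {
  .stopIf(!identical(dim(labels@data), gridDim(img)),
          "labels and image must share one grid")
  out <- labels@data
  excluded <- labels@excluded
  md <- img@channels$md@data
  fa <- img@channels$fa@data
  for (s in as.integer(peripheralIds)) {
    mask <- labels@data == s
    if (!any(mask)) {
      warning(sprintf("peripheral structure %d absent from the label map", s))
      next
    }
    csf <- mask & md >= mdCsfThreshold
    wm <- mask & !csf & fa > faWmThreshold
    ctx <- mask & !csf & !wm
    out[csf] <- 1000L * s + 1L
    out[ctx] <- 1000L * s + 2L
    out[wm] <- 1000L * s + 3L
    if (any(csf)) excluded <- union(excluded, 1000L * s + 1L)
  }
  labelMap(out, labels@spacing, labels@origin, excluded = excluded)
}
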