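# Interpolation primitives shared by registration, label propagation and
# the fusion loop. Points are 1-based voxel-centred coordinates; anything
# outside [1, n] on any axis takes the declared fill value (background
# semantics: label 0 has probability 1 outside the grid, intensities 0).

#' Sample a scalar volume at arbitrary voxel coordinates
#'
#' Trilinear mode returns convex combinations of the eight surrounding
#' voxel values; nearest mode returns an existing voxel value. Queries
#' outside the grid return \code{fill}.
#'
#' @param vol a \linkS4class{ScalarVolume} or a bare 3D array.
#' @param points numeric matrix (n x 3) of 1-based voxel coordinates.
#' @param mode "trilinear" or "nearest".
#' @param fill value returned outside the grid (default 0).
#' @return numeric vector of length \code{nrow(points)}.
#' @export
interpolateScalar <- function(vol, points, mode = c("trilinear", "nearest"),
                              fill = 0) {
  mode <- match.arg(mode)
  a <- if (is(vol, "ScalarVolume")) vol@data else vol
  points <- .asPoints(points)
  if (nrow(points) == 0L) return(numeric(0))
  .cpp_interp3(as.double(a), dim(a), points,
               if (mode == "trilinear") 0L else 1L, as.double(fill))
}

#' Trilinear probability of a label at arbitrary voxel coordinates
#'
#' The indicator volume of \code{label} is interpolated trilinearly, giving
#' a value in [0, 1]. Summed over all labels (including background 0) the
#' probabilities form a partition of unity at every point. Outside the
#' grid, background has probability 1 and every structure 0. A label absent
#' from the map yields a zero field.
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param points numeric matrix (n x 3) of 1-based voxel coordinates.
#' @param label a single label id (background 0 allowed).
#' @return numeric vector of probabilities in [0, 1].
#' @export
interpolateLabelProbability <- function(labels, points, label) {
  points <- .asPoints(points)
  if (nrow(points) == 0L) return(numeric(0))
  ind <- labels@data == label
  storage.mode(ind) <- "double"
  fill <- if (label == 0L) 1 else 0
  p <- .cpp_interp3(as.double(ind), dim(labels@data), points, 0L, fill)
  pmin(pmax(p, 0), 1)
}

.asPoints <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  .stopIf(ncol(points) != 3L, "points must be an n x 3 matrix")
  storage.mode(points) <- "double"
  points
}

# Sample a 3-channel displacement array at arbitrary coordinates
# (fill 0: no deformation outside the grid).
.interpDisp <- function(disp, points) {
  d <- dim(disp)[1:3]
  cbind(.cpp_interp3(as.double(disp[, , , 1]), d, points, 0L, 0),
        .cpp_interp3(as.double(disp[, , , 2]), d, points, 0L, 0),
        .cpp_interp3(as.double(disp[, , , 3]), d, points, 0L, 0))
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels).
.smooth3 <- function(a, sigma) {
  out <- .cpp_smooth3(as.double(a), dim(a), as.double(sigma))
  array(out, dim(a))
}
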