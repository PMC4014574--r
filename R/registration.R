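# Global two-channel diffeomorphic registration (greedy multi-resolution
# scheme with Gaussian-smoothed velocity updates, composed so that
# invertibility is preserved) and the per-structure local 12-parameter
# affine refinement under a diagonal Gaussian prior.

#' An identity deformation field
#'
#' @param dim grid shape (3 integers).
#' @return A \linkS4class{DeformationField} with zero displacement and
#'   geodesic proxy 0.
#' @export
identityField <- function(dim)
  new("DeformationField", disp = array(0, c(dim, 3)), geodesic = 0)

#' Register an atlas to a subject on two channels (FA + MD)
#'
#' Greedy multi-resolution diffeomorphic scheme: at each resolution level a
#' demons-type update is computed from the weighted two-channel residuals
#' and intensity gradients, smoothed by a Gaussian kernel (the fluid
#' regularizer standing in for an elliptic-operator norm), capped in step
#' size, and composed with the current field. Updates whose composed field
#' loses Jacobian positivity are rejected and the smoothing increased, so
#' the diffeomorphism contract (positive Jacobian determinant at all
#' interior voxels) holds throughout. The smoothing cascade runs coarse to
#' fine. The accumulated norm of the smoothed updates is recorded as a
#' geodesic-length proxy for \code{\link{diffeoPrior}}.
#'
#' If the final two-channel sum-of-squares energy exceeds the identity
#' energy the identity field is returned instead, so the returned field is
#' never worse than no registration.
#'
#' @param atlasImg,subjectImg \linkS4class{MultiContrastImage}s, or named
#'   lists with \code{fa} and \code{md} \linkS4class{ScalarVolume}s, on
#'   commensurate grids.
#' @param weights per-channel weights of the matching term (default equal).
#' @param levels number of resolution levels (coarsest factor 2^(levels-1)).
#' @param iterations per-level iteration counts (recycled).
#' @param sigmaFluid Gaussian smoothing sigma of the update, in voxels at
#'   each level.
#' @param maxStep maximum per-update displacement in voxels.
#' @return A \linkS4class{DeformationField} mapping subject to atlas voxel
#'   coordinates, with attributes \code{energy} (initial/final) and
#'   \code{schedule}.
#' @export
registerTwoChannel <- function(atlasImg, subjectImg, weights = c(1, 1),
                               levels = 3L, iterations = c(40L, 30L, 20L),
                               sigmaFluid = 2.0, maxStep = 0.4) {
  getCh <- function(x, nm)
    if (is(x, "MultiContrastImage")) x@channels[[nm]]@data else
      if (is(x[[nm]], "ScalarVolume")) x[[nm]]@data else x[[nm]]
  aF <- getCh(atlasImg, "fa"); aM <- getCh(atlasImg, "md")
  sF <- getCh(subjectImg, "fa"); sM <- getCh(subjectImg, "md")
  .stopIf(!identical(dim(aF), dim(sF)), "atlas and subject grids differ")
  d <- dim(sF)
  # normalize channel scales so MD (~1e-3) and FA (~1) contribute comparably
  sc <- vapply(list(sF, sM), function(x) max(stats::sd(x), 1e-12), numeric(1))
  aF <- aF / sc[1]; sF <- sF / sc[1]; aM <- aM / sc[2]; sM <- sM / sc[2]
  w <- weights / sum(weights)
  iterations <- rep_len(as.integer(iterations), levels)

  energy <- function(wF, wM, tF, tM)
    w[1] * sum((wF - tF)^2) + w[2] * sum((wM - tM)^2)

  disp <- NULL       # coarse-grid displacement, units of coarse voxels
  geodesic <- 0
  for (lev in seq_len(levels)) {
    f <- 2^(levels - lev)
    dc <- pmax(3L, as.integer(floor((d - 1) / f) + 1L))
    idx <- lapply(1:3, function(ax) seq(1, by = f, length.out = dc[ax]))
    down <- function(x) {
      if (f > 1) x <- .smooth3(x, rep(f / 2, 3))
      x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    }
    aFc <- down(aF); aMc <- down(aM); sFc <- down(sF); sMc <- down(sM)
    pts <- .voxelGrid(dc)
    if (is.null(disp)) {
      disp <- array(0, c(dc, 3))
    } else {
      # upsample previous level (factor 2f) onto this grid (factor f):
      # shared fine coordinate 1 + (i-1)*f, so halve coords, double values
      cpts <- (pts - 1) / 2 + 1
      disp <- array(2 * .interpDisp(disp, cpts), c(dc, 3))
    }
    sig <- sigmaFluid
    for (it in seq_len(iterations[lev])) {
      tgt <- pts + matrix(disp, ncol = 3)
      wF <- array(.cpp_interp3(as.double(aFc), dc, tgt, 0L, 0), dc)
      wM <- array(.cpp_interp3(as.double(aMc), dc, tgt, 0L, 0), dc)
      rF <- sFc - wF; rM <- sMc - wM
      gF <- .cpp_gradient3(as.double(wF), dc)
      gM <- .cpp_gradient3(as.double(wM), dc)
      num <- w[1] * as.vector(rF) * gF + w[2] * as.vector(rM) * gM
      den <- w[1] * (rowSums(gF^2) + as.vector(rF)^2 / maxStep^2) +
             w[2] * (rowSums(gM^2) + as.vector(rM)^2 / maxStep^2)
      # first-order: grad(warped) . u = residual
      u <- num / pmax(den, 1e-12)
      u[!is.finite(u)] <- 0
      uarr <- array(u, c(dc, 3))
      for (c3 in 1:3) uarr[, , , c3] <- .smooth3(uarr[, , , c3], rep(sig, 3))
      umax <- sqrt(max(rowSums(matrix(uarr, ncol = 3)^2)))
      if (umax > maxStep) uarr <- uarr * (maxStep / umax)
      if (umax < 1e-9) break
      # compose: new(x) = u(x) + disp(x + u(x))
      upts <- pts + matrix(uarr, ncol = 3)
      cand <- array(matrix(uarr, ncol = 3) + .interpDisp(disp, upts), c(dc, 3))
      if (.cpp_jacobian_min(as.double(cand), dc) <= 0) {
        sig <- sig * 1.5
        next
      }
      newE <- energy(array(.cpp_interp3(as.double(aFc), dc,
                                        pts + matrix(cand, ncol = 3), 0L, 0), dc),
                     array(.cpp_interp3(as.double(aMc), dc,
                                        pts + matrix(cand, ncol = 3), 0L, 0), dc),
                     sFc, sMc)
      oldE <- energy(wF, wM, sFc, sMc)
      .stopIf(!is.finite(newE), "non-finite registration energy")
      if (newE >= oldE) { sig <- min(sig * 1.25, 8); next }
      disp <- cand
      geodesic <- geodesic + f * sqrt(mean(rowSums(matrix(uarr, ncol = 3)^2)))
    }
  }
  # field is already on the fine grid at the last level
  pts <- .voxelGrid(d)
  e0 <- energy(aF, aM, sF, sM)
  tgt <- pts + matrix(disp, ncol = 3)
  e1 <- energy(array(.cpp_interp3(as.double(aF), d, tgt, 0L, 0), d),
               array(.cpp_interp3(as.double(aM), d, tgt, 0L, 0), d), sF, sM)
  if (e1 > e0) {
    warning("registration did not improve on identity; returning identity")
    fld <- identityField(d)
  } else {
    fld <- new("DeformationField", disp = disp, geodesic = geodesic)
  }
  attr(fld, "energy") <- c(initial = e0, final = min(e1, e0))
  attr(fld, "schedule") <- list(levels = levels, iterations = iterations,
                                sigmaFluid = sigmaFluid, maxStep = maxStep)
  fld
}

#' Construct a 12-parameter affine transform
#'
#' @param params numeric(12): 9 row-order deviations of the linear part
#'   from identity, then 3 translations in voxels.
#' @param center fixed point of the linear part (voxel coordinates).
#' @return An \linkS4class{AffineTransform12}.
#' @export
affineTransform12 <- function(params = rep(0, 12), center = c(0, 0, 0))
  new("AffineTransform12", params = as.numeric(params),
      center = as.numeric(center))

#' @rdname affineTransform12
#' @param aff an AffineTransform12.
#' @param points n x 3 matrix of voxel coordinates.
#' @export
applyAffine <- function(aff, points) {
  points <- .asPoints(points)
  A <- diag(3) + matrix(aff@params[1:9], 3, 3, byrow = TRUE)
  ctr <- matrix(aff@center, nrow(points), 3, byrow = TRUE)
  (points - ctr) %*% t(A) + ctr +
    matrix(aff@params[10:12], nrow(points), 3, byrow = TRUE)
}

#' Zero-mean diagonal Gaussian prior on the affine parameters
#'
#' Defaults: variance 0.01 for each of the 9 linear parameters (the linear
#' part should stay near identity) and 100 for the 3 translations
#' (loosely constrained, voxel units).
#'
#' @param variances numeric(12) of positive variances.
#' @return An \linkS4class{AffinePrior}.
#' @export
affinePrior <- function(variances = c(rep(0.01, 9), rep(100, 3)))
  new("AffinePrior", variances = as.numeric(variances))

#' @rdname affinePrior
#' @param aff an \linkS4class{AffineTransform12}.
#' @param prior an AffinePrior.
#' @return \code{affineLogPrior}: the unnormalized log prior density
#'   (0 at identity).
#' @export
affineLogPrior <- function(aff, prior = affinePrior())
  -0.5 * sum(aff@params^2 / prior@variances)

# Map subject voxel coordinates through local-affine-then-global-field
# (pull-back): y = affine(x); z = y + disp(y).
.transformPoints <- function(field, aff, points) {
  y <- if (is.null(aff)) .asPoints(points) else applyAffine(aff, points)
  y + .interpDisp(field@disp, y)
}

#' Resample a volume through the composed local affine and global field
#'
#' Applies the pull-back composition affine-then-field: the output value at
#' subject voxel x is the input sampled at \code{affine(x) + disp(affine(x))}.
#' Scalars use trilinear (or nearest) sampling; hard label maps use nearest.
#'
#' @param field a \linkS4class{DeformationField} on the subject grid.
#' @param affine an \linkS4class{AffineTransform12} or NULL for identity.
#' @param vol a \linkS4class{ScalarVolume} or \linkS4class{LabelMap} in
#'   atlas space.
#' @param mode "trilinear" or "nearest"; label maps force nearest.
#' @return The resampled volume of the same class, on the subject grid.
#' @export
composeAndResample <- function(field, affine, vol,
                               mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(field@disp)[1:3]
  pts <- .transformPoints(field, affine, .voxelGrid(d))
  if (is(vol, "LabelMap")) {
    v <- .cpp_interp3(as.double(vol@data), dim(vol@data), pts, 1L, 0)
    return(labelMap(array(as.integer(v), d), vol@spacing, vol@origin))
  }
  a <- if (is(vol, "ScalarVolume")) vol@data else vol
  out <- .cpp_interp3(as.double(a), dim(a), pts,
                      if (mode == "trilinear") 0L else 1L, 0)
  if (is(vol, "ScalarVolume"))
    scalarVolume(array(out, d), vol@spacing, vol@origin)
  else array(out, d)
}

# Deformed trilinear probability of one atlas label on the subject grid.
.resampleLabelProb <- function(field, affine, labels, label, points = NULL) {
  d <- dim(field@disp)[1:3]
  if (is.null(points)) points <- .voxelGrid(d)
  pts <- .transformPoints(field, affine, points)
  interpolateLabelProbability(labels, pts, label)
}

#' Relative prior weight of a deformation across an atlas library
#'
#' The prior on the global diffeomorphism is the exponential of the
#' negative geodesic-length proxy recorded during registration: identity
#' scores 1 before normalization, and larger deformations score strictly
#' less. Given a list of fields the scores are normalized to relative
#' weights across the library.
#'
#' @param field a \linkS4class{DeformationField} or a list of them.
#' @return A single unnormalized score, or normalized weights for a list.
#' @export
diffeoPrior <- function(field) {
  if (is(field, "DeformationField")) return(exp(-field@geodesic))
  g <- vapply(field, function(f) f@geodesic, numeric(1))
  w <- exp(-(g - min(g)))
  w / sum(w)
}

#' Optimize the local affine refinement of one structure
#'
#' Maximizes the sum of the soft Dice overlap between the deformed atlas
#' structure (under global-field-composed-with-affine) and the target
#' structure, and the Gaussian log prior on the affine parameters. The
#' search is derivative-free from identity: greedy unit-step descent on
#' the translation block first, then Nelder-Mead over all 12 parameters.
#' The evaluation is restricted to the structure's bounding box dilated by
#' \code{dilate} voxels. The returned transform never scores worse than
#' identity on the objective; the best-so-far objective trace is attached
#' as attribute \code{"trace"}.
#'
#' @param structure structure id.
#' @param atlasLabels the atlas \linkS4class{LabelMap}.
#' @param globalField the atlas-to-subject \linkS4class{DeformationField}.
#' @param targetParc current target parcellation \linkS4class{LabelMap}.
#' @param prior an \linkS4class{AffinePrior}.
#' @param dilate bounding-box dilation in voxels.
#' @param maxit Nelder-Mead iteration cap.
#' @return An \linkS4class{AffineTransform12} (identity, with a warning,
#'   when the structure is empty in either map).
#' @export
optimizeLocalAffine <- function(structure, atlasLabels, globalField,
                                targetParc, prior = affinePrior(),
                                dilate = 5L, maxit = 60L) {
  d <- dim(targetParc@data)
  tmask <- targetParc@data == structure
  amask <- atlasLabels@data == structure
  if (!any(amask)) {
    warning(sprintf("structure %d empty in atlas; identity returned", structure))
    return(affineTransform12())
  }
  if (!any(tmask)) {
    warning(sprintf("structure %d empty in target; identity returned", structure))
    return(affineTransform12())
  }
  ctr <- colMeans(which(tmask, arr.ind = TRUE))

  # bounding box: target structure plus the identity-deformed atlas structure
  p0 <- .resampleLabelProb(globalField, NULL, atlasLabels, structure)
  roi <- tmask | array(p0 > 0.25, d)
  bb <- apply(which(roi, arr.ind = TRUE), 2, range)
  lo <- pmax(bb[1, ] - dilate, 1L)
  hi <- pmin(bb[2, ] + dilate, d)
  pts <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                               z = lo[3]:hi[3]))
  q <- as.numeric(tmask[pts])

  trace <- numeric(0)
  best <- list(obj = -Inf, par = rep(0, 12))
  objective <- function(par) {
    aff <- tryCatch(affineTransform12(par, ctr), error = function(e) NULL)
    if (is.null(aff)) return(-Inf)
    p <- .resampleLabelProb(globalField, aff, atlasLabels, structure, pts)
    sdice <- 2 * sum(p * q) / max(sum(p) + sum(q), 1e-12)
    obj <- sdice - 0.5 * sum(par^2 / prior@variances)
    if (obj > best$obj) best <<- list(obj = obj, par = par)
    trace <<- c(trace, best$obj)
    obj
  }
  objective(rep(0, 12))
  identityObj <- best$obj

  # greedy unit-step translation search
  par <- rep(0, 12)
  cur <- identityObj
  repeat {
    improved <- FALSE
    for (k in 10:12) for (s in c(1, -1)) {
      cand <- par; cand[k] <- cand[k] + s
      v <- objective(cand)
      if (v > cur + 1e-10) { par <- cand; cur <- v; improved <- TRUE }
    }
    if (!improved || max(abs(par[10:12])) > 20) break
  }
  opt <- stats::optim(best$par, function(p) -objective(p),
                      method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-5))
  out <- if (best$obj >= identityObj) best$par else rep(0, 12)
  aff <- affineTransform12(out, ctr)
  attr(aff, "objective") <- best$obj
  attr(aff, "trace") <- trace
  aff
}
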