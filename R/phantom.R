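# Synthetic multi-atlas DTI phantom: a labeled ground-truth geometry whose
# per-structure channel intensities are drawn from Gaussian mixtures with
# channel-specific discriminability, plus random smooth diffeomorphic
# warps that stand in for the anatomical variability an atlas library
# covers. Every pipeline stage is testable on these phantoms without
# clinical data.

.mix <- function(weights, means, variances) {
  w <- weights / sum(weights)
  list(weights = w, means = means, variances = variances)
}

.evMix <- function(mean3, sd) {
  m <- mean3 / sqrt(sum(mean3^2))
  list(evx = .mix(1, m[1], sd^2), evy = .mix(1, m[2], sd^2),
       evz = .mix(1, m[3], sd^2))
}

.phantomStructure <- function(label, name, geometry, fa, md, ev)
  c(list(label = as.integer(label), name = name, geometry = geometry),
    list(mixtures = c(list(fa = fa, md = md), ev)))

#' Default six-structure phantom recipe
#'
#' A 48^3 grid at 2.5 mm isotropic spacing (the clinical DTI slice scale)
#' with six structures in a background: a CSF-filled ventricle (high MD),
#' two deep gray nuclei separated from each other by FA, two white-matter
#' tracts with distinct fiber orientations (separable only in the EV
#' channels), and a peripheral slab whose FA/MD mixtures straddle the
#' 0.0015 mm^2/s and 0.2 tissue thresholds. MD means (tissue ~0.0007,
#' CSF ~0.0030 mm^2/s) are chosen so the CSF threshold is exercised.
#' Atlas warps default to 2 voxels RMS displacement with 8 mm smoothness.
#'
#' @param seed base random seed of the phantom.
#' @param dim grid side length (isotropic).
#' @param spacing voxel size in mm.
#' @param deformMagnitude RMS warp displacement in voxels.
#' @param deformSmoothness warp smoothing sigma in mm.
#' @return A \linkS4class{PhantomSpec}.
#' @export
defaultPhantomSpec <- function(seed = 1L, dim = 48L, spacing = 2.5,
                               deformMagnitude = 2.0,
                               deformSmoothness = 8.0) {
  d <- rep(as.integer(dim), 3)
  c0 <- (d + 1) / 2
  grayEv <- .evMix(c(1, 1, 1), 0.22)
  structures <- list(
    .phantomStructure(1L, "ventricle",
      list(type = "ellipsoid", center = c(c0[1], c0[2], c0[3] + 2),
           radii = c(5, 8, 6)),
      fa = .mix(1, 0.08, 0.03^2), md = .mix(1, 0.0030, 0.0002^2),
      ev = grayEv),
    .phantomStructure(2L, "caudate",
      list(type = "ellipsoid", center = c(c0[1] - 10, c0[2] - 3, c0[3]),
           radii = c(4.5, 6, 6)),
      fa = .mix(1, 0.18, 0.04^2), md = .mix(1, 0.0007, 0.00008^2),
      ev = grayEv),
    .phantomStructure(3L, "thalamus",
      list(type = "ellipsoid", center = c(c0[1] + 10, c0[2] - 3, c0[3]),
           radii = c(5.5, 6, 6)),
      fa = .mix(1, 0.32, 0.05^2), md = .mix(1, 0.0007, 0.00008^2),
      ev = grayEv),
    .phantomStructure(4L, "tract_x",
      list(type = "tube", axis = 1L, center = c(c0[2] + 11, c0[3] - 9),
           radius = 3.5, extent = c(8, d[1] - 8)),
      fa = .mix(1, 0.55, 0.06^2), md = .mix(1, 0.0007, 0.00008^2),
      ev = .evMix(c(0.91, 0.29, 0.29), 0.08)),
    .phantomStructure(5L, "tract_z",
      list(type = "tube", axis = 3L, center = c(c0[1], c0[2] + 11),
           radius = 3.5, extent = c(8, d[3] - 8)),
      fa = .mix(1, 0.55, 0.06^2), md = .mix(1, 0.0007, 0.00008^2),
      ev = .evMix(c(0.29, 0.29, 0.91), 0.08)),
    .phantomStructure(6L, "peripheral",
      list(type = "box", lo = c(6, 6, 10), hi = c(d[1] - 5, 10, d[3] - 9)),
      fa = .mix(c(0.4, 0.6), c(0.10, 0.45), c(0.04^2, 0.06^2)),
      md = .mix(c(0.25, 0.75), c(0.0030, 0.0007), c(0.0002^2, 0.00008^2)),
      ev = grayEv))
  background <- c(list(fa = .mix(1, 0.05, 0.03^2),
                       md = .mix(1, 0.0004, 0.00015^2)),
                  .evMix(c(1, 1, 1), 0.3))
  new("PhantomSpec", dim = d, spacing = rep(spacing, 3),
      structures = structures, background = background,
      deformMagnitude = deformMagnitude,
      deformSmoothness = deformSmoothness, seed = as.integer(seed))
}

#' Ambiguity phantom: each adjacent pair separable in one channel group
#'
#' Five adjacent slabs where the ventricle and its gray-matter neighbour
#' differ only in MD (>= 5 sigma apart; FA and EV means coincide), the
#' gray slab and the first tract differ only in FA, the two tracts differ
#' only in the EV orientation channels, and the last pair again only in
#' FA. This geometry makes the single-contrast ablations fail in a
#' predictable, structure-specific way while the 5-channel fusion can
#' separate every pair.
#'
#' @param seed base random seed.
#' @param dim grid side length (default 36).
#' @param spacing voxel size in mm.
#' @return A \linkS4class{PhantomSpec}.
#' @export
makeAmbiguityPhantom <- function(seed = 1L, dim = 36L, spacing = 2.5) {
  d <- rep(as.integer(dim), 3)
  yz <- c(7, d[2] - 6)
  slab <- function(x0, x1) list(type = "box", lo = c(x0, yz[1], yz[1]),
                                hi = c(x1, yz[2], yz[2]))
  xs <- round(seq(5, d[1] - 4, length.out = 6))
  evA <- .evMix(c(0.91, 0.29, 0.29), 0.05)
  evB <- .evMix(c(0.29, 0.29, 0.91), 0.05)
  tissueMd <- .mix(1, 0.0007, 0.0001^2)
  structures <- list(
    .phantomStructure(1L, "ventricle", slab(xs[1], xs[2] - 1),
      fa = .mix(1, 0.20, 0.03^2), md = .mix(1, 0.0030, 0.0001^2), ev = evA),
    .phantomStructure(2L, "caudate", slab(xs[2], xs[3] - 1),
      fa = .mix(1, 0.20, 0.03^2), md = tissueMd, ev = evA),
    .phantomStructure(3L, "tract_a", slab(xs[3], xs[4] - 1),
      fa = .mix(1, 0.55, 0.05^2), md = tissueMd, ev = evA),
    .phantomStructure(4L, "tract_b", slab(xs[4], xs[5] - 1),
      fa = .mix(1, 0.55, 0.05^2), md = tissueMd, ev = evB),
    .phantomStructure(5L, "thalamus", slab(xs[5], xs[6]),
      fa = .mix(1, 0.30, 0.05^2), md = tissueMd, ev = evB))
  background <- c(list(fa = .mix(1, 0.05, 0.03^2),
                       md = .mix(1, 0.0004, 0.00015^2)),
                  .evMix(c(1, 1, 1), 0.3))
  new("PhantomSpec", dim = d, spacing = rep(spacing, 3),
      structures = structures, background = background,
      deformMagnitude = 2.0, deformSmoothness = 8.0, seed = as.integer(seed))
}

.rasterize <- function(spec) {
  d <- spec@dim
  g <- .voxelGrid(d)
  lab <- integer(nrow(g))
  for (s in spec@structures) { # later structures win on overlap
    geo <- s$geometry
    inside <- switch(geo$type,
      ellipsoid = rowSums(sweep(sweep(g, 2, geo$center), 2, geo$radii,
                                "/")^2) <= 1,
      box = g[, 1] >= geo$lo[1] & g[, 1] <= geo$hi[1] &
            g[, 2] >= geo$lo[2] & g[, 2] <= geo$hi[2] &
            g[, 3] >= geo$lo[3] & g[, 3] <= geo$hi[3],
      tube = {
        perp <- setdiff(1:3, geo$axis)
        (g[, perp[1]] - geo$center[1])^2 +
          (g[, perp[2]] - geo$center[2])^2 <= geo$radius^2 &
          g[, geo$axis] >= geo$extent[1] & g[, geo$axis] <= geo$extent[2]
      },
      stop(sprintf("unknown geometry type '%s'", geo$type)))
    if (any(lab[inside] != 0L))
      message(sprintf("phantom: structure %d overwrites %d voxels",
                      s$label, sum(lab[inside] != 0L)))
    lab[inside] <- s$label
  }
  array(lab, d)
}

.sampleMixture <- function(mix, n) {
  K <- length(mix$weights)
  comp <- if (K == 1L) rep(1L, n) else
    sample.int(K, n, replace = TRUE, prob = mix$weights)
  rnorm(n, mix$means[comp], sqrt(mix$variances[comp]))
}

#' Draw a ground-truth atlas pair from a phantom recipe
#'
#' Rasterizes the structure geometries into a label map (later structures
#' win on overlap, which is logged) and draws every voxel's 5-vector from
#' its structure's generating mixtures. The EV triple is projected to unit
#' norm and absolute-valued; FA is clamped into [0, 1] and MD to >= 0.
#' Deterministic per the spec seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed optional seed override (default the spec seed).
#' @param id atlas identifier.
#' @return An \linkS4class{AtlasPair}.
#' @export
makeGroundTruth <- function(spec, seed = spec@seed, id = "truth") {
  d <- spec@dim
  lab <- .rasterize(spec)
  chans <- .withSeed(seed, {
    out <- lapply(setNames(.mciChannels, .mciChannels),
                  function(nm) numeric(prod(d)))
    groups <- c(list(list(label = 0L, mixtures = spec@background)),
                lapply(spec@structures, function(s)
                  list(label = s$label, mixtures = s$mixtures)))
    for (gdef in groups) {
      idx <- which(as.integer(lab) == gdef$label)
      if (!length(idx)) next
      for (nm in .mciChannels)
        out[[nm]][idx] <- .sampleMixture(gdef$mixtures[[nm]], length(idx))
    }
    out
  })
  ev <- cbind(abs(chans$evx), abs(chans$evy), abs(chans$evz))
  nrm <- sqrt(rowSums(ev^2))
  nrm[nrm < 1e-9] <- 1
  ev <- ev / nrm
  img <- multiContrastImage(
    array(pmin(pmax(chans$fa, 0), 1), d), array(pmax(chans$md, 0), d),
    array(ev[, 1], d), array(ev[, 2], d), array(ev[, 3], d),
    spacing = spec@spacing)
  atlasPair(id, img, labelMap(lab, spec@spacing))
}

# Exponentiate a stationary velocity field by scaling and squaring.
.expField <- function(v, nSquare = 6L) {
  d <- dim(v)[1:3]
  pts <- .voxelGrid(d)
  u <- v / 2^nSquare
  for (i in seq_len(nSquare)) {
    shifted <- .interpDisp(u, pts + matrix(u, ncol = 3))
    u <- array(matrix(u, ncol = 3) + shifted, dim(v))
  }
  u
}

#' Apply a random smooth invertible warp to an atlas pair
#'
#' A Gaussian-filtered white-noise velocity field, scaled to the requested
#' RMS magnitude and exponentiated by scaling-and-squaring, deforms the
#' labels (nearest-neighbour) and channels (trilinear, EV triples
#' renormalized after interpolation). If the Jacobian of the resulting
#' map is not positive everywhere the magnitude is reduced automatically
#' (with a warning). The true forward and inverse displacement fields are
#' returned alongside for registration oracles.
#'
#' @param truth an \linkS4class{AtlasPair}.
#' @param magnitude RMS displacement in voxels (0 = identical copy).
#' @param smoothness Gaussian sigma of the velocity field in mm.
#' @param seed random seed.
#' @param id identifier of the deformed copy.
#' @return list with \code{atlas} (the deformed \linkS4class{AtlasPair}),
#'   \code{field} (displacement applied: copy(x) = truth(x + disp(x))) and
#'   \code{inverse}.
#' @export
deformCopy <- function(truth, magnitude, smoothness = 8, seed = 1L,
                       id = "copy") {
  d <- gridDim(truth@image)
  spacing <- voxelSpacing(truth@image)
  if (magnitude == 0) {
    return(list(atlas = atlasPair(id, truth@image, truth@labels),
                field = identityField(d), inverse = identityField(d)))
  }
  sigmaVox <- smoothness / spacing
  v <- .withSeed(seed, array(rnorm(prod(d) * 3), c(d, 3)))
  for (c3 in 1:3) v[, , , c3] <- .smooth3(v[, , , c3], sigmaVox)
  rms <- sqrt(mean(rowSums(matrix(v, ncol = 3)^2)))
  v <- v * (magnitude / rms)
  for (try in 1:6) {
    disp <- .expField(v)
    if (.cpp_jacobian_min(as.double(disp), d) > 0) break
    warning("warp magnitude reduced to preserve invertibility")
    v <- v * 0.8
  }
  inv <- .expField(-v)
  fld <- new("DeformationField", disp = disp,
             geodesic = sqrt(mean(rowSums(matrix(v, ncol = 3)^2))))
  pts <- .voxelGrid(d) + matrix(disp, ncol = 3)
  lab <- array(as.integer(.cpp_interp3(as.double(truth@labels@data), d, pts,
                                       1L, 0)), d)
  ch <- lapply(setNames(.mciChannels, .mciChannels), function(nm)
    .cpp_interp3(as.double(truth@image@channels[[nm]]@data), d, pts, 0L, 0))
  ev <- cbind(ch$evx, ch$evy, ch$evz)
  nrm <- sqrt(rowSums(ev^2))
  ok <- nrm > 1e-9
  ev[ok, ] <- ev[ok, ] / nrm[ok]
  img <- multiContrastImage(
    array(pmin(pmax(ch$fa, 0), 1), d), array(pmax(ch$md, 0), d),
    array(ev[, 1], d), array(ev[, 2], d), array(ev[, 3], d),
    spacing = spacing)
  list(atlas = atlasPair(id, img, labelMap(lab, spacing)),
       field = fld,
       inverse = new("DeformationField", disp = inv, geodesic = fld@geodesic))
}

#' Build a deformed multi-atlas library plus a held-out subject
#'
#' Each atlas is a fresh intensity realization of the ground-truth labels
#' (its own seed), deformed by its own random warp; a held-out deformed
#' copy serves as the to-be-parcellated subject, whose label map is the
#' evaluation ground truth. The true warp fields are returned for
#' registration oracles.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param nAtlases number of atlases (>= 1).
#' @param seeds per-atlas seeds (default derived from the spec seed).
#' @return list with \code{atlases}, \code{truth}, \code{subject} (an
#'   \linkS4class{AtlasPair}; its labels are ground truth, not an input),
#'   \code{fields} (true per-atlas warps) and \code{subjectField}.
#' @export
makeLibrary <- function(spec, nAtlases = 4L, seeds = NULL) {
  .stopIf(nAtlases < 1L, "nAtlases must be >= 1")
  if (is.null(seeds)) seeds <- spec@seed + seq_len(nAtlases)
  .stopIf(length(seeds) != nAtlases, "need one seed per atlas")
  truth <- makeGroundTruth(spec)
  atlases <- vector("list", nAtlases)
  fields <- vector("list", nAtlases)
  for (i in seq_len(nAtlases)) {
    real <- makeGroundTruth(spec, seed = spec@seed + 101L * i,
                            id = sprintf("atlas%02d", i))
    dc <- deformCopy(real, spec@deformMagnitude, spec@deformSmoothness,
                     seed = seeds[i], id = sprintf("atlas%02d", i))
    atlases[[i]] <- dc$atlas
    fields[[i]] <- dc$field
  }
  subjReal <- makeGroundTruth(spec, seed = spec@seed + 55555L, id = "subject")
  sc <- deformCopy(subjReal, spec@deformMagnitude, spec@deformSmoothness,
                   seed = spec@seed + 777L, id = "subject")
  list(atlases = atlases, truth = truth, subject = sc$atlas,
       fields = fields, subjectField = sc$field)
}
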