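# Internal helpers shared across modules.

# All 1-based voxel-centre coordinates of a grid, as an nvox x 3 matrix in
# array (column-major) order, matching as.vector() of a 3D array.
.voxelGrid <- function(d) {
  cbind(rep.int(seq_len(d[1]), d[2] * d[3]),
        rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
        rep(seq_len(d[3]), each = d[1] * d[2]))
}

# Row-wise log(sum(exp(m))) with -Inf-safe handling.
.logSumExpRows <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = TRUE)))
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

# Evaluate a deterministic expression under a temporary RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

.stopIf <- function(cond, ...) if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)

# Construct a ScalarVolume, coercing data to a plain 3D double array.
#' Construct a ScalarVolume
#'
#' @param data 3D numeric array.
#' @param spacing voxel size per axis in mm.
#' @param origin world coordinate of the first voxel.
#' @return A \linkS4class{ScalarVolume}.
#' @export
scalarVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("ScalarVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a LabelMap
#'
#' @param data 3D array of non-negative integer labels (0 = background).
#' @param spacing voxel size per axis in mm.
#' @param origin world coordinate of the first voxel.
#' @param excluded label ids excluded from analysis.
#' @return A \linkS4class{LabelMap}.
#' @export
labelMap <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     excluded = integer(0)) {
  storage.mode(data) <- "integer"
  new("LabelMap", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), excluded = as.integer(excluded))
}

#' Construct a MultiContrastImage from five channel volumes
#'
#' @param fa,md,evx,evy,evz the five channels, each a
#'   \linkS4class{ScalarVolume} or a bare 3D array (then \code{spacing}
#'   applies).
#' @param spacing voxel size used when channels are bare arrays.
#' @param clamp if TRUE, clamp FA and EV channels into [0, 1] and MD to
#'   >= 0 instead of rejecting out-of-range voxels.
#' @param naAction "reject" (default) fails on non-finite voxels; "mask"
#'   replaces them with 0.
#' @return A validated \linkS4class{MultiContrastImage}.
#' @export
multiContrastImage <- function(fa, md, evx, evy, evz, spacing = c(1, 1, 1),
                               clamp = FALSE,
                               naAction = c("reject", "mask")) {
  naAction <- match.arg(naAction)
  asVol <- function(x) if (is(x, "ScalarVolume")) x else scalarVolume(x, spacing)
  ch <- list(fa = asVol(fa), md = asVol(md), evx = asVol(evx),
             evy = asVol(evy), evz = asVol(evz))
  for (nm in names(ch)) {
    v <- ch[[nm]]@data
    if (any(!is.finite(v))) {
      if (naAction == "reject")
        stop(sprintf("channel '%s' contains %d non-finite voxels", nm,
                     sum(!is.finite(v))), call. = FALSE)
      v[!is.finite(v)] <- 0
    }
    if (clamp) {
      if (nm == "md") v <- pmax(v, 0) else v <- pmin(pmax(v, 0), 1)
    }
    ch[[nm]]@data <- v
  }
  new("MultiContrastImage", channels = ch)
}

#' Construct a TensorVolume
#'
#' @param data 4D array (nx, ny, nz, 6); component order Dxx, Dxy, Dxz,
#'   Dyy, Dyz, Dzz (upper triangle, row order), mm^2/s.
#' @param spacing voxel size per axis in mm.
#' @param origin world coordinate of the first voxel.
#' @return A \linkS4class{TensorVolume}.
#' @export
tensorVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("TensorVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct an AtlasPair
#'
#' @param id atlas identifier.
#' @param image a \linkS4class{MultiContrastImage}.
#' @param labels a \linkS4class{LabelMap} on the same grid.
#' @return An \linkS4class{AtlasPair}.
#' @export
atlasPair <- function(id, image, labels)
  new("AtlasPair", id = as.character(id), image = image, labels = labels)
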