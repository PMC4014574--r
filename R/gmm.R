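# Per-structure, per-channel Gaussian-mixture intensity signatures and the
# multi-contrast voxel likelihood. The mixture fit is a plain
# maximum-likelihood EM with k-means++ style seeding; this is the
# estimation step behind every structure signature, so it is implemented
# here rather than delegated (reference EM implementations serve as
# independent oracles in the test suite only).

.GMM_VAR_FLOOR <- 1e-6
.GMM_PRUNE_WEIGHT <- 1e-4
.DENSITY_FLOOR <- 1e-300

#' Component count as a function of structure size
#'
#' Small structures get fewer mixture components than large ones; the size
#' cutoff is 1000 mm^3. The per-class counts are configurable (defaults
#' kSmall = 2, kLarge = 3).
#'
#' @param volumeMm3 structure volume in mm^3.
#' @param kSmall components for structures below the cutoff.
#' @param kLarge components for structures at or above the cutoff.
#' @param cutoffMm3 size cutoff in mm^3 (default 1000).
#' @return integer component count.
#' @export
componentCountRule <- function(volumeMm3, kSmall = 2L, kLarge = 3L,
                               cutoffMm3 = 1000) {
  .stopIf(any(volumeMm3 < 0), "volume must be non-negative")
  .stopIf(kSmall < 1L || kLarge < 1L, "component counts must be >= 1")
  ifelse(volumeMm3 < cutoffMm3, as.integer(kSmall), as.integer(kLarge))
}

#' Fit a 1D Gaussian mixture by maximum-likelihood EM
#'
#' Initialization is k-means++ style seeding followed by a single nearest-
#' centre assignment; EM then iterates until the log-likelihood gain drops
#' below \code{tol} (default 1e-7) or 500 iterations. The log-likelihood is
#' non-decreasing across iterations. Variances are floored at 1e-6 to
#' guard against the usual ML-EM singularity; components whose weight
#' falls below 1e-4 are pruned and the weights renormalized, so that
#' homogeneous data collapse to a single effective component with weight 1.
#' The fit is deterministic given \code{seed}.
#'
#' @param samples numeric vector of channel intensities.
#' @param K requested component count; reduced (with a warning) when there
#'   are fewer samples than components.
#' @param seed integer seed for the initialization.
#' @param maxIter EM iteration cap.
#' @param tol log-likelihood convergence tolerance.
#' @return A \linkS4class{StructureIntensityModel} with the final
#'   log-likelihood in its \code{logLik} slot and the per-iteration
#'   log-likelihood trace in attribute \code{"trace"}.
#' @export
fitGmm <- function(samples, K, seed = 1L, maxIter = 500L, tol = 1e-7) {
  samples <- as.numeric(samples)
  .stopIf(any(!is.finite(samples)), "samples must be finite")
  n <- length(samples)
  .stopIf(n < 1L, "at least one sample required")
  K <- as.integer(K)
  .stopIf(K < 1L, "K must be >= 1")
  if (n < K) {
    warning(sprintf("only %d samples for K = %d; reducing K", n, K))
    K <- n
  }
  if (stats::var(samples) == 0 || K == 1L) {
    v <- max(if (n > 1) stats::var(samples) else 0, .GMM_VAR_FLOOR)
    m <- new("StructureIntensityModel", weights = 1, means = mean(samples),
             variances = v,
             logLik = sum(dnorm(samples, mean(samples), sqrt(v), log = TRUE)))
    attr(m, "trace") <- m@logLik
    return(m)
  }

  init <- .withSeed(seed, .kmeansppInit(samples, K))
  w <- init$weights; mu <- init$means; va <- pmax(init$variances, .GMM_VAR_FLOOR)

  ll <- -Inf
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    logcomp <- vapply(seq_len(K), function(k)
      log(w[k]) + dnorm(samples, mu[k], sqrt(va[k]), log = TRUE),
      numeric(n))
    lse <- .logSumExpRows(logcomp)
    newll <- sum(lse)
    r <- exp(logcomp - lse)
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * samples) / pmax(nk, 1e-12)
    dev2 <- (matrix(samples, n, K) - matrix(mu, n, K, byrow = TRUE))^2
    va <- pmax(colSums(r * dev2) / pmax(nk, 1e-12), .GMM_VAR_FLOOR)
    stopifnot(newll >= ll - 1e-8 * max(1, abs(ll))) # EM monotonicity
    trace <- c(trace, newll)
    if (is.finite(ll) && newll - ll < tol) { ll <- newll; break }
    ll <- newll
  }

  keep <- w >= .GMM_PRUNE_WEIGHT
  if (!all(keep)) {
    w <- w[keep] / sum(w[keep]); mu <- mu[keep]; va <- va[keep]
    ll <- sum(.logSumExpRows(vapply(seq_along(w), function(k)
      log(w[k]) + dnorm(samples, mu[k], sqrt(va[k]), log = TRUE), numeric(n))))
  }
  ord <- order(mu)
  w <- w / sum(w)
  m <- new("StructureIntensityModel", weights = w[ord], means = mu[ord],
           variances = va[ord], logLik = ll)
  attr(m, "trace") <- trace
  m
}

# k-means++ seeding + one hard assignment for initial mixture parameters.
.kmeansppInit <- function(x, K) {
  n <- length(x)
  centers <- x[sample.int(n, 1)]
  while (length(centers) < K) {
    d2 <- vapply(x, function(xi) min((xi - centers)^2), numeric(1))
    if (sum(d2) == 0) {
      centers <- c(centers, x[sample.int(n, 1)])
    } else {
      centers <- c(centers, x[sample.int(n, 1, prob = d2)])
    }
  }
  assign <- apply(outer(x, centers, function(a, b) (a - b)^2), 1, which.min)
  w <- tabulate(assign, K) / n
  mu <- vapply(seq_len(K), function(k)
    if (any(assign == k)) mean(x[assign == k]) else centers[k], numeric(1))
  va <- vapply(seq_len(K), function(k)
    if (sum(assign == k) > 1) stats::var(x[assign == k]) else .GMM_VAR_FLOOR,
    numeric(1))
  w <- pmax(w, 1e-6); w <- w / sum(w)
  list(weights = w, means = mu, variances = va)
}

#' Gaussian mixture density
#'
#' @param model a \linkS4class{StructureIntensityModel}.
#' @param value numeric vector of evaluation points.
#' @return the mixture density, strictly positive.
#' @export
gmmDensity <- function(model, value)
  exp(gmmLogDensity(model, value))

#' @rdname gmmDensity
#' @export
gmmLogDensity <- function(model, value) {
  K <- length(model@weights)
  lc <- vapply(seq_len(K), function(k)
    log(model@weights[k]) +
      dnorm(value, model@means[k], sqrt(model@variances[k]), log = TRUE),
    numeric(length(value)))
  if (length(value) == 1L) lc <- matrix(lc, nrow = 1)
  .logSumExpRows(lc)
}

#' Multi-contrast voxel likelihood under one structure's signature
#'
#' The per-channel mixture densities are conditionally independent given
#' the structure, so the voxel likelihood is the product of the channel
#' densities over the channels selected by \code{channelMask}. Restricting
#' the mask to a subset (FA-only, MD-only, EV-only) reproduces the
#' single-contrast ablations.
#'
#' @param intensity numeric(5) voxel vector (fa, md, evx, evy, evz) or an
#'   n x 5 matrix of voxels.
#' @param structure structure id.
#' @param signature an \linkS4class{AtlasSignature}.
#' @param channelMask logical(5) selecting channels; must select at least
#'   one.
#' @return likelihood value(s); 0 with a warning when the structure is
#'   missing from the signature.
#' @export
voxelLikelihood <- function(intensity, structure, signature,
                            channelMask = rep(TRUE, 5)) {
  .stopIf(!any(channelMask), "channelMask must select at least one channel")
  if (is.null(dim(intensity))) intensity <- matrix(intensity, ncol = 5)
  key <- as.character(structure)
  if (is.null(signature@models[[key]])) {
    warning(sprintf("structure %s missing from signature '%s'", key,
                    signature@atlasId))
    return(rep(0, nrow(intensity)))
  }
  exp(.structureLogLik(intensity, signature@models[[key]], channelMask))
}

# Log product of per-channel densities, each floored at .DENSITY_FLOOR.
.structureLogLik <- function(intensity, models, channelMask) {
  out <- 0
  for (ci in which(channelMask)) {
    ld <- gmmLogDensity(models[[.mciChannels[ci]]], intensity[, ci])
    out <- out + pmax(ld, log(.DENSITY_FLOOR))
  }
  out
}

#' Fit the full intensity signature of an atlas
#'
#' Fits one Gaussian mixture per (structure, channel), including the
#' background (label 0), with the component count determined by
#' \code{\link{componentCountRule}} on the structure volume. Structures
#' with many voxels are subsampled (deterministically per seed) to
#' \code{maxSamples} before fitting.
#'
#' @param atlas an \linkS4class{AtlasPair}.
#' @param kSmall,kLarge,cutoffMm3 passed to \code{componentCountRule}.
#' @param seed base seed; each (structure, channel) fit gets a distinct
#'   deterministic seed derived from it.
#' @param maxSamples subsampling cap per fit.
#' @return An \linkS4class{AtlasSignature}.
#' @export
fitAtlasSignature <- function(atlas, kSmall = 2L, kLarge = 3L,
                              cutoffMm3 = 1000, seed = 1L,
                              maxSamples = 5000L) {
  lab <- atlas@labels@data
  voxVol <- prod(atlas@labels@spacing)
  labs <- sort(unique(as.integer(lab)))
  chans <- lapply(.mciChannels, function(nm)
    as.numeric(atlas@image@channels[[nm]]@data))
  names(chans) <- .mciChannels
  models <- list()
  volumes <- numeric(0)
  for (li in seq_along(labs)) {
    l <- labs[li]
    idx <- which(lab == l)
    vol <- length(idx) * voxVol
    K <- componentCountRule(vol, kSmall, kLarge, cutoffMm3)
    if (length(idx) > maxSamples)
      idx <- .withSeed(seed + 7L * li,
                       idx[sample.int(length(idx), maxSamples)])
    m <- list()
    for (ci in seq_along(.mciChannels))
      m[[.mciChannels[ci]]] <- fitGmm(chans[[ci]][idx], K,
                                      seed = seed + 31L * li + ci)
    models[[as.character(l)]] <- m
    volumes[as.character(l)] <- vol
  }
  new("AtlasSignature", atlasId = atlas@id, models = models,
      volumes = volumes)
}

#' Serialize / deserialize atlas signatures as JSON
#'
#' The schema is \code{atlas id -> structure id -> channel -> \{K, weights,
#' means, variances\}} plus per-structure volumes.
#'
#' @param signatures a list of \linkS4class{AtlasSignature} objects.
#' @param path output / input JSON path.
#' @return \code{readSignatures} returns the list of signatures.
#' @rdname signatureIO
#' @export
writeSignatures <- function(signatures, path) {
  if (is(signatures, "AtlasSignature")) signatures <- list(signatures)
  out <- lapply(signatures, function(sig) {
    list(volumes = as.list(sig@volumes),
         structures = lapply(sig@models, function(m)
           lapply(m, function(g)
             list(K = length(g@weights), weights = g@weights,
                  means = g@means, variances = g@variances))))
  })
  names(out) <- vapply(signatures, function(s) s@atlasId, character(1))
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname signatureIO
#' @export
readSignatures <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(names(raw), function(id) {
    entry <- raw[[id]]
    models <- lapply(entry$structures, function(m)
      lapply(m, function(g)
        new("StructureIntensityModel", weights = as.numeric(g$weights),
            means = as.numeric(g$means),
            variances = as.numeric(g$variances))))
    new("AtlasSignature", atlasId = id, models = models,
        volumes = unlist(entry$volumes))
  })
}
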