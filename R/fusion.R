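# The EM/MAP likelihood-fusion loop. Latent variables are the atlas-label
# selector (which atlas interprets which voxel) and the per-structure
# local diffeomorphisms (global field composed with a local affine,
# handled by mode approximation). The loop alternates:
#   selector update  ->  parcellation argmax  ->  local transform update
# until the changed-voxel fraction falls below tolerance or 30 iterations.

#' Fusion loop configuration
#'
#' @param maxIterations EM iteration cap (default 30).
#' @param stopTolerance changed-voxel-fraction stopping threshold
#'   (default 1e-4).
#' @param channelMask logical(5): which contrasts (fa, md, evx, evy, evz)
#'   enter the intensity likelihood.
#' @param initAtlas "vote" (default) initializes the parcellation by
#'   majority vote over all propagated atlases; an integer selects a
#'   single designated atlas instead.
#' @param verbose print per-iteration progress.
#' @return A \linkS4class{FusionConfig}.
#' @export
fusionConfig <- function(maxIterations = 30, stopTolerance = 1e-4,
                         channelMask = rep(TRUE, 5), initAtlas = "vote",
                         verbose = FALSE) {
  new("FusionConfig", maxIterations = maxIterations,
      stopTolerance = stopTolerance, channelMask = channelMask,
      initAtlas = initAtlas, verbose = verbose)
}

#' Per-atlas intensity log-likelihoods of every candidate label
#'
#' Precomputes, for each atlas and each label (background included), the
#' log product of per-channel mixture densities at every subject voxel.
#' The subject intensities are fixed, so this is computed once per run.
#'
#' @param subject the subject \linkS4class{MultiContrastImage}.
#' @param signatures list of \linkS4class{AtlasSignature}, one per atlas.
#' @param labels integer vector of candidate labels.
#' @param channelMask logical(5) contrast selection.
#' @return list per atlas of (voxels x labels) matrices of log-likelihoods,
#'   with label ids as column names.
#' @export
intensityLogLik <- function(subject, signatures, labels,
                            channelMask = rep(TRUE, 5)) {
  inten <- vapply(.mciChannels, function(nm)
    as.numeric(subject@channels[[nm]]@data), numeric(prod(gridDim(subject))))
  lapply(signatures, function(sig) {
    m <- vapply(labels, function(l) {
      key <- as.character(l)
      if (is.null(sig@models[[key]]))
        rep(log(.DENSITY_FLOOR), nrow(inten))
      else .structureLogLik(inten, sig@models[[key]], channelMask)
    }, numeric(nrow(inten)))
    colnames(m) <- as.character(labels)
    m
  })
}

# Deformed trilinear label probabilities for one atlas: voxels x labels.
# Background (label 0) uses the identity local affine.
.atlasLabelProbs <- function(field, transforms, atlasLabels, labels) {
  d <- dim(field@disp)[1:3]
  pts <- .voxelGrid(d)
  m <- vapply(labels, function(l) {
    aff <- if (l == 0L) NULL else transforms[[as.character(l)]]
    .resampleLabelProb(field, aff, atlasLabels, l, pts)
  }, numeric(nrow(pts)))
  colnames(m) <- as.character(labels)
  m
}

# Refresh the cached probability columns of a label subset only.
.refreshLabelProbCols <- function(P, field, transforms, atlasLabels, which) {
  pts <- .voxelGrid(dim(field@disp)[1:3])
  for (l in which)
    P[, as.character(l)] <- .resampleLabelProb(field,
      transforms[[as.character(l)]], atlasLabels, l, pts)
  P
}

# Structure-level Dice between the current parcellation and each atlas's
# deformed structures (hard-thresholded at probability 0.5).
.diceFactors <- function(parc, labelProbs, labels) {
  t(vapply(labelProbs, function(P) {
    vapply(seq_along(labels), function(li) {
      a <- as.numeric(parc) == labels[li]
      b <- P[, li] >= 0.5
      s <- sum(a) + sum(b)
      if (s == 0) 1 else 2 * sum(a & b) / s
    }, numeric(1))
  }, numeric(length(labels))))
}

#' Initialize the fusion state
#'
#' Sets every per-structure local affine to identity and initializes the
#' parcellation from the atlases propagated through their global fields
#' (nearest-neighbour): either a majority vote across atlases (default;
#' ties to the smallest label) or the labels of one designated atlas.
#'
#' @param atlases list of \linkS4class{AtlasPair}.
#' @param subject the subject \linkS4class{MultiContrastImage}.
#' @param fields list of per-atlas \linkS4class{DeformationField}s on the
#'   subject grid.
#' @param cfg a \linkS4class{FusionConfig}.
#' @return A \linkS4class{FusionState}.
#' @export
initializeFusion <- function(atlases, subject, fields,
                             cfg = fusionConfig()) {
  .stopIf(length(atlases) == 0L, "empty atlas list")
  .stopIf(length(fields) != length(atlases),
          "need one deformation field per atlas")
  validObject(cfg)
  d <- gridDim(subject)
  labels <- sort(unique(unlist(lapply(atlases, function(a) labelSet(a@labels)))))
  labels <- c(0L, as.integer(labels))

  propagated <- lapply(seq_along(atlases), function(i)
    composeAndResample(fields[[i]], NULL, atlases[[i]]@labels))
  if (identical(cfg@initAtlas, "vote")) {
    counts <- array(0L, c(prod(d), length(labels)))
    for (p in propagated)
      for (li in seq_along(labels))
        counts[, li] <- counts[, li] + (as.integer(p@data) == labels[li])
    init <- labels[max.col(counts, ties.method = "first")]
  } else {
    idx <- as.integer(cfg@initAtlas)
    .stopIf(idx < 1L || idx > length(atlases),
            "initAtlas must be 'vote' or an atlas index")
    init <- as.integer(propagated[[idx]]@data)
  }
  parc <- labelMap(array(init, d), voxelSpacing(subject))

  transforms <- lapply(atlases, function(a) {
    tr <- lapply(labels[labels != 0L], function(l) affineTransform12())
    names(tr) <- as.character(labels[labels != 0L])
    tr
  })
  labelProbs <- lapply(seq_along(atlases), function(i)
    .atlasLabelProbs(fields[[i]], transforms[[i]], atlases[[i]]@labels,
                     labels))
  state <- new("FusionState", parcellation = parc, labels = labels,
               transforms = transforms, fields = fields,
               labelProbs = labelProbs,
               selector = matrix(1 / length(atlases), prod(d),
                                 length(atlases)),
               diceFactor = .diceFactors(parc@data, labelProbs, labels),
               geodesic = vapply(fields, function(f) f@geodesic, numeric(1)),
               iteration = 0L,
               history = data.frame(iteration = integer(0),
                                    changedFraction = numeric(0),
                                    objective = numeric(0),
                                    selectorFallback = integer(0)))
  state
}

#' Update the atlas-label selector (E-step)
#'
#' For each atlas a and voxel x currently labeled l = W(x), the selector
#' weight is proportional to the product of: the intensity likelihood of
#' the subject voxel under atlas a's structure-l signature; the Dice
#' overlap between the current structure l and atlas a's deformed
#' structure l; the deformation-magnitude prior of atlas a's global field;
#' and the Gaussian prior density of atlas a's structure-l local affine.
#' The geometric factors are constant within a structure; the weights are
#' normalized over atlases at each voxel. Voxels where every atlas scores
#' zero fall back to uniform weights (counted in attribute
#' \code{"fallback"}).
#'
#' @param state a \linkS4class{FusionState}.
#' @param logLik precomputed \code{\link{intensityLogLik}} list.
#' @param prior the \linkS4class{AffinePrior} for the local affines.
#' @return voxels x atlases selector matrix with rows summing to 1.
#' @export
computeSelector <- function(state, logLik, prior = affinePrior()) {
  nA <- length(state@fields)
  labels <- state@labels
  w <- as.integer(state@parcellation@data)
  labIdx <- match(w, labels)
  nvox <- length(w)
  logGeo <- -(state@geodesic - min(state@geodesic))
  logw <- matrix(0, nvox, nA)
  for (a in seq_len(nA)) {
    logAff <- vapply(seq_along(labels), function(li) {
      l <- labels[li]
      if (l == 0L) 0
      else affineLogPrior(state@transforms[[a]][[as.character(l)]], prior)
    }, numeric(1))
    logw[, a] <- logLik[[a]][cbind(seq_len(nvox), labIdx)] +
      log(pmax(state@diceFactor[a, labIdx], 1e-12)) +
      logGeo[a] + logAff[labIdx]
  }
  norm <- .logSumExpRows(logw)
  sel <- exp(logw - norm)
  bad <- !is.finite(norm)
  if (any(bad)) sel[bad, ] <- 1 / nA
  sel <- sel / rowSums(sel)
  attr(sel, "fallback") <- sum(bad)
  sel
}

#' Fused parcellation update (M-step over labels)
#'
#' Per voxel the new label maximizes, over the candidate labels, the sum
#' over atlases of selector weight times intensity likelihood times the
#' deformed trilinear label probability. Candidates are the labels with
#' nonzero deformed probability at the voxel under at least one atlas
#' (labels with zero probability everywhere score zero); ties break to the
#' smallest label id. Likelihood products are rescaled per voxel before
#' exponentiation so that 5-channel products cannot underflow.
#'
#' @param state a \linkS4class{FusionState} with a current selector.
#' @param logLik precomputed \code{\link{intensityLogLik}} list.
#' @return A \linkS4class{LabelMap}; the summed fused score of the chosen
#'   labels (the surrogate objective, in log form) is attached as
#'   attribute \code{"objective"}.
#' @export
updateParcellation <- function(state, logLik) {
  labels <- state@labels
  nvox <- nrow(state@selector)
  nA <- length(logLik)
  m <- logLik[[1]]
  for (a in seq_len(nA)[-1]) m <- pmax(m, logLik[[a]])
  mx <- do.call(pmax, as.data.frame(m)) # per-voxel rescaling constant
  score <- matrix(0, nvox, length(labels))
  for (a in seq_len(nA))
    score <- score + state@selector[, a] *
      exp(logLik[[a]] - mx) * state@labelProbs[[a]]
  pick <- max.col(score, ties.method = "first") # first = smallest label id
  newW <- labels[pick]
  chosen <- score[cbind(seq_len(nvox), pick)]
  objective <- sum(log(pmax(chosen, .DENSITY_FLOOR)) + mx)
  out <- labelMap(array(as.integer(newW), dim(state@parcellation@data)),
                  state@parcellation@spacing, state@parcellation@origin)
  attr(out, "objective") <- objective
  out
}

#' Re-optimize the per-structure local affines (mode approximation)
#'
#' Re-runs \code{\link{optimizeLocalAffine}} for every (atlas, structure)
#' against the current parcellation, then refreshes the cached deformed
#' label probabilities and the structure-level Dice factors.
#'
#' @param state a \linkS4class{FusionState}.
#' @param atlases the atlas list used to build the state.
#' @param prior the \linkS4class{AffinePrior}.
#' @param changedLabels optional subset of structure ids to re-optimize.
#'   Structures whose target voxel set is unchanged since the last update
#'   are already at their optimum, so restricting the refresh to the
#'   changed structures is exact and saves most of the work late in the
#'   EM loop. Default: all structures.
#' @return The updated \linkS4class{FusionState}.
#' @export
updateTransforms <- function(state, atlases, prior = affinePrior(),
                             changedLabels = NULL) {
  labels <- state@labels
  todo <- labels[labels != 0L]
  if (!is.null(changedLabels)) todo <- intersect(todo, changedLabels)
  memo <- attr(state, "transformMemo")
  if (is.null(memo)) {
    memo <- new.env(parent = emptyenv())
    attr(state, "transformMemo") <- memo
  }
  parcVec <- as.integer(state@parcellation@data)
  for (a in seq_along(atlases)) {
    for (l in todo) {
      key <- as.character(l)
      # the optimum depends only on the target voxel set of the structure,
      # so an unchanged (or previously seen) mask reuses the cached result
      idx <- which(parcVec == l)
      mkey <- sprintf("a%d_l%d", a, l)
      hits <- get0(mkey, envir = memo, ifnotfound = list())
      cachedAff <- NULL
      for (h in hits) if (identical(h$idx, idx)) { cachedAff <- h$aff; break }
      if (!is.null(cachedAff)) {
        state@transforms[[a]][[key]] <- cachedAff
        next
      }
      aff <- withCallingHandlers(
        optimizeLocalAffine(l, atlases[[a]]@labels, state@fields[[a]],
                            state@parcellation, prior),
        warning = function(w) invokeRestart("muffleWarning"))
      state@transforms[[a]][[key]] <- aff
      assign(mkey, c(utils::head(hits, 4), list(list(idx = idx, aff = aff))),
             envir = memo)
    }
    if (length(todo))
      state@labelProbs[[a]] <- .refreshLabelProbCols(state@labelProbs[[a]],
        state@fields[[a]], state@transforms[[a]], atlases[[a]]@labels, todo)
  }
  state@diceFactor <- .diceFactors(state@parcellation@data, state@labelProbs,
                                   labels)
  state
}

#' Run the full EM/MAP likelihood fusion
#'
#' Alternates selector update, parcellation argmax and local-transform
#' re-optimization until the changed-voxel fraction drops below
#' \code{stopTolerance} or \code{maxIterations} (default 30) is reached.
#' The per-iteration changed fraction and surrogate objective (the summed
#' log fused score of the chosen labels) are recorded in the state
#' history. A divergence guard stops the loop (with a flag) if the changed
#' fraction increases for five consecutive iterations. The run is
#' deterministic given its inputs.
#'
#' @param atlases list of \linkS4class{AtlasPair}.
#' @param subject the subject \linkS4class{MultiContrastImage}.
#' @param signatures list of per-atlas \linkS4class{AtlasSignature}s.
#' @param fields list of per-atlas global \linkS4class{DeformationField}s.
#' @param cfg a \linkS4class{FusionConfig}.
#' @param prior the \linkS4class{AffinePrior} for local refinements.
#' @return list with elements \code{labels} (the fused
#'   \linkS4class{LabelMap}) and \code{state} (the final
#'   \linkS4class{FusionState} including the history).
#' @export
runFusion <- function(atlases, subject, signatures, fields,
                      cfg = fusionConfig(), prior = affinePrior()) {
  .stopIf(length(signatures) != length(atlases),
          "need one signature per atlas")
  state <- initializeFusion(atlases, subject, fields, cfg)
  ll <- intensityLogLik(subject, signatures, state@labels, cfg@channelMask)
  prevW <- as.integer(state@parcellation@data)
  prevChanged <- Inf
  riseCount <- 0L
  for (it in seq_len(as.integer(cfg@maxIterations))) {
    sel <- computeSelector(state, ll, prior)
    state@selector <- sel
    newParc <- updateParcellation(state, ll)
    newW <- as.integer(newParc@data)
    changed <- mean(newW != prevW)
    state@parcellation <- newParc
    state@iteration <- it
    state@history <- rbind(state@history,
      data.frame(iteration = it, changedFraction = changed,
                 objective = attr(newParc, "objective"),
                 selectorFallback = attr(sel, "fallback")))
    if (cfg@verbose)
      message(sprintf("iteration %d: changed %.5f, objective %.4g", it,
                      changed, attr(newParc, "objective")))
    if (changed < cfg@stopTolerance) break
    if (changed > prevChanged) riseCount <- riseCount + 1L else riseCount <- 0L
    if (riseCount >= 5L) {
      state@flags <- c(state@flags, "divergence: changed fraction rose 5x")
      warning("fusion stopped early: changed-voxel fraction rose for 5 consecutive iterations")
      break
    }
    prevChanged <- changed
    moved <- newW != prevW
    changedLabels <- unique(c(newW[moved], prevW[moved]))
    prevW <- newW
    if (it < cfg@maxIterations)
      state <- updateTransforms(state, atlases, prior,
                                changedLabels = changedLabels)
  }
  list(labels = state@parcellation, state = state)
}
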