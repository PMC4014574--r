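# Shared fixtures. Expensive end-to-end phantom runs are computed once per
# test session and reused across tests.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# A small constant-intensity atlas: two blocks (labels 1, 2) in background,
# with well-separated single-Gaussian channel signatures.
makeBlockAtlas <- function(d = c(8, 8, 8), spacing = c(1, 1, 1), noise = 0,
                           seed = 1) {
  lab <- array(0L, d)
  lab[2:4, 2:7, 2:7] <- 1L
  lab[5:7, 2:7, 2:7] <- 2L
  set.seed(seed)
  mk <- function(vals) { # vals: background, label1, label2 means
    a <- array(vals[1], d)
    a[lab == 1L] <- vals[2]
    a[lab == 2L] <- vals[3]
    if (noise > 0) a <- a + array(rnorm(prod(d), 0, noise), d)
    a
  }
  fa <- pmin(pmax(mk(c(0.05, 0.2, 0.5)), 0), 1)
  md <- pmax(mk(c(0.0004, 0.0007, 0.0007)), 0)
  ex <- mk(c(0.58, 0.58, 0.91)); ey <- mk(c(0.58, 0.58, 0.29))
  ez <- mk(c(0.58, 0.58, 0.29))
  nrm <- sqrt(ex^2 + ey^2 + ez^2)
  img <- multiContrastImage(fa, md, ex / nrm, ey / nrm, ez / nrm,
                            spacing = spacing)
  atlasPair("block", img, labelMap(lab, spacing))
}

# Default 48^3 six-structure phantom pipeline (4 atlases, fixed seeds):
# library, registration, signatures, baselines and the fused run.
defaultPhantomRun <- function() cachedFixture("defaultPhantomRun", {
  spec <- defaultPhantomSpec(seed = 1L)
  lib <- suppressMessages(makeLibrary(spec, nAtlases = 4L))
  fields <- lapply(lib$atlases, function(a)
    registerTwoChannel(a@image, lib$subject@image))
  sigs <- lapply(lib$atlases, fitAtlasSignature, seed = 1L)
  singleDice <- vapply(seq_along(fields), function(i) {
    p <- composeAndResample(fields[[i]], NULL, lib$atlases[[i]]@labels)
    mean(diceByLabel(p, lib$subject@labels, labels = 1:6))
  }, numeric(1))
  res <- suppressWarnings(runFusion(lib$atlases, lib$subject@image, sigs,
                                    fields, fusionConfig()))
  list(spec = spec, lib = lib, fields = fields, sigs = sigs,
       singleDice = singleDice,
       fusedDice = diceByLabel(res$labels, lib$subject@labels, labels = 1:6),
       res = res)
})

# Ablation runs on the ambiguity phantom for one seed: per-structure Dice
# under the full 5-channel mask and the FA-only / MD-only / EV-only masks.
ablationRun <- function(seed) cachedFixture(sprintf("ablation%d", seed), {
  spec <- makeAmbiguityPhantom(seed)
  lib <- suppressMessages(makeLibrary(spec, nAtlases = 4L))
  fields <- lapply(lib$atlases, function(a)
    registerTwoChannel(a@image, lib$subject@image))
  sigs <- lapply(lib$atlases, fitAtlasSignature, seed = 1L)
  masks <- list(full = rep(TRUE, 5),
                fa = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                md = c(FALSE, TRUE, FALSE, FALSE, FALSE),
                ev = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  vapply(masks, function(m) {
    r <- suppressWarnings(runFusion(lib$atlases, lib$subject@image, sigs,
                                    fields, fusionConfig(channelMask = m)))
    diceByLabel(r$labels, lib$subject@labels, labels = 1:5)
  }, numeric(5))
})

# Independent brute-force fused-posterior labeling: per voxel and label,
# sum over atlases of selector * intensity likelihood * trilinearly
# interpolated deformed label probability, evaluated with plain loops and
# direct density calls.
bruteForceParcellation <- function(atlases, subject, sigs, fields,
                                   transforms, selector, labels,
                                   channelMask = rep(TRUE, 5)) {
  d <- gridDim(subject)
  inten <- sapply(c("fa", "md", "evx", "evy", "evz"), function(nm)
    as.numeric(volData(channel(subject, nm))))
  out <- integer(prod(d))
  vox <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    vox <- vox + 1L
    best <- -1; bestLab <- 0L
    for (l in labels) {
      s <- 0
      for (a in seq_along(atlases)) {
        aff <- if (l == 0L) NULL else transforms[[a]][[as.character(l)]]
        pt <- matrix(c(i, j, k), 1, 3)
        y <- if (is.null(aff)) pt else applyAffine(aff, pt)
        yy <- y + cbind(
          interpolateScalar(fields[[a]]@disp[, , , 1], y, fill = 0),
          interpolateScalar(fields[[a]]@disp[, , , 2], y, fill = 0),
          interpolateScalar(fields[[a]]@disp[, , , 3], y, fill = 0))
        p <- interpolateLabelProbability(atlases[[a]]@labels, yy, l)
        lik <- prod(vapply(which(channelMask), function(ci)
          max(gmmDensity(sigs[[a]]@models[[as.character(l)]][[
            c("fa", "md", "evx", "evy", "evz")[ci]]], inten[vox, ci]),
            1e-300), numeric(1)))
        s <- s + selector[vox, a] * lik * p
      }
      if (s > best) { best <- s; bestLab <- l }
    }
    out[vox] <- bestLab
  }
  array(out, d)
}
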