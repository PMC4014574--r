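# The EM/MAP fusion loop: initialization, selector, parcellation argmax,
# transform refresh and the full run contracts.

.monoModel <- function(mu, v) new("StructureIntensityModel", weights = 1,
                                  means = mu, variances = v)

# identical single-Gaussian models for every structure and channel:
# intensity carries no information about the label
.uninformativeSignature <- function(labels, id = "flat") {
  tmpl <- list(fa = .monoModel(0.5, 1), md = .monoModel(0.5, 1),
               evx = .monoModel(0.5, 1), evy = .monoModel(0.5, 1),
               evz = .monoModel(0.5, 1))
  models <- lapply(setNames(as.character(labels), as.character(labels)),
                   function(l) tmpl)
  new("AtlasSignature", atlasId = id, models = models,
      volumes = setNames(rep(1000, length(labels)), as.character(labels)))
}

test_that("initialization propagates labels and honors the init policy", {
  atlas <- makeBlockAtlas(noise = 0.01)
  d <- gridDim(atlas@image)
  st <- initializeFusion(list(atlas), atlas@image,
                         list(identityField(d)))
  expect_identical(volData(st@parcellation), volData(atlas@labels))
  expect_identical(st@labels, c(0L, 1L, 2L))
  # all local affines start at identity
  expect_true(all(vapply(st@transforms[[1]],
                         function(a) all(a@params == 0), logical(1))))

  expect_error(fusionConfig(maxIterations = 0), "maxIterations")
  expect_error(initializeFusion(list(), atlas@image, list()), "empty")
})

test_that("majority-vote initialization matches a brute-force vote oracle", {
  d <- c(8, 8, 8)
  set.seed(31)
  atlases <- lapply(1:3, function(i) {
    lab <- array(sample(0:2, prod(d), TRUE), d)
    img <- multiContrastImage(array(0.3, d), array(7e-4, d), array(1, d),
                              array(0, d), array(0, d))
    atlasPair(sprintf("a%d", i), img, labelMap(lab))
  })
  fields <- lapply(1:3, function(i) identityField(d))
  st <- initializeFusion(atlases, atlases[[1]]@image, fields)

  # brute force: count votes per label, argmax with smallest-label ties
  votes <- sapply(0:2, function(l)
    Reduce(`+`, lapply(atlases, function(a)
      as.integer(as.integer(volData(a@labels)) == l))))
  oracle <- c(0L, 1L, 2L)[max.col(votes, ties.method = "first")]
  expect_identical(as.integer(volData(st@parcellation)), oracle)

  # designated-atlas policy returns that atlas's propagated labels
  st1 <- initializeFusion(atlases, atlases[[1]]@image, fields,
                          fusionConfig(initAtlas = 2))
  expect_identical(volData(st1@parcellation), volData(atlases[[2]]@labels))
})

test_that("selector is uniform for identical atlases and renormalizes", {
  atlas <- makeBlockAtlas(noise = 0.01)
  d <- gridDim(atlas@image)
  sig <- fitAtlasSignature(atlas, seed = 2)
  atlases <- list(atlas, atlas)
  fields <- list(identityField(d), identityField(d))
  st <- initializeFusion(atlases, atlas@image, fields)
  ll <- intensityLogLik(atlas@image, list(sig, sig), st@labels)
  sel <- computeSelector(st, ll)
  expect_equal(rowSums(sel), rep(1, prod(d)), tolerance = 1e-9)
  expect_equal(as.numeric(sel), rep(0.5, 2 * prod(d)), tolerance = 1e-12)
})

test_that("an atlas with zero intensity likelihood gets zero weight", {
  atlas <- makeBlockAtlas(noise = 0.01)
  d <- gridDim(atlas@image)
  labels <- c(0L, 1L, 2L)
  goodSig <- fitAtlasSignature(atlas, seed = 2)
  # far-off means: density underflows to the floor at every voxel
  offTmpl <- list(fa = .monoModel(1e6, 1e-6), md = .monoModel(1e6, 1e-6),
                  evx = .monoModel(1e6, 1e-6), evy = .monoModel(1e6, 1e-6),
                  evz = .monoModel(1e6, 1e-6))
  badSig <- new("AtlasSignature", atlasId = "bad",
                models = lapply(setNames(as.character(labels),
                                         as.character(labels)),
                                function(l) offTmpl),
                volumes = setNames(rep(1000, 3), as.character(labels)))
  st <- initializeFusion(list(atlas, atlas), atlas@image,
                         list(identityField(d), identityField(d)))
  ll <- intensityLogLik(atlas@image, list(goodSig, badSig), st@labels)
  sel <- computeSelector(st, ll)
  expect_true(all(sel[, 1] > 1 - 1e-10))
  expect_equal(rowSums(sel), rep(1, prod(d)), tolerance = 1e-9)
})

test_that("selector equals a brute-force evaluation of the product formula", {
  set.seed(33)
  a1 <- makeBlockAtlas(noise = 0.02, seed = 41)
  a2 <- makeBlockAtlas(noise = 0.02, seed = 42)
  d <- gridDim(a1@image)
  sigs <- list(fitAtlasSignature(a1, seed = 2), fitAtlasSignature(a2, seed = 3))
  f1 <- identityField(d)
  f2 <- identityField(d)
  f2@disp <- array(rnorm(prod(d) * 3, 0, 0.2), c(d, 3))
  f2@geodesic <- 0.7
  subject <- makeBlockAtlas(noise = 0.02, seed = 43)@image
  atlases <- list(a1, a2)
  fields <- list(f1, f2)
  st <- initializeFusion(atlases, subject, fields)
  # give atlas 2 a nonzero structure-1 affine so the prior factor matters
  st@transforms[[2]][["1"]]@params[10] <- 0.8
  st@labelProbs[[2]] <- dtifusion:::.atlasLabelProbs(f2, st@transforms[[2]],
                                                     a2@labels, st@labels)
  ll <- intensityLogLik(subject, sigs, st@labels)
  sel <- computeSelector(st, ll)

  prior <- affinePrior()
  inten <- sapply(c("fa", "md", "evx", "evy", "evz"), function(nm)
    as.numeric(volData(channel(subject, nm))))
  w <- as.integer(volData(st@parcellation))
  geoW <- exp(-(st@geodesic - min(st@geodesic)))
  for (vox in sample(prod(d), 60)) {
    l <- w[vox]
    li <- match(l, st@labels)
    raw <- vapply(1:2, function(a) {
      lik <- suppressWarnings(
        voxelLikelihood(inten[vox, ], l, sigs[[a]]))
      affF <- if (l == 0L) 1 else
        exp(affineLogPrior(st@transforms[[a]][[as.character(l)]], prior))
      max(lik, 1e-300) * max(st@diceFactor[a, li], 1e-12) * geoW[a] * affF
    }, numeric(1))
    expect_equal(sel[vox, ], raw / sum(raw), tolerance = 1e-10)
  }
})

test_that("with flat intensities the update reduces to weighted voting", {
  set.seed(34)
  d <- c(10, 10, 10)
  mkAtlas <- function(seed, shift) {
    lab <- array(0L, d)
    lab[(3:6) + shift, 3:8, 3:8] <- 1L
    lab[7:9, 3:8, 3:8] <- 2L
    img <- multiContrastImage(array(0.3, d), array(7e-4, d), array(1, d),
                              array(0, d), array(0, d))
    atlasPair(sprintf("s%d", seed), img, labelMap(lab))
  }
  atlases <- list(mkAtlas(1, 0), mkAtlas(2, 1))
  fields <- lapply(1:2, function(i) {
    f <- identityField(d)
    f@disp <- array(rnorm(prod(d) * 3, 0, 0.3), c(d, 3))
    f
  })
  labels <- c(0L, 1L, 2L)
  sigs <- list(.uninformativeSignature(labels, "f1"),
               .uninformativeSignature(labels, "f2"))
  subject <- atlases[[1]]@image
  st <- initializeFusion(atlases, subject, fields)
  st@selector <- matrix(0.5, prod(d), 2)
  ll <- intensityLogLik(subject, sigs, labels)
  out <- updateParcellation(st, ll)

  # oracle: trilinear-probability-weighted majority vote of deformed labels
  pts <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  probSum <- sapply(labels, function(l)
    Reduce(`+`, lapply(1:2, function(a) {
      y <- pts + cbind(
        interpolateScalar(fields[[a]]@disp[, , , 1], pts, fill = 0),
        interpolateScalar(fields[[a]]@disp[, , , 2], pts, fill = 0),
        interpolateScalar(fields[[a]]@disp[, , , 3], pts, fill = 0))
      0.5 * interpolateLabelProbability(atlases[[a]]@labels, y, l)
    })))
  oracle <- labels[max.col(probSum, ties.method = "first")]
  expect_identical(as.integer(volData(out)), oracle)
})

test_that("equal label priors are broken by the FA likelihood", {
  d <- c(8, 8, 8)
  lab <- array(1L, d); lab[5:8, , ] <- 2L
  img <- multiContrastImage(array(0.35, d), array(7e-4, d), array(1, d),
                            array(0, d), array(0, d))
  atlas <- atlasPair("a", img, labelMap(lab))
  # half-voxel shift puts the boundary face exactly on voxel centers x = 4
  f <- identityField(d)
  f@disp[, , , 1] <- 0.5
  labels <- c(0L, 1L, 2L)
  tmpl <- function(faMu) list(fa = .monoModel(faMu, 0.0025),
                              md = .monoModel(7e-4, 1e-8),
                              evx = .monoModel(1, 0.01),
                              evy = .monoModel(0, 0.01),
                              evz = .monoModel(0, 0.01))
  sig <- new("AtlasSignature", atlasId = "a",
             models = list("0" = tmpl(0.05), "1" = tmpl(0.2),
                           "2" = tmpl(0.5)),
             volumes = c("0" = 1e4, "1" = 1e4, "2" = 1e4))
  # subject FA 0.45: at x = 4 the label prior ties (0.5/0.5) but the FA
  # likelihood favors structure 2
  subj <- multiContrastImage(array(0.45, d), array(7e-4, d), array(1, d),
                             array(0, d), array(0, d))
  st <- initializeFusion(list(atlas), subj, list(f))
  ll <- intensityLogLik(subj, list(sig), labels)
  st@selector <- matrix(1, prod(d), 1)
  out <- updateParcellation(st, ll)
  expect_true(all(volData(out)[4, , ] == 2L))
  p1 <- dtifusion:::.resampleLabelProb(f, NULL, atlas@labels, 1L)
  expect_equal(unique(as.vector(array(p1, d)[4, , ])), 0.5)
})

test_that("transform refresh improves structure overlap and is idempotent", {
  d <- c(16, 16, 16)
  lab <- array(0L, d); lab[5:10, 5:10, 5:10] <- 1L
  img <- multiContrastImage(array(0.3, d), array(7e-4, d), array(1, d),
                            array(0, d), array(0, d))
  off <- array(0L, d); off[8:13, 5:10, 5:10] <- 1L
  atlas <- atlasPair("a", img, labelMap(off))
  subject <- img
  st <- initializeFusion(list(atlas), subject, list(identityField(d)))
  st@parcellation <- labelMap(lab)
  st@diceFactor <- dtifusion:::.diceFactors(lab, st@labelProbs, st@labels)
  before <- st@diceFactor[1, 2]
  st2 <- updateTransforms(st, list(atlas))
  after <- st2@diceFactor[1, 2]
  expect_gt(after, before)
  # re-running at the optimum leaves the transform (and Dice) in place
  st3 <- updateTransforms(st2, list(atlas))
  expect_equal(st3@diceFactor[1, 2], after, tolerance = 1e-9)
  expect_equal(st3@transforms[[1]][["1"]]@params,
               st2@transforms[[1]][["1"]]@params, tolerance = 0.5)

  # every structure empty in the parcellation -> identity transforms
  stEmpty <- st
  stEmpty@parcellation <- labelMap(array(0L, d))
  st4 <- updateTransforms(stEmpty, list(atlas))
  expect_equal(st4@transforms[[1]][["1"]]@params, rep(0, 12))
})

test_that("run stops per tolerance and respects the iteration cap", {
  atlas <- makeBlockAtlas(noise = 0.01)
  d <- gridDim(atlas@image)
  sig <- fitAtlasSignature(atlas, seed = 2)

  # self-atlas run: converges at iteration 1 with zero changed voxels
  res <- runFusion(list(atlas), atlas@image, list(sig),
                   list(identityField(d)))
  expect_identical(res$state@iteration, 1L)
  expect_equal(res$state@history$changedFraction, 0)
  expect_identical(volData(res$labels), volData(atlas@labels))

  # stopTolerance 1 stops after exactly one EM iteration
  res1 <- runFusion(list(atlas), atlas@image, list(sig),
                    list(identityField(d)),
                    fusionConfig(stopTolerance = 1.0))
  expect_identical(res1$state@iteration, 1L)

  # the cap bounds the iteration count
  res2 <- runFusion(list(atlas), atlas@image, list(sig),
                    list(identityField(d)),
                    fusionConfig(maxIterations = 3, stopTolerance = 0))
  expect_lte(res2$state@iteration, 3L)
})
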