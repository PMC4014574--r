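# Synthetic phantom generator: determinism, generating-mixture fidelity,
# invertible warps and the ambiguity design.

test_that("ground truth is deterministic and honors the generating mixtures", {
  spec <- defaultPhantomSpec(seed = 7, dim = 32)
  gt1 <- suppressMessages(makeGroundTruth(spec))
  gt2 <- suppressMessages(makeGroundTruth(spec))
  expect_identical(volData(channel(gt1@image, "fa")),
                   volData(channel(gt2@image, "fa")))
  expect_identical(volData(gt1@labels), volData(gt2@labels))
  gt3 <- suppressMessages(makeGroundTruth(spec, seed = 8))
  expect_false(identical(volData(channel(gt1@image, "fa")),
                         volData(channel(gt3@image, "fa"))))

  # phantom satisfies the container invariants by construction
  expect_s4_class(gt1@image, "MultiContrastImage")
  expect_true(validObject(gt1@image))
  expect_true(validObject(gt1@labels))

  # empirical channel means within 3 standard errors of generating means
  for (s in spec@structures[1:3]) {
    idx <- volData(gt1@labels) == s$label
    n <- sum(idx)
    for (nm in c("fa", "md")) {
      mix <- s$mixtures[[nm]]
      mu <- sum(mix$weights * mix$means)
      sdv <- sqrt(sum(mix$weights * (mix$variances + mix$means^2)) - mu^2)
      emp <- mean(volData(channel(gt1@image, nm))[idx])
      expect_lt(abs(emp - mu), 3 * sdv / sqrt(n) + 1e-6)
    }
  }
})

test_that("zero-variance single-component structures are constant inside", {
  spec <- defaultPhantomSpec(seed = 1, dim = 16)
  spec@structures <- list(spec@structures[[2]])
  spec@structures[[1]]$geometry <- list(type = "box", lo = c(4, 4, 4),
                                        hi = c(12, 12, 12))
  spec@structures[[1]]$mixtures$fa <- list(weights = 1, means = 0.3,
                                           variances = 1e-20)
  gt <- makeGroundTruth(spec)
  inside <- volData(gt@labels) == spec@structures[[1]]$label
  expect_equal(diff(range(volData(channel(gt@image, "fa"))[inside])), 0,
               tolerance = 1e-8)
})

test_that("warped copies stay invertible and round-trip through the inverse", {
  spec <- defaultPhantomSpec(seed = 9, dim = 32)
  gt <- suppressMessages(makeGroundTruth(spec))

  # magnitude 0 is an identical copy
  same <- deformCopy(gt, magnitude = 0)
  expect_identical(volData(same$atlas@labels), volData(gt@labels))
  expect_equal(max(abs(same$field@disp)), 0)

  dc <- deformCopy(gt, magnitude = 2, smoothness = 8, seed = 10)
  d <- gridDim(gt@image)
  expect_gt(dtifusion:::.cpp_jacobian_min(as.double(dc$field@disp), d), 0)
  expect_gt(dtifusion:::.cpp_jacobian_min(as.double(dc$inverse@disp), d), 0)
  expect_false(identical(volData(dc$atlas@labels), volData(gt@labels)))

  # total labeled volume change is bounded by the Jacobian range
  v0 <- sum(volData(gt@labels) != 0)
  v1 <- sum(volData(dc$atlas@labels) != 0)
  expect_lt(abs(v1 - v0) / v0, 0.35)

  # warping the copy back through the inverse recovers the labels
  pts <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  y <- pts + matrix(dc$inverse@disp, ncol = 3)
  back <- array(as.integer(interpolateScalar(
    array(as.double(volData(dc$atlas@labels)), d), y, mode = "nearest")), d)
  for (l in labelSet(gt@labels)) {
    dice <- diceCoefficient(back == l, volData(gt@labels) == l)
    expect_gt(dice, 0.95)
  }
})

test_that("library copies are distinct and include a held-out subject", {
  spec <- defaultPhantomSpec(seed = 2, dim = 24)
  lib <- suppressMessages(makeLibrary(spec, nAtlases = 3))
  expect_length(lib$atlases, 3)
  expect_length(lib$fields, 3)
  # distinct seeds -> pairwise-distinct label maps
  for (i in 1:2) for (j in (i + 1):3)
    expect_false(identical(volData(lib$atlases[[i]]@labels),
                           volData(lib$atlases[[j]]@labels)))
  expect_false(identical(volData(lib$subject@labels),
                         volData(lib$atlases[[1]]@labels)))

  # n = 1 with zero deformation reduces to the ground truth
  spec0 <- defaultPhantomSpec(seed = 2, dim = 24, deformMagnitude = 0)
  lib0 <- suppressMessages(makeLibrary(spec0, nAtlases = 1))
  expect_identical(volData(lib0$atlases[[1]]@labels),
                   volData(lib0$truth@labels))
})

test_that("ambiguity phantom pairs are separable in exactly one channel group", {
  spec <- makeAmbiguityPhantom(seed = 1)
  stx <- spec@structures
  mixOf <- function(i, nm) stx[[i]]$mixtures[[nm]]
  mu <- function(i, nm) sum(mixOf(i, nm)$weights * mixOf(i, nm)$means)
  sg <- function(i, nm) sqrt(max(mixOf(i, nm)$variances))

  # ventricle vs tissue neighbour: MD >= 5 sigma apart, FA/EV coincide
  expect_gte(abs(mu(1, "md") - mu(2, "md")) /
             max(sg(1, "md"), sg(2, "md")), 5)
  expect_equal(mu(1, "fa"), mu(2, "fa"))
  for (nm in c("evx", "evy", "evz")) expect_equal(mu(1, nm), mu(2, nm))

  # the two tracts differ only in the EV channels
  expect_equal(mu(3, "fa"), mu(4, "fa"))
  expect_equal(mu(3, "md"), mu(4, "md"))
  expect_gt(abs(mu(3, "evx") - mu(4, "evx")), 0.3)

  # FA-only likelihoods cannot separate the tracts: density ratio ~ 1
  gt <- makeGroundTruth(spec)
  sig <- fitAtlasSignature(gt, seed = 1)
  idx <- which(volData(gt@labels) == 3L)[1:200]
  inten <- sapply(c("fa", "md", "evx", "evy", "evz"), function(nm)
    as.numeric(volData(channel(gt@image, nm)))[idx])
  faMask <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  l3 <- voxelLikelihood(inten, 3, sig, faMask)
  l4 <- voxelLikelihood(inten, 4, sig, faMask)
  expect_lt(abs(mean(log(l3 / l4))), 0.2) # chance level
  # while the EV channels separate them decisively
  evMask <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  e3 <- voxelLikelihood(inten, 3, sig, evMask)
  e4 <- voxelLikelihood(inten, 4, sig, evMask)
  expect_gt(mean(log(e3 / e4)), 5)
})

test_that("signature fitting recovers phantom generating means", {
  spec <- defaultPhantomSpec(seed = 3, dim = 32)
  gt <- suppressMessages(makeGroundTruth(spec))
  sig <- fitAtlasSignature(gt, seed = 4)
  for (s in spec@structures[1:3]) {
    m <- sig@models[[as.character(s$label)]]$md
    fitMean <- sum(m@weights * m@means)
    genMean <- sum(s$mixtures$md$weights * s$mixtures$md$means)
    expect_lt(abs(fitMean - genMean), 5e-5) # MD units: ~2% of tissue MD
  }
})
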