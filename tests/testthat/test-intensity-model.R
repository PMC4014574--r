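# Gaussian-mixture intensity signatures and the multi-contrast likelihood.

test_that("component count follows the 1000 mm^3 size rule", {
  expect_equal(componentCountRule(500), 2L)
  expect_equal(componentCountRule(5000), 3L)
  expect_equal(componentCountRule(999.9), 2L)
  expect_equal(componentCountRule(1000), 3L)
  expect_equal(componentCountRule(5000, kSmall = 1L, kLarge = 1L), 1L)
  expect_error(componentCountRule(-1), "non-negative")
})

test_that("EM recovers a well-separated two-component mixture", {
  set.seed(20)
  x <- c(rnorm(1000, 0.2, 0.01), rnorm(1000, 0.7, 0.01))
  m <- fitGmm(x, 2, seed = 4)
  expect_equal(m@means, c(0.2, 0.7), tolerance = 0.01)
  expect_equal(m@weights, c(0.5, 0.5), tolerance = 0.05)
  # log-likelihood trace is non-decreasing at every iteration
  tr <- attr(m, "trace")
  expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-length(tr)]))))
  # determinism given the seed
  m2 <- fitGmm(x, 2, seed = 4)
  expect_identical(m@means, m2@means)
  expect_identical(m@weights, m2@weights)
})

test_that("EM matches an independent reference implementation", {
  withr::local_package("mclust")
  set.seed(21)
  x <- c(rnorm(1000, 0.2, 0.01), rnorm(1000, 0.7, 0.01))
  m <- fitGmm(x, 2, seed = 4)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(m@logLik, ref$loglik, tolerance = 1e-3)
  expect_equal(sort(m@means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 1e-3)
})

test_that("degenerate samples collapse to a single point-mass component", {
  m <- fitGmm(rep(0.7, 100), K = 2, seed = 1)
  expect_equal(m@means, 0.7, tolerance = 1e-12)
  expect_equal(m@weights, 1)
  expect_gte(min(m@variances), 1e-6) # variance floor

  expect_warning(m3 <- fitGmm(c(0.1, 0.9), K = 5, seed = 1), "reducing K")
  expect_lte(length(m3@weights), 2L)
})

test_that("mean recovery within 2 standard errors across 20 seeds", {
  set.seed(30)
  fails <- 0L
  for (s in 1:20) {
    x <- c(rnorm(1000, 0.3, 0.02), rnorm(1000, 0.6, 0.02)) # 15 sigma apart
    m <- fitGmm(x, 2, seed = s)
    se <- 0.02 / sqrt(1000)
    if (any(abs(m@means - c(0.3, 0.6)) > 2 * se)) fails <- fails + 1L
  }
  # 2-SE coverage is ~95% per component; allow a small number of misses
  expect_lte(fails, 3L)
})

test_that("mixture density matches direct formula evaluation", {
  g1 <- new("StructureIntensityModel", weights = 1, means = 0, variances = 1)
  expect_equal(gmmDensity(g1, 0), 1 / sqrt(2 * pi), tolerance = 1e-12)

  m <- new("StructureIntensityModel", weights = c(0.5, 0.5),
           means = c(-1, 1), variances = c(0.25, 0.25))
  xs <- seq(-3, 3, by = 0.1)
  direct <- 0.5 * dnorm(xs, -1, 0.5) + 0.5 * dnorm(xs, 1, 0.5)
  expect_equal(gmmDensity(m, xs), direct, tolerance = 1e-12)
  # symmetric mixture evaluated at 0 equals one component's density at its
  # offset (the two half-weighted components coincide there)
  expect_equal(gmmDensity(m, 0), dnorm(1, 0, 0.5), tolerance = 1e-12)

  # monotone decay in the tail and numeric integral 1
  tail <- gmmDensity(m, seq(2, 8, by = 0.25))
  expect_true(all(diff(tail) < 0))
  xs2 <- seq(-10, 10, by = 0.001)
  expect_equal(sum(gmmDensity(m, xs2)) * 0.001, 1, tolerance = 1e-4)
})

test_that("voxel likelihood composes channel densities over the mask", {
  mono <- function(mu, v) new("StructureIntensityModel", weights = 1,
                              means = mu, variances = v)
  models <- list(
    "1" = list(fa = mono(0.2, 0.01), md = mono(7e-4, 1e-8),
               evx = mono(0.6, 0.01), evy = mono(0.6, 0.01),
               evz = mono(0.5, 0.01)),
    "2" = list(fa = mono(0.5, 0.01), md = mono(7e-4, 1e-8),
               evx = mono(0.6, 0.01), evy = mono(0.6, 0.01),
               evz = mono(0.5, 0.01)))
  sig <- new("AtlasSignature", atlasId = "t", models = models,
             volumes = c("1" = 100, "2" = 100))
  x <- c(0.3, 7e-4, 0.6, 0.6, 0.5)

  full <- voxelLikelihood(x, 1, sig)
  direct <- prod(dnorm(x[1], 0.2, 0.1), dnorm(x[2], 7e-4, 1e-4),
                 dnorm(x[3], 0.6, 0.1), dnorm(x[4], 0.6, 0.1),
                 dnorm(x[5], 0.5, 0.1))
  expect_equal(full, direct, tolerance = 1e-10)

  # FA equidistant between the two structures -> equal FA-only likelihoods
  faMask <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  x35 <- c(0.35, 7e-4, 0.6, 0.6, 0.5)
  expect_equal(voxelLikelihood(x35, 1, sig, faMask),
               voxelLikelihood(x35, 2, sig, faMask), tolerance = 1e-12)

  # caudate-like voxel scores higher under the caudate model by FA alone
  # even when the MD channels tie
  xc <- c(0.2, 7e-4, 0.6, 0.6, 0.5)
  expect_gt(voxelLikelihood(xc, 1, sig), voxelLikelihood(xc, 2, sig))

  expect_warning(z <- voxelLikelihood(x, 9, sig), "missing")
  expect_equal(z, 0)
  expect_error(voxelLikelihood(x, 1, sig, rep(FALSE, 5)), "at least one")
})

test_that("broad intra-structure variance downweights a channel", {
  mono <- function(mu, v) new("StructureIntensityModel", weights = 1,
                              means = mu, variances = v)
  # both structures have near-uniform (huge-variance) EV models but tight,
  # well-separated FA models: the likelihood ratio must be FA-driven
  mk <- function(fa_mu) list(fa = mono(fa_mu, 0.0004),
                             md = mono(7e-4, 1e-8),
                             evx = mono(0.5, 4), evy = mono(0.5, 4),
                             evz = mono(0.5, 4))
  sig <- new("AtlasSignature", atlasId = "t",
             models = list("1" = mk(0.2), "2" = mk(0.5)),
             volumes = c("1" = 1, "2" = 1))
  x <- c(0.22, 7e-4, 0.9, 0.1, 0.1) # EV wildly different from the means
  full <- voxelLikelihood(x, 1, sig) / voxelLikelihood(x, 2, sig)
  faOnly <- voxelLikelihood(x, 1, sig, c(TRUE, rep(FALSE, 4))) /
            voxelLikelihood(x, 2, sig, c(TRUE, rep(FALSE, 4)))
  expect_equal(log(full), log(faOnly), tolerance = 0.05)
  expect_gt(full, 100)
})

test_that("atlas signatures cover all structures and serialize to JSON", {
  atlas <- makeBlockAtlas(noise = 0.01)
  sig <- fitAtlasSignature(atlas, seed = 2)
  expect_setequal(names(sig@models), c("0", "1", "2"))
  expect_equal(sig@volumes[["1"]], sum(volData(atlas@labels) == 1L))
  # structure means are recovered from the atlas voxels
  expect_equal(sum(sig@models[["2"]]$fa@weights * sig@models[["2"]]$fa@means),
               0.5, tolerance = 0.02)

  dir <- withr::local_tempdir()
  p <- file.path(dir, "sig.json")
  writeSignatures(list(sig), p)
  back <- readSignatures(p)[[1]]
  expect_equal(back@models[["1"]]$md@means, sig@models[["1"]]$md@means)
  expect_equal(back@models[["2"]]$fa@weights, sig@models[["2"]]$fa@weights)
  expect_equal(back@volumes, sig@volumes)
})
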