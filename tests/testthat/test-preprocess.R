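test_that("resampling to the input grid is the identity", {
  vol <- randomVolume(dim = c(8L, 8L, 8L), spacing = 1.2, origin = c(0, 0, 0))
  out <- resampleIsotropic(vol, 1.2, "linear")
  expect_equal(gridDim(out), gridDim(vol))
  expect_lt(max(abs(volValues(out) - volValues(vol))), 1e-6)
  expect_equal(origin(out), origin(vol), tolerance = 1e-9)
})

test_that("resampling preserves constants and linear ramps", {
  const <- scalarVolume(array(3.7, c(6L, 6L, 6L)), spacing = 2.4)
  out <- resampleIsotropic(const, 1.0)
  expect_true(all(abs(volValues(out) - 3.7) < 1e-12))

  # linear field is reproduced exactly by trilinear interpolation (interior)
  n <- 10L
  ax <- (seq_len(n) - 1) * 2.4
  ramp <- array(0, rep(n, 3))
  for (k in seq_len(n)) ramp[, , k] <-
      outer(ax, ax, function(x, y) 0.5 * x - 0.2 * y) + 0.1 * ax[k]
  vol <- scalarVolume(ramp, spacing = 2.4, origin = c(0, 0, 0))
  out <- resampleIsotropic(vol, 1.2)
  co <- DosePaintR:::.axisCoords(out)
  expected <- array(0, gridDim(out))
  for (k in seq_along(co[[3]])) expected[, , k] <-
      outer(co[[1]], co[[2]], function(x, y) 0.5 * x - 0.2 * y) +
      0.1 * co[[3]][k]
  interior <- array(FALSE, gridDim(out))
  interior[3:(dim(interior)[1] - 3), 3:(dim(interior)[2] - 3),
           3:(dim(interior)[3] - 3)] <- TRUE
  expect_lt(max(abs(volValues(out)[interior] - expected[interior])), 1e-3)
})

test_that("masks resample with nearest-neighbour and stay binary", {
  m <- sphereMask(6, 2.4, 12L)
  out <- resampleIsotropic(m, 1.2)
  expect_s4_class(out, "BinaryMask")
  expect_true(all(volValues(out) %in% c(0L, 1L)))
  expect_gt(sum(volValues(out)), 0)
  expect_error(resampleIsotropic(m, -1), "> 0")
})

test_that("reference normalization divides out the reference mean", {
  vol <- randomVolume(dim = c(10L, 10L, 10L), seed = 5L)
  vol@values <- vol@values + 10
  ref <- binaryMask(array(rep(c(1, 0), c(500, 500)), c(10, 10, 10)),
                    spacing = spacing(vol), origin = origin(vol),
                    label = "reference")
  out <- normalizeToReference(vol, ref)
  expect_equal(mean(volValues(out)[volValues(ref) == 1L]), 1,
               tolerance = 1e-12)

  const <- scalarVolume(array(4, c(10, 10, 10)), spacing = spacing(vol),
                        origin = origin(vol))
  expect_true(all(abs(volValues(normalizeToReference(const, ref)) - 1) <
                    1e-12))

  # direct arithmetic: value 5 with reference mean 2 -> 2.5
  v <- array(2, c(5, 5, 5)); v[1, 1, 1] <- 5
  refAll <- binaryMask(array(1, c(5, 5, 5)), label = "reference")
  refAll@values[1, 1, 1] <- 0L  # keep the probe voxel out of the reference
  vol2 <- scalarVolume(v)
  out2 <- normalizeToReference(vol2, refAll)
  expect_equal(volValues(out2)[1, 1, 1], 2.5, tolerance = 1e-12)

  zero <- scalarVolume(array(0, c(10, 10, 10)), spacing = spacing(vol),
                       origin = origin(vol))
  expect_error(normalizeToReference(zero, ref), "degenerate")
  tiny <- binaryMask(array(c(1, rep(0, 999)), c(10, 10, 10)),
                     spacing = spacing(vol), origin = origin(vol))
  expect_error(normalizeToReference(vol, tiny), "need >= 100")
})

test_that("bilateral filter matches a brute-force oracle and preserves edges", {
  set.seed(9)
  arr <- array(rnorm(10 * 9 * 8, mean = 2), c(10, 9, 8))
  vol <- scalarVolume(arr, spacing = c(1.2, 1.0, 0.8))
  out <- bilateralSmooth(vol, spatialSdMm = 1.5, rangeSd = 0.8)
  oracle <- bruteBilateral(arr, spacing(vol), 1.5, 0.8)
  expect_lt(max(abs(volValues(out) - oracle)), 1e-10)

  # constants are fixed points
  const <- scalarVolume(array(5, c(6, 6, 6)))
  expect_true(all(abs(volValues(bilateralSmooth(const, 2, 0.5)) - 5) <
                    1e-12))

  # range sd -> Inf limit equals plain Gaussian smoothing
  vol2 <- scalarVolume(array(rnorm(12^3), c(12, 12, 12)), spacing = 1)
  wide <- bilateralSmooth(vol2, spatialSdMm = 2, rangeSd = 1e7)
  gauss <- DosePaintR:::.gaussBlur(volValues(vol2), 2, spacing(vol2))
  expect_lt(max(abs(volValues(wide) - gauss)), 1e-3)

  # two-region step: voxels >= 3 voxels from the edge barely change
  step <- array(0, c(14, 10, 10)); step[8:14, , ] <- 1
  sv <- scalarVolume(step, spacing = 1)
  sm <- bilateralSmooth(sv, spatialSdMm = 2, rangeSd = 0.1)
  far <- array(FALSE, dim(step)); far[c(1:4, 11:14), , ] <- TRUE
  expect_lt(max(abs(volValues(sm)[far] - step[far])), 0.01)

  expect_error(bilateralSmooth(vol, -1, 0.5), "> 0")
})

test_that("standardization yields population z-scores over the mask", {
  vol <- randomVolume(dim = c(8L, 8L, 8L), seed = 13L)
  mask <- binaryMask(array(runif(512) < 0.6, c(8, 8, 8)),
                     spacing = spacing(vol), origin = origin(vol))
  out <- standardizeVolume(vol, mask)
  inm <- volValues(mask) == 1L
  expect_equal(mean(volValues(out)[inm]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(volValues(out)[inm]^2)), 1, tolerance = 1e-9)
  expect_true(all(is.nan(volValues(out)[!inm])))

  # hand-computed: {1,2,3} with population sd sqrt(2/3)
  v <- array(0, c(3, 1, 1)); v[] <- 1:3
  m <- binaryMask(array(1, c(3, 1, 1)))
  z <- volValues(standardizeVolume(scalarVolume(v), m))
  expect_equal(as.numeric(z), c(-1.224745, 0, 1.224745), tolerance = 1e-6)

  # idempotence
  out2 <- standardizeVolume(out, mask)
  expect_lt(max(abs(volValues(out2)[inm] - volValues(out)[inm])), 1e-9)

  const <- scalarVolume(array(2, c(8, 8, 8)), spacing = spacing(vol),
                        origin = origin(vol))
  expect_error(standardizeVolume(const, mask), "zero variance")
})

test_that("field-of-view restriction NaNs exactly the out-of-slab voxels", {
  vol <- randomVolume(dim = c(6L, 6L, 6L), seed = 1L)
  full <- binaryMask(array(1, c(6, 6, 6)), spacing = spacing(vol),
                     origin = origin(vol))
  expect_identical(volValues(restrictToFov(vol, full)), volValues(vol))

  slab <- array(0, c(6, 6, 6)); slab[, , 2:4] <- 1
  fov <- binaryMask(slab, spacing = spacing(vol), origin = origin(vol))
  out <- restrictToFov(vol, fov)
  expect_identical(sum(is.nan(volValues(out))), sum(slab == 0))
  expect_identical(volValues(out)[slab == 1], volValues(vol)[slab == 1])

  empty <- binaryMask(array(0, c(6, 6, 6)), spacing = spacing(vol),
                      origin = origin(vol))
  expect_error(restrictToFov(vol, empty), "empty")
})

test_that("normalize-smooth-standardize chain ignores global rescaling", {
  cs <- sharedSmallCase()
  raw <- scalarVolume(volValues(cs@adc) + 5, spacing = spacing(cs@adc),
                      origin = origin(cs@adc))
  brain <- getStructure(cs@structures, "brain")
  ref <- binaryMask(volValues(brain) == 1L &
                      volValues(getStructure(cs@structures, "CTV")) == 0L &
                      volValues(getStructure(cs@structures, "CSF")) == 0L,
                    spacing = spacing(brain), origin = origin(brain),
                    label = "reference")
  chain <- function(v)
    standardizeVolume(bilateralSmooth(normalizeToReference(v, ref), 2, 0.5),
                      brain)
  a <- chain(raw)
  scaled <- scalarVolume(3.2 * volValues(raw), spacing = spacing(raw),
                         origin = origin(raw))
  b <- chain(scaled)
  inb <- volValues(brain) == 1L
  expect_lt(max(abs(volValues(a)[inb] - volValues(b)[inb])), 1e-6)
})
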