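test_that("zero-margin expansion is the identity", {
  m <- sphereMask(6, 1.5, 16L)
  out <- expandMargin(m, 0)
  expect_identical(volValues(out), volValues(m))
  empty <- binaryMask(array(0, c(4, 4, 4)))
  expect_error(expandMargin(empty, 5), "empty")
  expect_error(expandMargin(m, -1), ">= 0")
})

test_that("expansion agrees with a brute-force distance oracle", {
  set.seed(4)
  arr <- array(runif(8 * 7 * 6) < 0.05, c(8, 7, 6))
  arr[4, 4, 3] <- TRUE
  m <- binaryMask(arr, spacing = c(1.2, 1.0, 0.8))
  for (margin in c(1.0, 2.5)) {
    out <- expandMargin(m, margin)
    oracle <- bruteDistance(arr, spacing(m)) <= margin + 1e-9
    expect_identical(volValues(out) == 1L, oracle)
  }
})

test_that("a barrier clips the expansion without shifting the free side", {
  m <- sphereMask(4, 1, 20L)
  upper <- array(FALSE, c(20, 20, 20)); upper[, , 11:20] <- TRUE
  barrier <- binaryMask(upper, spacing = 1, origin = origin(m),
                        label = "barrier")
  noBar <- expandMargin(m, 5)
  withBar <- expandMargin(m, 5, barrier = barrier)
  # nothing inside the barrier except original seed voxels
  expect_true(all(volValues(withBar)[upper & volValues(m) == 0L] == 0L))
  # the unblocked half matches the barrier-free expansion
  expect_identical(volValues(withBar)[!upper], volValues(noBar)[!upper])
  # seed always contained
  expect_true(all(volValues(withBar)[volValues(m) == 1L] == 1L))
})

test_that("expansion is monotone in the margin and composes additively", {
  m <- sphereMask(5, 1.2, 24L)
  a <- expandMargin(m, 3)
  b <- expandMargin(m, 7)
  expect_true(all(volValues(a) <= volValues(b)))
  # composition never overshoots the single-step expansion (triangle
  # inequality is exact on voxel centres) and undershoots it by at most
  # the voxel-diagonal discretization slack
  composed <- expandMargin(expandMargin(m, 3), 4)
  expect_true(all(volValues(composed) <= volValues(b)))
  slack <- sqrt(sum(spacing(m)^2))
  inner <- expandMargin(m, 7 - slack)
  expect_true(all(volValues(inner) <= volValues(composed)))
})

test_that("spherical margins reproduce the prescribed radius increases", {
  gtv <- sphereMask(10, 1, 64L, label = "GTV")
  ctv <- expandMargin(gtv, 15)
  expect_equal(equivalentSphereRadiusMm(ctv) - equivalentSphereRadiusMm(gtv),
               15, tolerance = 0.02)
  ptv <- expandMargin(ctv, 3)
  expect_equal(equivalentSphereRadiusMm(ptv) - equivalentSphereRadiusMm(ctv),
               3, tolerance = 0.05)
})

test_that("buildStructureSet clips the CTV to brain and nests targets", {
  cs <- sharedSmallCase()
  gtv <- getStructure(cs@structures, "GTV")
  brain <- getStructure(cs@structures, "brain")
  csf <- getStructure(cs@structures, "CSF")
  s <- buildStructureSet(gtv, brain, csf)
  ctv <- getStructure(s, "CTV")
  ptv <- getStructure(s, "PTV")
  expect_true(all(volValues(ctv) <= volValues(brain)))
  expect_true(all(volValues(gtv) <= volValues(ctv)))
  expect_true(all(volValues(ctv) <= volValues(ptv)))

  # PTV shell thickness: median distance of shell voxels to the CTV ~ 3 mm
  shell <- volValues(ptv) == 1L & volValues(ctv) == 0L
  d <- DosePaintR:::.edt(volValues(ctv) != 0L, spacing(ctv))
  expect_lt(abs(stats::median(d[shell]) - 3 / 2) , 3)
  expect_true(max(d[shell]) <= 3 + max(spacing(ctv)))

  # a GTV poking out of the brain is rejected
  outside <- binaryMask(array(1, gridDim(gtv)), spacing = spacing(gtv),
                        origin = origin(gtv), label = "GTV")
  expect_error(buildStructureSet(outside, brain, csf), "outside the brain")
})

test_that("a deep-seated GTV yields the analytic CTV volume", {
  # 10 mm sphere + 15 mm margin inside a large brain: volume of a 25 mm
  # sphere within discretization tolerance
  n <- 56L
  gtv <- sphereMask(10, 1.2, n, label = "GTV")
  brain <- binaryMask(array(1, rep(n, 3)), spacing = 1.2,
                      origin = origin(gtv), label = "brain")
  csf <- binaryMask(array(0, rep(n, 3)), spacing = 1.2,
                    origin = origin(gtv), label = "CSF")
  csf@values[1, 1, 1] <- 1L  # non-empty placeholder far from the GTV
  s <- buildStructureSet(gtv, brain, csf)
  vol <- sum(volValues(getStructure(s, "CTV"))) * 1.2^3
  # voxel-centre expansion biases the radius low by up to half a voxel at
  # this 1.2 mm resolution, so allow ~5% on the volume
  expect_equal(vol, 4 / 3 * pi * 25^3, tolerance = 0.05)
})

test_that("structure-set validity enforces nesting and required names", {
  cs <- sharedSmallCase()
  masks <- cs@structures@masks
  expect_error(structureSet(masks[c("GTV", "CTV", "PTV", "brain")]),
               "missing required structures")
  swapped <- masks
  swapped$GTV <- masks$CTV
  swapped$CTV <- masks$GTV
  expect_error(structureSet(swapped), "not contained")
})
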