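# Shared fixtures and independent oracles for the test suite.

# Desk-scale phantom: same physical extent as the default head, coarser grid.
smallPhantomConfig <- function(seed = 1L, ...) {
  PhantomConfig(gridShape = c(48L, 48L, 48L), spacingMm = 2.4,
                seed = as.integer(seed), ...)
}

# A tiny grid-aligned random volume.
randomVolume <- function(dim = c(7L, 6L, 5L), spacing = c(1.2, 1.2, 1.2),
                         origin = c(-10, 0, 4), seed = 42L) {
  set.seed(seed)
  scalarVolume(array(rnorm(prod(dim)), dim), spacing = spacing,
               origin = origin)
}

# Rasterize a sphere mask on an isotropic grid centred at the origin.
sphereMask <- function(radiusMm, spacingMm, nVox, label = "sphere") {
  ax <- (seq_len(nVox) - (nVox + 1) / 2) * spacingMm
  x <- array(ax, rep(nVox, 3))
  y <- array(rep(ax, each = nVox), rep(nVox, 3))
  z <- array(rep(ax, each = nVox^2), rep(nVox, 3))
  binaryMask(x^2 + y^2 + z^2 <= radiusMm^2, spacing = spacingMm,
             origin = rep(ax[1], 3), label = label)
}

# Brute-force Euclidean distance (mm) from the set voxels of a mask array.
bruteDistance <- function(maskArr, spacingMm) {
  d <- dim(maskArr)
  seeds <- which(maskArr != 0, arr.ind = TRUE)
  out <- array(Inf, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    out[i, j, k] <- sqrt(min(
      ((i - seeds[, 1]) * spacingMm[1])^2 +
        ((j - seeds[, 2]) * spacingMm[2])^2 +
        ((k - seeds[, 3]) * spacingMm[3])^2))
  out
}

# Brute-force bilateral filter on a small 3-D array (physical-distance and
# intensity Gaussian weights, window truncated at 3.5 spatial sd).
bruteBilateral <- function(arr, spacingMm, spatialSdMm, rangeSd) {
  d <- dim(arr)
  rad <- pmax(1, ceiling(3.5 * spatialSdMm / spacingMm))
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    c0 <- arr[i, j, k]
    ii <- max(1, i - rad[1]):min(d[1], i + rad[1])
    jj <- max(1, j - rad[2]):min(d[2], j + rad[2])
    kk <- max(1, k - rad[3]):min(d[3], k + rad[3])
    acc <- 0; wsum <- 0
    for (a in ii) for (b in jj) for (cc in kk) {
      v <- arr[a, b, cc]
      w <- exp(-0.5 * (((a - i) * spacingMm[1])^2 +
                         ((b - j) * spacingMm[2])^2 +
                         ((cc - k) * spacingMm[3])^2) / spatialSdMm^2) *
        exp(-0.5 * (v - c0)^2 / rangeSd^2)
      acc <- acc + w * v; wsum <- wsum + w
    }
    out[i, j, k] <- acc / wsum
  }
  out
}

# Sort-based DVH oracle: fraction of voxels with dose >= d.
bruteVolumeFraction <- function(doses, d) sum(sort(doses) >= d) / length(doses)

# Sort-based Dx% oracle: linear interpolation between order statistics
# (type-7), written independently of stats::quantile.
bruteDxPercent <- function(doses, xPercent) {
  v <- sort(doses)
  n <- length(v)
  h <- (n - 1) * (100 - xPercent) / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# Identity plan for a prescription (exercised further in its own tests).
asPlan <- function(rx) idealPlan(rx)

# Small synthetic regions / dose fields for evaluation-metric tests.
mkRegion <- function(n, dims = c(10L, 10L, 10L), seed = 1L) {
  set.seed(seed)
  arr <- array(0L, dims)
  arr[sample(prod(dims), n)] <- 1L
  binaryMask(arr, label = "region")
}

mkDose <- function(valuesInRegion, region) {
  v <- array(0, gridDim(region))
  v[volValues(region) == 1L] <- valuesInRegion
  new("DosePlan", values = v, spacing = spacing(region),
      origin = origin(region), converged = TRUE, objectiveTrace = 0)
}

mkRx <- function(valuesInRegion, region, dMin = 60, dMax = 80) {
  v <- array(NaN, gridDim(region))
  v[volValues(region) == 1L] <- valuesInRegion
  new("DosePrescription", values = v, spacing = spacing(region),
      origin = origin(region), dMinGy = dMin, dMaxGy = dMax)
}

# Cached small phantom shared across test files (generation is cheap but
# not free; the object is immutable).
.sharedEnv <- new.env()
sharedSmallCase <- function() {
  if (is.null(.sharedEnv$case))
    .sharedEnv$case <- generatePhantom(smallPhantomConfig(seed = 7L))
  .sharedEnv$case
}
sharedSmallProbability <- function() {
  if (is.null(.sharedEnv$p)) {
    cs <- sharedSmallCase()
    .sharedEnv$p <- tumourProbabilityMap(cs@adc, cs@rcbf, cs@structures)
  }
  .sharedEnv$p
}
sharedSmallRx <- function() {
  if (is.null(.sharedEnv$rx))
    .sharedEnv$rx <- dosePrescription(sharedSmallProbability(),
                                      sharedSmallCase()@structures)
  .sharedEnv$rx
}
sharedSmallDpPlan <- function() {
  if (is.null(.sharedEnv$planDp))
    .sharedEnv$planDp <- optimizePlan(
      sharedSmallRx(), sharedSmallCase()@structures,
      beam = SurrogateBeamModel(maxIterations = 80L),
      mode = "dose_painting")
  .sharedEnv$planDp
}
sharedSmallStdPlan <- function() {
  if (is.null(.sharedEnv$planStd)) {
    cs <- sharedSmallCase()
    .sharedEnv$planStd <- optimizePlan(
      standardPrescription(cs@structures), cs@structures,
      beam = SurrogateBeamModel(maxIterations = 80L), mode = "standard")
  }
  .sharedEnv$planStd
}
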