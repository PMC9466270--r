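# Parametric-map preprocessing: isotropic resampling, reference-region
# normalization, edge-preserving bilateral smoothing, standardization, and
# field-of-view restriction. Inputs are assumed co-registered.

#' Resample a volume to isotropic spacing
#'
#' The output grid covers the same physical extent as the input (voxel-edge
#' to voxel-edge); linear interpolation is used for scalar maps and
#' nearest-neighbour for masks. Samples falling outside the input grid are
#' clamped to the nearest edge voxel.
#'
#' @param vol a \linkS4class{ScalarVolume} or \linkS4class{BinaryMask}.
#' @param spacingMm target isotropic spacing, mm.
#' @param mode \code{"linear"} or \code{"nearest"}; masks always use
#'   nearest-neighbour.
#' @return Resampled object of the same class.
#' @export
resampleIsotropic <- function(vol, spacingMm = 1.2,
                              mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (spacingMm <= 0) stop("spacingMm must be > 0", call. = FALSE)
  isMask <- is(vol, "BinaryMask")
  if (isMask) mode <- "nearest"
  d <- dim(vol@values)
  extent <- d * vol@spacing
  newDim <- pmax(1L, as.integer(ceiling(extent / spacingMm - 1e-6)))
  newSpacing <- rep(spacingMm, 3)
  # first output voxel centre sits half a (new) voxel inside the old edge
  newOrigin <- vol@origin - vol@spacing / 2 + newSpacing / 2

  # continuous input indices (1-based) of the output voxel centres
  idx <- lapply(1:3, function(a) {
    xo <- newOrigin[a] + (seq_len(newDim[a]) - 1) * newSpacing[a]
    (xo - vol@origin[a]) / vol@spacing[a] + 1
  })

  if (mode == "nearest") {
    near <- lapply(1:3, function(a) pmin(pmax(round(idx[[a]]), 1L), d[a]))
    out <- vol@values[as.matrix(expand.grid(near[[1]], near[[2]],
                                            near[[3]]))]
    out <- array(out, newDim)
  } else {
    lo <- lapply(1:3, function(a) pmin(pmax(floor(idx[[a]]), 1L), d[a]))
    hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d[a]))
    fr <- lapply(1:3, function(a) pmin(pmax(idx[[a]] - lo[[a]], 0), 1))
    g <- function(ix, iy, iz)
      array(vol@values[as.matrix(expand.grid(ix, iy, iz))], newDim)
    fx <- array(fr[[1]], newDim)
    fy <- array(rep(fr[[2]], each = newDim[1]), newDim)
    fz <- array(rep(fr[[3]], each = newDim[1] * newDim[2]), newDim)
    out <-
      g(lo[[1]], lo[[2]], lo[[3]]) * (1 - fx) * (1 - fy) * (1 - fz) +
      g(hi[[1]], lo[[2]], lo[[3]]) * fx * (1 - fy) * (1 - fz) +
      g(lo[[1]], hi[[2]], lo[[3]]) * (1 - fx) * fy * (1 - fz) +
      g(hi[[1]], hi[[2]], lo[[3]]) * fx * fy * (1 - fz) +
      g(lo[[1]], lo[[2]], hi[[3]]) * (1 - fx) * (1 - fy) * fz +
      g(hi[[1]], lo[[2]], hi[[3]]) * fx * (1 - fy) * fz +
      g(lo[[1]], hi[[2]], hi[[3]]) * (1 - fx) * fy * fz +
      g(hi[[1]], hi[[2]], hi[[3]]) * fx * fy * fz
  }
  if (isMask)
    binaryMask(out, spacing = newSpacing, origin = newOrigin,
               label = vol@label)
  else scalarVolume(out, spacing = newSpacing, origin = newOrigin)
}

#' Normalize a map to a contralateral reference region
#'
#' Divides the volume by its mean over the reference region, so the
#' reference mean of the output is exactly 1. The reference region should
#' lie in contralateral normal-appearing brain, away from tumour and CSF.
#'
#' @param vol a \linkS4class{ScalarVolume}.
#' @param ref a \linkS4class{BinaryMask} reference region (>= \code{minVoxels}
#'   voxels).
#' @param minVoxels minimum reference size (default 100).
#' @return Normalized \linkS4class{ScalarVolume}.
#' @export
normalizeToReference <- function(vol, ref, minVoxels = 100L) {
  assertSameGrid(volume = vol, reference = ref)
  nref <- sum(ref@values)
  if (nref < minVoxels)
    stop("reference region has ", nref, " voxels; need >= ", minVoxels,
         call. = FALSE)
  m <- mean(vol@values[.inMask(ref)])
  if (!is.finite(m) || abs(m) < 1e-9)
    stop("degenerate reference region: mean is ", m, call. = FALSE)
  scalarVolume(vol@values / m, spacing = vol@spacing, origin = vol@origin)
}

#' Edge-preserving bilateral smoothing
#'
#' Each output voxel is a normalized weighted mean of its neighbours with
#' weights Gaussian both in physical distance and in intensity difference,
#' so strong edges (e.g. tumour/CSF interfaces) are preserved while noise
#' within homogeneous regions is suppressed. NaN voxels are skipped as
#' neighbours and remain NaN in the output.
#'
#' @param vol a \linkS4class{ScalarVolume}.
#' @param spatialSdMm spatial kernel sd in mm (default 2).
#' @param rangeSd intensity kernel sd, in the map's units (default 0.5).
#' @return Smoothed \linkS4class{ScalarVolume}.
#' @export
bilateralSmooth <- function(vol, spatialSdMm = 2, rangeSd = 0.5) {
  if (spatialSdMm <= 0 || rangeSd <= 0)
    stop("spatialSdMm and rangeSd must be > 0", call. = FALSE)
  sigmaVox <- spatialSdMm / vol@spacing
  out <- .cpp_bilateral3d(as.numeric(vol@values),
                          as.integer(dim(vol@values)),
                          as.numeric(sigmaVox), rangeSd)
  scalarVolume(array(out, dim(vol@values)), spacing = vol@spacing,
               origin = vol@origin)
}

#' Standardize a map over a mask (z-scoring)
#'
#' Subtracts the mask mean and divides by the population (\eqn{\div N})
#' standard deviation over the mask, yielding mean 0 and sd 1 there; voxels
#' outside the mask are set to NaN.
#'
#' @param vol a \linkS4class{ScalarVolume}.
#' @param mask a \linkS4class{BinaryMask} with at least 2 voxels.
#' @return Standardized \linkS4class{ScalarVolume} (NaN outside the mask).
#' @export
standardizeVolume <- function(vol, mask) {
  assertSameGrid(volume = vol, mask = mask)
  idx <- .inMask(mask)
  n <- sum(idx)
  if (n < 2L) stop("standardization mask needs >= 2 voxels", call. = FALSE)
  v <- vol@values[idx]
  if (anyNA(v)) stop("NaN values inside the standardization mask",
                     call. = FALSE)
  mu <- mean(v)
  sdPop <- sqrt(mean((v - mu)^2))
  if (sdPop <= 0)
    stop("zero variance over the standardization mask", call. = FALSE)
  out <- array(NaN, dim(vol@values))
  out[idx] <- (vol@values[idx] - mu) / sdPop
  scalarVolume(out, spacing = vol@spacing, origin = vol@origin)
}

#' Restrict a map to a field-of-view mask
#'
#' Voxels outside the FOV become NaN; inside values are unchanged. Mirrors
#' the restriction of parametric maps to the region where both diffusion-
#' and perfusion-weighted data were acquired.
#'
#' @param vol a \linkS4class{ScalarVolume}.
#' @param fov a non-empty \linkS4class{BinaryMask}.
#' @return Restricted \linkS4class{ScalarVolume}.
#' @export
restrictToFov <- function(vol, fov) {
  assertSameGrid(volume = vol, fov = fov)
  .stopIfEmpty(fov, "FOV")
  out <- vol@values
  out[!.inMask(fov)] <- NaN
  scalarVolume(out, spacing = vol@spacing, origin = vol@origin)
}
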