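# Internal helpers shared across modules.

# Compare two grid-aligned objects; returns TRUE or a message string.
.gridsAgree <- function(a, b, spacingTol = 1e-4, originTol = 1e-3) {
  if (!identical(dim(a@values), dim(b@values)))
    return(sprintf("shape %s vs %s",
                   paste(dim(a@values), collapse = "x"),
                   paste(dim(b@values), collapse = "x")))
  if (any(abs(a@spacing - b@spacing) > spacingTol))
    return(sprintf("spacing (%s) vs (%s) mm",
                   paste(signif(a@spacing, 6), collapse = ","),
                   paste(signif(b@spacing, 6), collapse = ",")))
  if (any(abs(a@origin - b@origin) > originTol))
    return(sprintf("origin (%s) vs (%s) mm",
                   paste(signif(a@origin, 6), collapse = ","),
                   paste(signif(b@origin, 6), collapse = ",")))
  TRUE
}

# Physical coordinates (mm) of voxel centres along each axis.
.axisCoords <- function(vol) {
  d <- dim(vol@values)
  lapply(1:3, function(a) vol@origin[a] + (seq_len(d[a]) - 1) * vol@spacing[a])
}

# Squared-distance field (mm) from the set voxels of a mask array.
# Wrapper around the compiled anisotropic Euclidean distance transform.
.edt <- function(maskArr, spacingMm) {
  d <- dim(maskArr)
  out <- .cpp_edt3d(as.logical(maskArr), as.integer(d),
                    as.numeric(spacingMm))
  array(out, dim = d)
}

# Separable Gaussian blur; sigmaMm scalar or length-3, converted to voxels.
.gaussBlur <- function(arr, sigmaMm, spacingMm, renorm = TRUE) {
  if (length(sigmaMm) == 1L) sigmaMm <- rep(sigmaMm, 3L)
  sigmaVox <- sigmaMm / spacingMm
  out <- .cpp_gauss3d(as.numeric(arr), as.integer(dim(arr)),
                      as.numeric(sigmaVox), renorm)
  array(out, dim = dim(arr))
}

.logit <- function(p) log(p / (1 - p))
.sigmoid <- function(x) 1 / (1 + exp(-x))

# Logical index array from a BinaryMask.
.inMask <- function(mask) mask@values != 0L

.stopIfEmpty <- function(mask, what = mask@label) {
  if (sum(mask@values) == 0L)
    stop("mask '", what, "' is empty", call. = FALSE)
  invisible(TRUE)
}

# Sub-seed derivation for cohorts: deterministic, order-independent,
# kept below 2^31.
.subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %%
               2147483647)
}
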