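# Surrogate treatment planning: deliverable dose as a Gaussian point-spread
# convolution of a non-negative latent intensity field, fitted to the
# prescription by projected gradient descent under one-sided quadratic
# penalties for target coverage, OAR limits, and out-of-target falloff.
# This is a transparent stand-in for a clinical VMAT optimizer: it has no
# machine model, but preserves the structure of the planning problem
# (a smoothness-limited fit to a heterogeneous prescription under
# constraints).

.FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Optimize a deliverable dose plan against a prescription
#'
#' Finds a non-negative latent field \eqn{u} such that the delivered dose
#' \eqn{D = K u} (with \eqn{K} an isotropic Gaussian point-spread operator
#' of FWHM \code{psfFwhmMm}) minimizes a weighted sum of one-sided quadratic
#' penalties: squared deviation from the prescription inside the PTV
#' (\code{mode = "dose_painting"}) or from the uniform base dose
#' (\code{mode = "standard"}); under-dose penalties against the GTV/CTV/PTV
#' minimum-dose targets; an over-dose penalty against the PTV maximum;
#' per-OAR limit penalties; and a quadratic falloff penalty outside the PTV
#' beyond \code{falloffMarginMm}. In \code{standard} mode the GTV/CTV
#' minimum-dose boost targets collapse to the PTV coverage goal: a uniform
#' plan prescribes no boost. Optimization is projected gradient
#' descent with step halving on objective increase, so the objective trace
#' is non-increasing; if the relative objective change has not reached
#' \code{tol} at \code{maxIterations} the plan is returned with
#' \code{converged = FALSE} (not an error).
#'
#' @param rx a \linkS4class{DosePrescription}.
#' @param structures a \linkS4class{StructureSet}.
#' @param targets an \linkS4class{OptimizerTargets}.
#' @param constraints a \linkS4class{ConstraintSet}.
#' @param beam a \linkS4class{SurrogateBeamModel}.
#' @param mode \code{"dose_painting"} or \code{"standard"}.
#' @return A \linkS4class{DosePlan}.
#' @export
optimizePlan <- function(rx, structures, targets = OptimizerTargets(),
                         constraints = ConstraintSet(),
                         beam = SurrogateBeamModel(),
                         mode = c("dose_painting", "standard")) {
  mode <- match.arg(mode)
  stopifnot(is(rx, "DosePrescription"), is(structures, "StructureSet"))
  ptv <- getStructure(structures, "PTV")
  assertSameGrid(prescription = rx, PTV = ptv)
  .stopIfEmpty(ptv, "PTV")

  sp <- rx@spacing
  fullDim <- dim(rx@values)
  sigmaVox <- beam@psfFwhmMm * .FWHM_TO_SIGMA / sp

  inPtv <- .inMask(ptv)
  inCtv <- .inMask(getStructure(structures, "CTV"))
  inGtv <- .inMask(getStructure(structures, "GTV"))

  # crop to the PTV bounding box plus PSF support, falloff margin, and the
  # reach of any OAR present (penalties need their voxels in the box)
  padMm <- beam@falloffMarginMm + 3.5 * beam@psfFwhmMm * .FWHM_TO_SIGMA + 2
  boxMask <- inPtv
  oarRows <- constraints@limits[
    vapply(constraints@limits$structure, hasStructure, logical(1),
           x = structures), , drop = FALSE]
  for (s in oarRows$structure)
    boxMask <- boxMask | .inMask(getStructure(structures, s))
  rng <- lapply(1:3, function(a) {
    pres <- which(apply(boxMask, a, any))
    pad <- ceiling(padMm / sp[a])
    c(max(1L, min(pres) - pad), min(fullDim[a], max(pres) + pad))
  })
  ix <- seq(rng[[1]][1], rng[[1]][2])
  iy <- seq(rng[[2]][1], rng[[2]][2])
  iz <- seq(rng[[3]][1], rng[[3]][2])
  crop <- function(arr) arr[ix, iy, iz, drop = FALSE]

  cPtv <- crop(inPtv); cCtv <- crop(inCtv); cGtv <- crop(inGtv)
  target <- array(0, dim(cPtv))
  if (mode == "dose_painting") {
    target[cPtv] <- crop(rx@values)[cPtv]
  } else {
    target[cPtv] <- rx@dMinGy
    # a uniform plan has no boost: the GTV/CTV minimum-dose targets are
    # dose-painting goals and collapse to the PTV coverage goal here
    targets <- OptimizerTargets(gtvMinGy = targets@ptvMinGy,
                                ctvMinGy = targets@ptvMinGy,
                                ptvMinGy = targets@ptvMinGy,
                                ptvMaxGy = targets@ptvMaxGy)
  }

  # falloff region: outside the PTV, beyond the falloff margin
  distPtv <- .edt(cPtv, sp)
  cFall <- !cPtv & distPtv > beam@falloffMarginMm

  oarMasks <- lapply(oarRows$structure, function(s)
    crop(.inMask(getStructure(structures, s))))

  K <- function(arr) {
    if (beam@psfFwhmMm <= 0) return(arr)
    .cpp_gauss3d(as.numeric(arr), as.integer(dim(arr)),
                 as.numeric(sigmaVox), FALSE) |>
      array(dim = dim(arr))
  }

  wFit <- beam@weightFit; wTgt <- beam@weightTargets
  wOar <- beam@weightOar; wFall <- beam@weightFalloff

  objective <- function(d) {
    val <- wFit * sum((d[cPtv] - target[cPtv])^2) +
      wTgt * sum(pmax(0, targets@gtvMinGy - d[cGtv])^2) +
      wTgt * sum(pmax(0, targets@ctvMinGy - d[cCtv])^2) +
      wTgt * sum(pmax(0, targets@ptvMinGy - d[cPtv])^2) +
      wTgt * sum(pmax(0, d[cPtv] - targets@ptvMaxGy)^2) +
      wFall * sum(d[cFall]^2)
    for (k in seq_along(oarMasks)) {
      m <- oarMasks[[k]]
      if (!any(m)) next
      w <- wOar * oarRows$weight[k]
      lim <- oarRows$limit_gy[k]
      if (oarRows$metric[k] == "Dmax") {
        val <- val + w * sum(pmax(0, d[m] - lim)^2)
      } else {
        val <- val + w * sum(m) * max(0, mean(d[m]) - lim)^2
      }
    }
    val
  }

  gradDose <- function(d) {
    g <- array(0, dim(d))
    g[cPtv] <- g[cPtv] + 2 * wFit * (d[cPtv] - target[cPtv])
    g[cGtv] <- g[cGtv] - 2 * wTgt * pmax(0, targets@gtvMinGy - d[cGtv])
    g[cCtv] <- g[cCtv] - 2 * wTgt * pmax(0, targets@ctvMinGy - d[cCtv])
    g[cPtv] <- g[cPtv] - 2 * wTgt * pmax(0, targets@ptvMinGy - d[cPtv])
    g[cPtv] <- g[cPtv] + 2 * wTgt * pmax(0, d[cPtv] - targets@ptvMaxGy)
    g[cFall] <- g[cFall] + 2 * wFall * d[cFall]
    for (k in seq_along(oarMasks)) {
      m <- oarMasks[[k]]
      if (!any(m)) next
      w <- wOar * oarRows$weight[k]
      lim <- oarRows$limit_gy[k]
      if (oarRows$metric[k] == "Dmax") {
        g[m] <- g[m] + 2 * w * pmax(0, d[m] - lim)
      } else {
        g[m] <- g[m] + 2 * w * max(0, mean(d[m]) - lim)
      }
    }
    g
  }

  u <- target            # latent field initialized to the prescription
  d <- K(u)
  f <- objective(d)
  trace <- f
  eta <- beam@stepSize
  convergedFlag <- FALSE

  for (iter in seq_len(beam@maxIterations)) {
    if (f <= 0) { convergedFlag <- TRUE; break }
    gu <- K(gradDose(d))   # K is self-adjoint (zero-padded convolution)
    accepted <- FALSE
    for (h in 1:40) {
      u1 <- pmax(u - eta * gu, 0)  # pmax(x, 0) keeps the dim attribute
      d1 <- K(u1)
      f1 <- objective(d1)
      if (f1 <= f) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) { convergedFlag <- TRUE; break }  # at numerical floor
    rel <- (f - f1) / max(1, abs(f))
    u <- u1; d <- d1; f <- f1
    trace <- c(trace, f)
    eta <- eta * 1.1
    if (rel < beam@tol) { convergedFlag <- TRUE; break }
  }

  dose <- array(0, fullDim)
  dose[ix, iy, iz] <- d
  dose <- pmax(dose, 0)
  new("DosePlan", values = dose, spacing = sp, origin = rx@origin,
      converged = convergedFlag, objectiveTrace = trace)
}

#' Check OAR constraints against a plan
#'
#' Computes the achieved Dmax/Dmean for every constrained structure present
#' in the structure set and flags whether each limit is met.
#'
#' @param plan a \linkS4class{DosePlan}.
#' @param structures a \linkS4class{StructureSet}.
#' @param constraints a \linkS4class{ConstraintSet}.
#' @return data.frame with columns \code{structure}, \code{metric},
#'   \code{limit_gy}, \code{achieved_gy}, \code{pass}.
#' @export
checkConstraints <- function(plan, structures,
                             constraints = ConstraintSet()) {
  lim <- constraints@limits
  present <- vapply(lim$structure, hasStructure, logical(1), x = structures)
  lim <- lim[present, , drop = FALSE]
  achieved <- vapply(seq_len(nrow(lim)), function(k) {
    m <- .inMask(getStructure(structures, lim$structure[k]))
    v <- plan@values[m]
    if (!length(v)) return(NA_real_)
    if (lim$metric[k] == "Dmax") max(v) else mean(v)
  }, numeric(1))
  data.frame(structure = lim$structure, metric = lim$metric,
             limit_gy = lim$limit_gy, achieved_gy = achieved,
             pass = achieved < lim$limit_gy, row.names = NULL,
             stringsAsFactors = FALSE)
}
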