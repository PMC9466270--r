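# Dose-painting prescriptions: linear mapping from tumour probability to
# dose, the inverse prescription, and the uniform standard prescription.

#' Dose-painting prescription from a tumour-probability map
#'
#' Maps probability linearly to dose,
#' \code{D = dMin + (dMax - dMin) * p}, inside the CTV; the PTV ring
#' outside the CTV (the setup margin) is prescribed the base dose
#' \code{dMin}; voxels outside the PTV are NaN.
#'
#' @param p a \linkS4class{TumourProbabilityMap}.
#' @param structures a \linkS4class{StructureSet} with CTV and PTV.
#' @param params a \linkS4class{PrescriptionParams} (defaults 60--80 Gy).
#' @return A \linkS4class{DosePrescription}.
#' @export
dosePrescription <- function(p, structures, params = PrescriptionParams()) {
  ctv <- getStructure(structures, "CTV")
  ptv <- getStructure(structures, "PTV")
  assertSameGrid(probability = p, CTV = ctv, PTV = ptv)
  inCtv <- .inMask(ctv)
  inPtv <- .inMask(ptv)
  pv <- p@values[inCtv]
  if (anyNA(pv))
    stop("probability map is NaN inside the CTV", call. = FALSE)
  if (min(pv) < 0 || max(pv) > 1)
    stop("probability outside [0, 1]", call. = FALSE)
  dose <- array(NaN, dim(p@values))
  dose[inPtv] <- params@dMinGy
  dose[inCtv] <- params@dMinGy + (params@dMaxGy - params@dMinGy) * pv
  new("DosePrescription", values = dose, spacing = p@spacing,
      origin = p@origin, dMinGy = params@dMinGy, dMaxGy = params@dMaxGy)
}

#' Inverse dose prescription
#'
#' \code{Dinv = dMax - D} per voxel on the PTV (NaN outside). Used to coerce
#' treatment planning systems that cannot take a heterogeneous prescription
#' directly: the inverse map is assigned to a mock pretreated plan so that
#' optimizing the remainder to a uniform level paints the intended dose.
#' Applying the operation twice returns the original prescription.
#'
#' @param rx a \linkS4class{DosePrescription}.
#' @return A \linkS4class{ScalarVolume} of inverse dose in Gy.
#' @export
inversePrescription <- function(rx) {
  stopifnot(is(rx, "DosePrescription"))
  scalarVolume(rx@dMaxGy - rx@values, spacing = rx@spacing,
               origin = rx@origin)
}

#' Ideal plan delivering a prescription exactly
#'
#' Wraps a prescription as a \linkS4class{DosePlan} whose dose equals the
#' prescribed dose on the PTV and 0 outside. Useful as the identity
#' reference for conformity metrics (its quality factor against its own
#' prescription is exactly 100) and for evaluating prescriptions with the
#' TCP model before any optimization.
#'
#' @param rx a \linkS4class{DosePrescription}.
#' @return A \linkS4class{DosePlan}.
#' @export
idealPlan <- function(rx) {
  stopifnot(is(rx, "DosePrescription"))
  v <- rx@values
  v[is.nan(v)] <- 0
  new("DosePlan", values = v, spacing = rx@spacing, origin = rx@origin,
      converged = TRUE, objectiveTrace = 0)
}

#' Standard uniform prescription
#'
#' The standard-of-care plan: a uniform \code{dMin} (60 Gy by default)
#' prescribed over the whole PTV, NaN outside.
#'
#' @param structures a \linkS4class{StructureSet} with a non-empty PTV.
#' @param params a \linkS4class{PrescriptionParams}.
#' @return A \linkS4class{DosePrescription}.
#' @export
standardPrescription <- function(structures, params = PrescriptionParams()) {
  ptv <- getStructure(structures, "PTV")
  .stopIfEmpty(ptv, "PTV")
  dose <- array(NaN, dim(ptv@values))
  dose[.inMask(ptv)] <- params@dMinGy
  new("DosePrescription", values = dose, spacing = ptv@spacing,
      origin = ptv@origin, dMinGy = params@dMinGy, dMaxGy = params@dMaxGy)
}
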