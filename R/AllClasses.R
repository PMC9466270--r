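#' @useDynLib DosePaintR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# ---------------------------------------------------------------------------
# Grid-aligned volumes
# ---------------------------------------------------------------------------

#' ScalarVolume: a 3-D scalar field on a regular grid
#'
#' The basic container for every voxel map handled by the package: ADC and
#' rCBF parametric maps, tumour-probability maps, dose prescriptions and
#' planned dose distributions. Values live on a regular grid with per-axis
#' voxel spacing in mm and a physical origin at the centre of voxel
#' \code{(1,1,1)} (voxel-centre convention: the physical coordinate of voxel
#' \code{(i,j,k)} is \code{origin + (c(i,j,k) - 1) * spacing}).
#'
#' \code{NaN} values are permitted (they mark voxels outside a field of view
#' or outside a target structure); all arithmetic operations in the package
#' require explicit masking first.
#'
#' @slot values 3-D numeric array.
#' @slot spacing numeric(3), voxel size in mm, strictly positive.
#' @slot origin numeric(3), physical coordinate (mm) of the first voxel centre.
#'
#' @aliases ScalarVolume-class
#' @export ScalarVolume
#' @exportClass ScalarVolume
ScalarVolume <- setClass(
  "ScalarVolume",
  slots = c(values = "array", spacing = "numeric", origin = "numeric"),
  prototype = list(values = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
                   origin = c(0, 0, 0))
)

setValidity("ScalarVolume", function(object) {
  if (length(dim(object@values)) != 3L)
    return("'values' must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("'spacing' must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("'origin' must be 3 finite values (mm)")
  TRUE
})

#' BinaryMask: a \{0,1\} structure mask on a regular grid
#'
#' Masks share the grid conventions of \linkS4class{ScalarVolume}. Any
#' nonzero input value is coerced to 1, so masks are tolerant of upstream
#' encodings (e.g. label values > 1).
#'
#' @slot values 3-D integer array with values in \{0, 1\}.
#' @slot spacing,origin as in \linkS4class{ScalarVolume}.
#' @slot label structure name, e.g. \code{"GTV"}.
#'
#' @aliases BinaryMask-class
#' @export BinaryMask
#' @exportClass BinaryMask
BinaryMask <- setClass(
  "BinaryMask",
  slots = c(values = "array", spacing = "numeric", origin = "numeric",
            label = "character"),
  prototype = list(values = array(0L, c(1, 1, 1)), spacing = c(1, 1, 1),
                   origin = c(0, 0, 0), label = "mask")
)

setValidity("BinaryMask", function(object) {
  if (length(dim(object@values)) != 3L)
    return("'values' must be a 3-D array")
  v <- object@values
  if (anyNA(v)) return("mask values must not contain NA")
  if (!all(v == 0L | v == 1L)) return("mask values must be 0 or 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("'spacing' must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("'origin' must be 3 finite values (mm)")
  if (length(object@label) != 1L) return("'label' must be a single string")
  TRUE
})

#' Construct a ScalarVolume
#'
#' @param values 3-D numeric array.
#' @param spacing numeric(3) voxel size in mm (a scalar is recycled).
#' @param origin numeric(3) physical coordinate of the first voxel centre (mm).
#' @return A \linkS4class{ScalarVolume}.
#' @export
scalarVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(values) <- "double"
  new("ScalarVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a BinaryMask (nonzero values become 1)
#'
#' @param values 3-D array; any nonzero entry is treated as inside the mask.
#' @param spacing,origin grid metadata as in [scalarVolume()].
#' @param label structure name.
#' @return A \linkS4class{BinaryMask}.
#' @export
binaryMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       label = "mask") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  v <- array(as.integer(values != 0), dim = dim(values))
  new("BinaryMask", values = v, spacing = as.numeric(spacing),
      origin = as.numeric(origin), label = as.character(label))
}

# ---------------------------------------------------------------------------
# StructureSet
# ---------------------------------------------------------------------------

#' StructureSet: named masks on a shared grid
#'
#' Holds the radiotherapy structures for one case. The required names are
#' \code{GTV}, \code{CTV}, \code{PTV}, \code{brain} and \code{CSF}; organ-at-
#' risk masks (\code{brainstem}, \code{chiasm}, \code{optic_nerve_L/R},
#' \code{lens_L/R}, \code{retina_L/R}) are optional. Validity enforces a
#' shared grid, target nesting GTV \eqn{\subseteq} CTV \eqn{\subseteq} PTV,
#' and disjointness of CSF from the GTV.
#'
#' @slot masks named list of \linkS4class{BinaryMask}.
#'
#' @aliases StructureSet-class
#' @export StructureSet
#' @exportClass StructureSet
StructureSet <- setClass("StructureSet", slots = c(masks = "list"))

REQUIRED_STRUCTURES <- c("GTV", "CTV", "PTV", "brain", "CSF")
OAR_NAMES <- c("brainstem", "chiasm", "optic_nerve_L", "optic_nerve_R",
               "lens_L", "lens_R", "retina_L", "retina_R")

setValidity("StructureSet", function(object) {
  m <- object@masks
  if (length(m) == 0L) return("structure set must contain at least one mask")
  if (is.null(names(m)) || any(names(m) == ""))
    return("all masks must be named")
  if (!all(vapply(m, is, logical(1), "BinaryMask")))
    return("all elements of 'masks' must be BinaryMask objects")
  missing <- setdiff(REQUIRED_STRUCTURES, names(m))
  if (length(missing))
    return(paste("missing required structures:",
                 paste(missing, collapse = ", ")))
  ref <- m[[1]]
  for (nm in names(m)) {
    ok <- .gridsAgree(ref, m[[nm]])
    if (!isTRUE(ok))
      return(sprintf("grid mismatch between '%s' and '%s': %s",
                     names(m)[1], nm, ok))
  }
  gtv <- m$GTV@values; ctv <- m$CTV@values; ptv <- m$PTV@values
  if (any(gtv > ctv)) return("GTV is not contained in CTV")
  if (any(ctv > ptv)) return("CTV is not contained in PTV")
  if (any(gtv + m$CSF@values > 1L)) return("CSF overlaps the GTV")
  TRUE
})

#' Construct a StructureSet
#' @param masks named list of \linkS4class{BinaryMask} objects; must include
#'   GTV, CTV, PTV, brain and CSF.
#' @return A \linkS4class{StructureSet}.
#' @export
structureSet <- function(masks) new("StructureSet", masks = masks)

# ---------------------------------------------------------------------------
# Probability / dose volumes
# ---------------------------------------------------------------------------

#' TumourProbabilityMap: voxel-wise tumour probability within the CTV
#'
#' A \linkS4class{ScalarVolume} restricted to the clinical target volume:
#' probability 1 on the GTV, 0 on CSF, model-derived values in \[0,1\]
#' elsewhere inside the CTV, and \code{NaN} outside. The \code{provenance}
#' list records the model parameters and override counts.
#'
#' @slot provenance list with model parameters and override record.
#' @aliases TumourProbabilityMap-class
#' @exportClass TumourProbabilityMap
setClass("TumourProbabilityMap", contains = "ScalarVolume",
         slots = c(provenance = "list"))

#' DosePrescription: per-voxel prescribed dose in Gy on the PTV
#'
#' @slot dMinGy,dMaxGy prescription dose range (Gy).
#' @aliases DosePrescription-class
#' @exportClass DosePrescription
setClass("DosePrescription", contains = "ScalarVolume",
         slots = c(dMinGy = "numeric", dMaxGy = "numeric"))

setValidity("DosePrescription", function(object) {
  if (!(object@dMinGy > 0 && object@dMinGy <= object@dMaxGy))
    return("need 0 < dMinGy <= dMaxGy")
  v <- object@values[!is.nan(object@values)]
  if (length(v) && (min(v) < object@dMinGy - 1e-9 ||
                    max(v) > object@dMaxGy + 1e-9))
    return("prescribed dose outside [dMinGy, dMaxGy]")
  TRUE
})

#' DosePlan: a deliverable dose distribution in Gy
#'
#' Produced by the surrogate plan optimizer. Dose is finite and non-negative
#' everywhere on the grid; \code{objectiveTrace} records the optimizer's
#' objective value per iteration (non-increasing by construction).
#'
#' @slot converged logical flag.
#' @slot objectiveTrace numeric vector of objective values.
#' @aliases DosePlan-class
#' @exportClass DosePlan
setClass("DosePlan", contains = "ScalarVolume",
         slots = c(converged = "logical", objectiveTrace = "numeric"))

setValidity("DosePlan", function(object) {
  if (anyNA(object@values)) return("plan dose must be finite everywhere")
  if (min(object@values) < -1e-9) return("plan dose must be non-negative")
  tr <- object@objectiveTrace
  if (length(tr) > 1L && any(diff(tr) > 1e-9 * pmax(1, abs(tr[-length(tr)]))))
    return("objective trace must be non-increasing")
  TRUE
})

# ---------------------------------------------------------------------------
# Parameter objects
# ---------------------------------------------------------------------------

#' Infiltration model parameters
#'
#' Coefficients of the multiparametric MRI glioma-infiltration model: the
#' voxel-wise linear predictor is
#' \code{intercept + coefADC * ADC + coefRCBF * rCBF} on standardized inputs.
#' The published model was fitted by logistic regression, so the default
#' \code{link = "logistic"} maps the predictor through the logistic sigmoid;
#' \code{link = "clamped-linear"} instead clips the predictor to \[0,1\],
#' taking the printed linear formula literally.
#'
#' @param intercept,coefADC,coefRCBF model coefficients (defaults 1.64, 1.80,
#'   1.43).
#' @param link \code{"logistic"} or \code{"clamped-linear"}.
#' @return An \code{InfiltrationModelParams} object.
#' @aliases InfiltrationModelParams-class
#' @export
InfiltrationModelParams <- function(intercept = 1.64, coefADC = 1.80,
                                    coefRCBF = 1.43, link = "logistic") {
  new("InfiltrationModelParams", intercept = intercept, coefADC = coefADC,
      coefRCBF = coefRCBF, link = link)
}
setClass("InfiltrationModelParams",
         slots = c(intercept = "numeric", coefADC = "numeric",
                   coefRCBF = "numeric", link = "character"),
         prototype = list(intercept = 1.64, coefADC = 1.80, coefRCBF = 1.43,
                          link = "logistic"))
setValidity("InfiltrationModelParams", function(object) {
  if (!all(is.finite(c(object@intercept, object@coefADC, object@coefRCBF))))
    return("coefficients must be finite")
  if (!object@link %in% c("logistic", "clamped-linear"))
    return("link must be 'logistic' or 'clamped-linear'")
  TRUE
})

#' Dose-painting prescription parameters
#'
#' \code{dMinGy} (default 60 Gy) is the standard-of-care prescription and the
#' dose assigned at tumour probability 0; \code{dMaxGy} (default 80 Gy) is
#' the maximum boost dose, assigned at probability 1. \code{fractions} is
#' metadata only: all doses in the package are physical total dose.
#'
#' @param dMinGy,dMaxGy prescription dose range in Gy.
#' @param fractions number of daily fractions (metadata).
#' @return A \code{PrescriptionParams} object.
#' @aliases PrescriptionParams-class
#' @export
PrescriptionParams <- function(dMinGy = 60, dMaxGy = 80, fractions = 30L) {
  new("PrescriptionParams", dMinGy = dMinGy, dMaxGy = dMaxGy,
      fractions = as.integer(fractions))
}
setClass("PrescriptionParams",
         slots = c(dMinGy = "numeric", dMaxGy = "numeric",
                   fractions = "integer"),
         prototype = list(dMinGy = 60, dMaxGy = 80, fractions = 30L))
setValidity("PrescriptionParams", function(object) {
  if (!(object@dMinGy > 0 && object@dMinGy <= object@dMaxGy))
    return("need 0 < dMinGy <= dMaxGy")
  TRUE
})

#' Margin-expansion configuration
#'
#' Clinical margins: CTV = GTV + 1.5 cm (clipped to anatomical boundaries,
#' here the brain mask), PTV = CTV + 0.3 cm setup margin (not clipped).
#'
#' @param ctvMarginMm GTV-to-CTV margin in mm (default 15).
#' @param ptvMarginMm CTV-to-PTV margin in mm (default 3).
#' @return A \code{MarginConfig} object.
#' @aliases MarginConfig-class
#' @export
MarginConfig <- function(ctvMarginMm = 15, ptvMarginMm = 3) {
  new("MarginConfig", ctvMarginMm = ctvMarginMm, ptvMarginMm = ptvMarginMm)
}
setClass("MarginConfig",
         slots = c(ctvMarginMm = "numeric", ptvMarginMm = "numeric"),
         prototype = list(ctvMarginMm = 15, ptvMarginMm = 3))
setValidity("MarginConfig", function(object) {
  if (object@ctvMarginMm < 0 || object@ptvMarginMm < 0)
    return("margins must be >= 0")
  TRUE
})

#' Plan-optimizer dose targets
#'
#' Minimum-dose targets for GTV/CTV/PTV and the PTV maximum, defaulting to
#' the clinical planning goals 76.8, 61.2, 60.6 and 77.5 Gy used to drive a
#' dose-painting optimization between 60 and 80 Gy.
#'
#' @param gtvMinGy,ctvMinGy,ptvMinGy,ptvMaxGy dose targets in Gy.
#' @return An \code{OptimizerTargets} object.
#' @aliases OptimizerTargets-class
#' @export
OptimizerTargets <- function(gtvMinGy = 76.8, ctvMinGy = 61.2,
                             ptvMinGy = 60.6, ptvMaxGy = 77.5) {
  new("OptimizerTargets", gtvMinGy = gtvMinGy, ctvMinGy = ctvMinGy,
      ptvMinGy = ptvMinGy, ptvMaxGy = ptvMaxGy)
}
setClass("OptimizerTargets",
         slots = c(gtvMinGy = "numeric", ctvMinGy = "numeric",
                   ptvMinGy = "numeric", ptvMaxGy = "numeric"),
         prototype = list(gtvMinGy = 76.8, ctvMinGy = 61.2, ptvMinGy = 60.6,
                          ptvMaxGy = 77.5))
setValidity("OptimizerTargets", function(object) {
  ok <- object@ptvMinGy <= object@ctvMinGy &&
    object@ctvMinGy <= object@gtvMinGy && object@gtvMinGy <= object@ptvMaxGy
  if (!ok) return("need ptvMin <= ctvMin <= gtvMin <= ptvMax")
  TRUE
})

#' Organ-at-risk constraint set
#'
#' A table of per-structure dose limits with penalty weights. The defaults
#' follow EORTC-style limits for high-grade glioma planning: brain mean dose
#' < 45 Gy; maximum dose < 54 Gy for brainstem, chiasm and optic nerves,
#' < 10 Gy for lenses and < 50 Gy for retinas.
#'
#' @param limits data.frame with columns \code{structure}, \code{metric}
#'   (\code{"Dmax"} or \code{"Dmean"}), \code{limit_gy}, \code{weight}. The
#'   default table is used when omitted.
#' @return A \code{ConstraintSet} object.
#' @aliases ConstraintSet-class
#' @export
ConstraintSet <- function(limits = NULL) {
  if (is.null(limits)) limits <- .defaultOarLimits()
  if (is.null(limits$weight)) limits$weight <- 1
  new("ConstraintSet", limits = limits)
}
setClass("ConstraintSet", slots = c(limits = "data.frame"))
setValidity("ConstraintSet", function(object) {
  need <- c("structure", "metric", "limit_gy", "weight")
  if (!all(need %in% names(object@limits)))
    return(paste("limits must have columns:", paste(need, collapse = ", ")))
  if (any(object@limits$limit_gy <= 0)) return("limits must be positive")
  if (!all(object@limits$metric %in% c("Dmax", "Dmean")))
    return("metric must be 'Dmax' or 'Dmean'")
  TRUE
})

.defaultOarLimits <- function() {
  data.frame(
    structure = c("brain", "brainstem", "chiasm", "optic_nerve_L",
                  "optic_nerve_R", "lens_L", "lens_R", "retina_L",
                  "retina_R"),
    metric = c("Dmean", rep("Dmax", 8)),
    limit_gy = c(45, 54, 54, 54, 54, 10, 10, 50, 50),
    weight = 1,
    stringsAsFactors = FALSE
  )
}

#' Surrogate beam model and optimizer settings
#'
#' The deliverability surrogate: planned dose is the convolution of a
#' non-negative latent fluence-like field with an isotropic Gaussian point
#' spread function whose FWHM (default 5 mm, the leaf width of a typical
#' MLC) limits achievable dose gradients. Remaining fields control the
#' projected-gradient optimizer and the penalty weights of its objective.
#'
#' @param psfFwhmMm Gaussian PSF full width at half maximum, mm.
#' @param maxIterations iteration cap.
#' @param stepSize initial gradient step.
#' @param tol relative objective-change convergence tolerance.
#' @param weightFit,weightTargets,weightOar,weightFalloff penalty weights for
#'   the prescription-fit, min/max target, OAR, and out-of-target falloff
#'   terms.
#' @param falloffMarginMm distance beyond the PTV where the falloff penalty
#'   starts (default 10 mm).
#' @return A \code{SurrogateBeamModel} object.
#' @aliases SurrogateBeamModel-class
#' @export
SurrogateBeamModel <- function(psfFwhmMm = 5, maxIterations = 400L,
                               stepSize = 0.01, tol = 1e-6,
                               weightFit = 1, weightTargets = 10,
                               weightOar = 100, weightFalloff = 0.01,
                               falloffMarginMm = 10) {
  new("SurrogateBeamModel", psfFwhmMm = psfFwhmMm,
      maxIterations = as.integer(maxIterations), stepSize = stepSize,
      tol = tol, weightFit = weightFit, weightTargets = weightTargets,
      weightOar = weightOar, weightFalloff = weightFalloff,
      falloffMarginMm = falloffMarginMm)
}
setClass("SurrogateBeamModel",
         slots = c(psfFwhmMm = "numeric", maxIterations = "integer",
                   stepSize = "numeric", tol = "numeric",
                   weightFit = "numeric", weightTargets = "numeric",
                   weightOar = "numeric", weightFalloff = "numeric",
                   falloffMarginMm = "numeric"),
         prototype = list(psfFwhmMm = 5, maxIterations = 400L,
                          stepSize = 0.01, tol = 1e-6, weightFit = 1,
                          weightTargets = 10, weightOar = 100,
                          weightFalloff = 0.01, falloffMarginMm = 10))
setValidity("SurrogateBeamModel", function(object) {
  if (object@psfFwhmMm < 0) return("psfFwhmMm must be >= 0")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (object@stepSize <= 0 || object@tol <= 0)
    return("stepSize and tol must be > 0")
  TRUE
})

#' Tumour control probability parameters
#'
#' The TCP model is \code{TCP = exp(-C * sum_i p_i * exp(-alpha * D_i))}
#' over a target region, with intrinsic radiosensitivity
#' \code{alpha = 0.12} per Gy (from historical dose-escalation studies in
#' glioblastoma) and \code{C = 0.032} calibrated so the cohort-average CTV
#' TCP of standard 60 Gy plans matches the 27\% one-year progression-free
#' survival of standard of care.
#'
#' @param alphaPerGy radiosensitivity in 1/Gy.
#' @param cConstant calibration constant.
#' @return A \code{TCPParams} object.
#' @aliases TCPParams-class
#' @export
TCPParams <- function(alphaPerGy = 0.12, cConstant = 0.032) {
  new("TCPParams", alphaPerGy = alphaPerGy, cConstant = cConstant)
}
setClass("TCPParams",
         slots = c(alphaPerGy = "numeric", cConstant = "numeric"),
         prototype = list(alphaPerGy = 0.12, cConstant = 0.032))
setValidity("TCPParams", function(object) {
  if (object@alphaPerGy <= 0 || object@cConstant <= 0)
    return("alphaPerGy and cConstant must be > 0")
  TRUE
})

#' Phantom generator configuration
#'
#' Defines a synthetic head: a brain ellipsoid with a skull shell, two
#' ellipsoidal ventricles (CSF), a spherical GTV, simple geometric organs at
#' risk, and a ground-truth infiltration field decaying exponentially with
#' distance from the GTV surface. ADC/rCBF maps are constructed by inverting
#' the infiltration model so the phantom is self-consistent with the
#' analysis it feeds.
#'
#' @param gridShape voxel counts per axis (default 96^3).
#' @param spacingMm isotropic voxel size in mm (default 1.2).
#' @param brainSemiAxesMm brain ellipsoid semi-axes, mm.
#' @param gtvRadiusMm GTV sphere radius, mm (default 10).
#' @param gtvCentreOffsetMm GTV centre offset from the brain centre, mm.
#' @param infiltrationDecayMm exponential decay length of the infiltration
#'   field, mm (default 10).
#' @param noiseSd additive Gaussian noise sd on the standardized maps
#'   (default 0.1).
#' @param mixingFraction share of the linear predictor carried by the ADC
#'   term (default 0.5).
#' @param link link function used when inverting the infiltration model.
#' @param seed integer seed.
#' @return A \code{PhantomConfig} object.
#' @aliases PhantomConfig-class
#' @export
PhantomConfig <- function(gridShape = c(96L, 96L, 96L), spacingMm = 1.2,
                          brainSemiAxesMm = c(50, 62, 48), gtvRadiusMm = 10,
                          gtvCentreOffsetMm = c(20, 10, 5),
                          infiltrationDecayMm = 10, noiseSd = 0.1,
                          mixingFraction = 0.5, link = "logistic",
                          seed = 1L) {
  new("PhantomConfig", gridShape = as.integer(gridShape),
      spacingMm = spacingMm, brainSemiAxesMm = brainSemiAxesMm,
      gtvRadiusMm = gtvRadiusMm, gtvCentreOffsetMm = gtvCentreOffsetMm,
      infiltrationDecayMm = infiltrationDecayMm, noiseSd = noiseSd,
      mixingFraction = mixingFraction, link = link, seed = as.integer(seed))
}
setClass("PhantomConfig",
         slots = c(gridShape = "integer", spacingMm = "numeric",
                   brainSemiAxesMm = "numeric", gtvRadiusMm = "numeric",
                   gtvCentreOffsetMm = "numeric",
                   infiltrationDecayMm = "numeric", noiseSd = "numeric",
                   mixingFraction = "numeric", link = "character",
                   seed = "integer"),
         prototype = list(gridShape = c(96L, 96L, 96L), spacingMm = 1.2,
                          brainSemiAxesMm = c(50, 62, 48), gtvRadiusMm = 10,
                          gtvCentreOffsetMm = c(20, 10, 5),
                          infiltrationDecayMm = 10, noiseSd = 0.1,
                          mixingFraction = 0.5, link = "logistic",
                          seed = 1L))
setValidity("PhantomConfig", function(object) {
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@mixingFraction < 0 || object@mixingFraction > 1)
    return("mixingFraction must be in [0, 1]")
  if (object@gtvRadiusMm <= 0) return("gtvRadiusMm must be > 0")
  if (object@infiltrationDecayMm <= 0)
    return("infiltrationDecayMm must be > 0")
  if (!object@link %in% c("logistic", "clamped-linear"))
    return("link must be 'logistic' or 'clamped-linear'")
  # GTV must fit inside the brain ellipsoid
  u <- object@gtvCentreOffsetMm / object@brainSemiAxesMm
  rad <- sqrt(sum(u^2))
  # conservative: offset norm + radius along worst axis
  if (rad + object@gtvRadiusMm / min(object@brainSemiAxesMm) > 1)
    return("GTV does not fit inside the brain ellipsoid")
  TRUE
})

#' PhantomCase: one synthetic case
#'
#' @slot adc,rcbf standardized parametric maps (\linkS4class{ScalarVolume}).
#' @slot structures \linkS4class{StructureSet} with targets, brain, CSF, OARs.
#' @slot pTrue ground-truth infiltration probability in \[0,1\].
#' @slot fov field-of-view mask (axial slab around the GTV).
#' @slot seed generating seed.
#' @slot config the generating \code{PhantomConfig}.
#' @aliases PhantomCase-class
#' @exportClass PhantomCase
setClass("PhantomCase",
         slots = c(adc = "ScalarVolume", rcbf = "ScalarVolume",
                   structures = "StructureSet", pTrue = "ScalarVolume",
                   fov = "BinaryMask", seed = "integer",
                   config = "PhantomConfig"))

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@values)
  v <- object@values[!is.nan(object@values)]
  cat(sprintf("%s %dx%dx%d, spacing %.4g x %.4g x %.4g mm\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  if (length(v))
    cat(sprintf("  finite values: %d of %d, range [%.4g, %.4g]\n",
                length(v), prod(d), min(v), max(v)))
  else cat("  no finite values\n")
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask '%s' %dx%dx%d, spacing %.4g x %.4g x %.4g mm, %d voxels set\n",
              object@label, d[1], d[2], d[3], object@spacing[1],
              object@spacing[2], object@spacing[3], sum(object@values)))
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet with %d structures:\n", length(object@masks)))
  for (nm in names(object@masks))
    cat(sprintf("  %-14s %8d voxels (%.2f cm^3)\n", nm,
                sum(object@masks[[nm]]@values),
                sum(object@masks[[nm]]@values) *
                  prod(object@masks[[nm]]@spacing) / 1000))
})

setMethod("show", "DosePlan", function(object) {
  callNextMethod()
  cat(sprintf("  converged: %s after %d iterations\n", object@converged,
              length(object@objectiveTrace)))
})

setMethod("show", "PhantomCase", function(object) {
  d <- dim(object@adc@values)
  cat(sprintf("PhantomCase (seed %d): grid %dx%dx%d @ %.3g mm\n",
              object@seed, d[1], d[2], d[3], object@config@spacingMm))
  show(object@structures)
})
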