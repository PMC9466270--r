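# CTV/PTV construction by metric margin expansion with anatomical-barrier
# clipping.

#' Expand a mask by a metric margin
#'
#' Adds every voxel whose Euclidean distance (in physical mm, voxel-centre to
#' voxel-centre, anisotropy-aware) to the seed mask is at most
#' \code{marginMm}, then removes voxels inside the optional barrier. The
#' seed itself is always retained, so \code{seed} \eqn{\subseteq} output even
#' when seed voxels lie inside the barrier. The expansion is implemented
#' with an exact Euclidean distance transform followed by thresholding; the
#' barrier is a post-hoc clip, not a geodesic obstacle.
#'
#' @param seedMask non-empty \linkS4class{BinaryMask}.
#' @param marginMm margin in mm, \eqn{\ge 0}.
#' @param barrier optional \linkS4class{BinaryMask} of voxels the expansion
#'   may never enter (e.g. outside-brain for anatomical clipping).
#' @param label label for the output mask.
#' @return A \linkS4class{BinaryMask} on the same grid.
#' @export
expandMargin <- function(seedMask, marginMm, barrier = NULL,
                         label = seedMask@label) {
  stopifnot(is(seedMask, "BinaryMask"))
  .stopIfEmpty(seedMask, "seed")
  if (marginMm < 0) stop("marginMm must be >= 0", call. = FALSE)
  if (!is.null(barrier)) assertSameGrid(seed = seedMask, barrier = barrier)
  inSeed <- .inMask(seedMask)
  if (marginMm == 0) {
    out <- inSeed
  } else {
    dist <- .edt(inSeed, seedMask@spacing)
    out <- dist <= marginMm + 1e-9
  }
  if (!is.null(barrier)) out <- out & !.inMask(barrier)
  out <- out | inSeed
  binaryMask(out, spacing = seedMask@spacing, origin = seedMask@origin,
             label = label)
}

#' Build the clinical structure set from GTV, brain, CSF and OARs
#'
#' The clinical target volume (CTV) is the GTV expanded by
#' \code{ctvMarginMm} (default 1.5 cm) and clipped to the brain, which
#' stands in for the anatomical boundaries a clinician would respect. The
#' planning target volume (PTV) adds the setup margin \code{ptvMarginMm}
#' (default 0.3 cm) to the CTV and is deliberately not clipped to the brain:
#' the setup margin accounts for positioning uncertainty, not anatomy.
#'
#' @param gtv,brain,csf \linkS4class{BinaryMask} objects on one grid; the
#'   GTV must lie inside the brain.
#' @param oars optional named list of OAR \linkS4class{BinaryMask} objects.
#' @param margins a \linkS4class{MarginConfig}.
#' @return A \linkS4class{StructureSet} with GTV, CTV, PTV, brain, CSF and
#'   any OARs.
#' @export
buildStructureSet <- function(gtv, brain, csf, oars = list(),
                              margins = MarginConfig()) {
  assertSameGrid(c(list(GTV = gtv, brain = brain, CSF = csf), oars))
  .stopIfEmpty(gtv, "GTV")
  if (any(.inMask(gtv) & !.inMask(brain)))
    stop("GTV extends outside the brain mask", call. = FALSE)
  notBrain <- binaryMask(!.inMask(brain), spacing = brain@spacing,
                         origin = brain@origin, label = "outside_brain")
  ctv <- expandMargin(gtv, margins@ctvMarginMm, barrier = notBrain,
                      label = "CTV")
  ptv <- expandMargin(ctv, margins@ptvMarginMm, label = "PTV")
  # CSF may not claim GTV voxels (the GTV is residual tumour by definition)
  csfVals <- .inMask(csf) & !.inMask(gtv)
  csf <- binaryMask(csfVals, spacing = csf@spacing, origin = csf@origin,
                    label = "CSF")
  gtv@label <- "GTV"; brain@label <- "brain"
  masks <- c(list(GTV = gtv, CTV = ctv, PTV = ptv, brain = brain,
                  CSF = csf), oars)
  structureSet(masks)
}

#' Equivalent-sphere radius of a mask
#'
#' Radius (mm) of the sphere whose volume equals the mask's voxel volume;
#' used to verify margin geometry.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return Radius in mm.
#' @export
equivalentSphereRadiusMm <- function(mask) {
  vol <- sum(mask@values) * prod(mask@spacing)
  (3 * vol / (4 * pi))^(1 / 3)
}
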