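# Accessor generics for grid-aligned volumes and derived objects.

#' @name volume-accessors
#' @title Accessors for grid-aligned volumes
#' @description \code{volValues} returns the 3-D array of voxel values,
#'   \code{spacing} the per-axis voxel size in mm, \code{origin} the physical
#'   coordinate of the first voxel centre, \code{gridDim} the voxel counts,
#'   and \code{voxelVolumeMm3} the volume of one voxel in mm^3.
#'   \code{maskLabel} returns a mask's structure name.
#' @param x a \linkS4class{ScalarVolume} or \linkS4class{BinaryMask}.
#' @return See description; \code{volValues} returns an array, the others
#'   numeric vectors or scalars.
NULL

#' @rdname volume-accessors
#' @export
setGeneric("volValues", function(x) standardGeneric("volValues"))
#' @rdname volume-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname volume-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname volume-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname volume-accessors
#' @export
setGeneric("voxelVolumeMm3", function(x) standardGeneric("voxelVolumeMm3"))
#' @rdname volume-accessors
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))

#' @rdname volume-accessors
setMethod("volValues", "ScalarVolume", function(x) x@values)
#' @rdname volume-accessors
setMethod("volValues", "BinaryMask", function(x) x@values)
#' @rdname volume-accessors
setMethod("spacing", "ScalarVolume", function(x) x@spacing)
#' @rdname volume-accessors
setMethod("spacing", "BinaryMask", function(x) x@spacing)
#' @rdname volume-accessors
setMethod("origin", "ScalarVolume", function(x) x@origin)
#' @rdname volume-accessors
setMethod("origin", "BinaryMask", function(x) x@origin)
#' @rdname volume-accessors
setMethod("gridDim", "ScalarVolume", function(x) dim(x@values))
#' @rdname volume-accessors
setMethod("gridDim", "BinaryMask", function(x) dim(x@values))
#' @rdname volume-accessors
setMethod("voxelVolumeMm3", "ScalarVolume", function(x) prod(x@spacing))
#' @rdname volume-accessors
setMethod("voxelVolumeMm3", "BinaryMask", function(x) prod(x@spacing))
#' @rdname volume-accessors
setMethod("maskLabel", "BinaryMask", function(x) x@label)

#' @name structure-accessors
#' @title Accessors for structure sets
#' @param x a \linkS4class{StructureSet}.
#' @param name structure name, e.g. \code{"GTV"}.
#' @return \code{structureNames} returns a character vector;
#'   \code{getStructure} a \linkS4class{BinaryMask} (error if absent);
#'   \code{hasStructure} a logical.
NULL

#' @rdname structure-accessors
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))
#' @rdname structure-accessors
#' @export
setGeneric("getStructure", function(x, name) standardGeneric("getStructure"))
#' @rdname structure-accessors
#' @export
setGeneric("hasStructure", function(x, name) standardGeneric("hasStructure"))

#' @rdname structure-accessors
setMethod("structureNames", "StructureSet", function(x) names(x@masks))
#' @rdname structure-accessors
setMethod("getStructure", "StructureSet", function(x, name) {
  if (!name %in% names(x@masks))
    stop("no structure named '", name, "' in the set", call. = FALSE)
  x@masks[[name]]
})
#' @rdname structure-accessors
setMethod("hasStructure", "StructureSet",
          function(x, name) name %in% names(x@masks))

#' @name plan-accessors
#' @title Accessors for dose plans and prescriptions
#' @param x a \linkS4class{DosePlan} or \linkS4class{DosePrescription}.
#' @return \code{converged} a logical, \code{objectiveTrace} a numeric
#'   vector, \code{doseRangeGy} the prescription's \code{c(dMin, dMax)}.
NULL

#' @rdname plan-accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname plan-accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname plan-accessors
#' @export
setGeneric("doseRangeGy", function(x) standardGeneric("doseRangeGy"))

#' @rdname plan-accessors
setMethod("converged", "DosePlan", function(x) x@converged)
#' @rdname plan-accessors
setMethod("objectiveTrace", "DosePlan", function(x) x@objectiveTrace)
#' @rdname plan-accessors
setMethod("doseRangeGy", "DosePrescription",
          function(x) c(x@dMinGy, x@dMaxGy))
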