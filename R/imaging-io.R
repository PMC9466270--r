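# NIfTI I/O, grid-consistency checks, and metric-report serialization.

#' Read a 3-D scalar volume from a NIfTI file
#'
#' Spacing is taken from the header \code{pixdim} (mm) and the origin from
#' the sform/qform translation. Only single 3-D volumes are accepted.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return A \linkS4class{ScalarVolume}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
    attr(img2, "pixdim") <- attr(img, "pixdim")
    d <- d[1:3]
    vals <- img2
  } else if (length(d) != 3L) {
    stop("expected a single 3-D volume, got ", length(d), "-D data in ",
         path, call. = FALSE)
  } else {
    vals <- array(as.numeric(img), dim = d)
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-finite or non-positive voxel spacing in ", path,
         call. = FALSE)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  org <- as.numeric(aff[1:3, 4])
  scalarVolume(vals, spacing = sp, origin = org)
}

#' Write a ScalarVolume to a NIfTI file
#'
#' The header records the spacing in \code{pixdim} and the origin in the
#' sform (diagonal affine, voxel-centre convention).
#'
#' @param vol a \linkS4class{ScalarVolume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}); overwritten if
#'   present.
#' @param datatype NIfTI storage type; \code{"double"} is lossless for
#'   scalar maps, \code{"uint8"} suits masks.
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path, datatype = "double") {
  stopifnot(is(vol, "ScalarVolume") || is(vol, "BinaryMask"))
  arr <- vol@values
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol@spacing
  aff <- diag(c(vol@spacing, 1))
  aff[1:3, 4] <- vol@origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary mask from a NIfTI file
#'
#' Any nonzero voxel value is read as 1, so label maps and masks written
#' with other conventions are accepted.
#'
#' @param path path to a NIfTI file.
#' @param label structure name to attach.
#' @return A \linkS4class{BinaryMask}.
#' @export
readMask <- function(path, label = "mask") {
  vol <- readVolume(path)
  binaryMask(vol@values, spacing = vol@spacing, origin = vol@origin,
             label = label)
}

#' Write a BinaryMask to a NIfTI file (uint8)
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  writeVolume(mask, path, datatype = "uint8")
}

#' Assert that volumes and masks share one grid
#'
#' Shapes must be identical; spacings must agree within 1e-4 mm and origins
#' within 1e-3 mm. Every multi-volume operation in the package calls this
#' before doing arithmetic.
#'
#' @param ... volumes/masks, or a single list of them (optionally named for
#'   better error messages).
#' @return \code{TRUE} invisibly; stops with the offending pair otherwise.
#' @export
assertSameGrid <- function(...) {
  vols <- list(...)
  if (length(vols) == 1L && is.list(vols[[1]]) &&
      !is(vols[[1]], "ScalarVolume") && !is(vols[[1]], "BinaryMask"))
    vols <- vols[[1]]
  if (length(vols) == 0L) stop("no volumes given", call. = FALSE)
  nms <- names(vols)
  if (is.null(nms)) nms <- paste0("volume", seq_along(vols))
  nms[nms == ""] <- paste0("volume", which(nms == ""))
  for (i in seq_along(vols)[-1]) {
    ok <- .gridsAgree(vols[[1]], vols[[i]])
    if (!isTRUE(ok))
      stop(sprintf("grid mismatch between '%s' and '%s': %s", nms[1],
                   nms[i], ok), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a per-structure metric report as CSV with a JSON twin
#'
#' @param metrics data.frame with columns \code{plan}, \code{structure},
#'   \code{metric}, \code{value} and optionally \code{units} (filled with
#'   \code{""} if absent).
#' @param path output CSV path; a \code{.json} twin is written alongside.
#' @return The CSV path, invisibly.
#' @export
writeReport <- function(metrics, path) {
  cols <- c("plan", "structure", "metric", "value", "units")
  if (is.null(metrics$units)) metrics$units <- ""
  missing <- setdiff(setdiff(cols, "units"), names(metrics))
  if (length(missing))
    stop("metrics table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- metrics[, cols, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  jsonPath <- sub("\\.csv$", ".json", path)
  if (identical(jsonPath, path)) jsonPath <- paste0(path, ".json")
  jsonlite::write_json(out, jsonPath, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a DVH curve as CSV
#'
#' Columns are \code{structure}, \code{dose_Gy}, \code{volume_percent}.
#'
#' @param dvh a data.frame as returned by [dvhCurve()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeDvh <- function(dvh, path) {
  stopifnot(all(c("structure", "dose_Gy", "volume_percent") %in% names(dvh)))
  utils::write.csv(dvh[, c("structure", "dose_Gy", "volume_percent")], path,
                   row.names = FALSE)
  invisible(path)
}
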