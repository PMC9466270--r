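# Voxel-wise tumour-probability mapping from standardized ADC/rCBF maps.

#' Linear predictor of the infiltration model
#'
#' Evaluates \code{intercept + coefADC * adc + coefRCBF * rcbf} on
#' standardized inputs (default coefficients 1.64, 1.80, 1.43). Vectorized.
#'
#' @param adc,rcbf standardized ADC and rCBF values.
#' @param params an \linkS4class{InfiltrationModelParams}.
#' @return The linear predictor (unbounded).
#' @export
linearPredictor <- function(adc, rcbf, params = InfiltrationModelParams()) {
  if (any(!is.finite(adc)) || any(!is.finite(rcbf)))
    stop("non-finite input to the linear predictor", call. = FALSE)
  params@intercept + params@coefADC * adc + params@coefRCBF * rcbf
}

# Apply the configured link to a linear predictor.
.applyLink <- function(L, link) {
  switch(link,
         logistic = .sigmoid(L),
         `clamped-linear` = pmin(pmax(L, 0), 1),
         stop("unknown link: ", link, call. = FALSE))
}

#' Voxel-wise tumour-probability map
#'
#' Applies the infiltration model inside the CTV: the linear predictor of
#' the standardized ADC/rCBF values is mapped through the link function,
#' then the GTV is overridden to probability 1 (it is residual tumour by
#' definition) and CSF inside the CTV to 0 (the model was not validated
#' there). Voxels outside the CTV are NaN. CTV voxels where either input
#' map is NaN (outside the perfusion field of view) receive probability 0
#' unless a GTV/CSF override applies, with a warning: probability 0 maps to
#' the safe 60 Gy base prescription downstream.
#'
#' @param adc,rcbf standardized \linkS4class{ScalarVolume} maps.
#' @param structures a \linkS4class{StructureSet} with GTV, CTV, CSF.
#' @param params an \linkS4class{InfiltrationModelParams}.
#' @return A \linkS4class{TumourProbabilityMap}.
#' @export
tumourProbabilityMap <- function(adc, rcbf, structures,
                                 params = InfiltrationModelParams()) {
  stopifnot(is(structures, "StructureSet"))
  ctv <- getStructure(structures, "CTV")
  gtv <- getStructure(structures, "GTV")
  csf <- getStructure(structures, "CSF")
  assertSameGrid(adc = adc, rcbf = rcbf, CTV = ctv)
  .stopIfEmpty(ctv, "CTV")

  inCtv <- .inMask(ctv)
  inGtv <- .inMask(gtv)
  inCsf <- .inMask(csf) & inCtv

  a <- adc@values
  r <- rcbf@values
  missing <- inCtv & (is.na(a) | is.na(r))
  nMissing <- sum(missing & !inGtv & !inCsf)
  if (nMissing > 0)
    warning(nMissing, " CTV voxels lack ADC/rCBF coverage; assigned ",
            "probability 0 (base-dose prescription)", call. = FALSE)

  out <- array(NaN, dim(a))
  model <- inCtv & !missing
  out[model] <- .applyLink(
    linearPredictor(a[model], r[model], params), params@link)
  out[missing] <- 0
  out[inGtv] <- 1
  out[inCsf] <- 0

  new("TumourProbabilityMap",
      values = out, spacing = adc@spacing, origin = adc@origin,
      provenance = list(
        params = list(intercept = params@intercept,
                      coefADC = params@coefADC,
                      coefRCBF = params@coefRCBF, link = params@link),
        overrides = list(gtv_to_1 = sum(inGtv), csf_to_0 = sum(inCsf),
                         missing_to_0 = nMissing)))
}
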