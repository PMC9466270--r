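# End-to-end orchestration: simulate -> preprocess -> contour ->
# probability -> prescribe -> plan -> evaluate, for one case or a cohort,
# driven by a single serializable configuration.

#' Default run configuration
#'
#' A nested list mirroring every module's parameters, serializable to YAML
#' or JSON. Phantom ADC/rCBF maps are generated already standardized, so
#' the preprocessing stage defaults to field-of-view restriction only;
#' normalization, bilateral smoothing and standardization can be switched
#' on for externally supplied maps.
#'
#' @param seed global seed; all stage randomness derives from it.
#' @return A named list of stage configurations.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(gridShape = c(96L, 96L, 96L), spacingMm = 1.2,
                   brainSemiAxesMm = c(50, 62, 48), gtvRadiusMm = 10,
                   gtvCentreOffsetMm = c(20, 10, 5),
                   infiltrationDecayMm = 10, noiseSd = 0.1,
                   mixingFraction = 0.5, link = "logistic"),
    preprocess = list(restrictToFov = TRUE, normalize = FALSE,
                      smooth = FALSE, standardize = FALSE,
                      spatialSdMm = 2, rangeSd = 0.5),
    margins = list(ctvMarginMm = 15, ptvMarginMm = 3),
    model = list(intercept = 1.64, coefADC = 1.80, coefRCBF = 1.43,
                 link = "logistic"),
    prescription = list(dMinGy = 60, dMaxGy = 80, fractions = 30L),
    targets = list(gtvMinGy = 76.8, ctvMinGy = 61.2, ptvMinGy = 60.6,
                   ptvMaxGy = 77.5),
    beam = list(psfFwhmMm = 5, maxIterations = 400L, stepSize = 0.01,
                tol = 1e-6, weightFit = 1, weightTargets = 10,
                weightOar = 100, weightFalloff = 0.01,
                falloffMarginMm = 10),
    tcp = list(alphaPerGy = 0.12, cConstant = 0.032, targetTcp = 0.27)
  )
}

#' Read / write a run configuration
#'
#' YAML (\code{.yml}/\code{.yaml}) or JSON, chosen by extension. Values
#' missing from the file are filled from [defaultRunConfig()].
#'
#' @param path config file path.
#' @return \code{readRunConfig}: the configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- defaultRunConfig()
  for (k in names(base)) {
    if (is.null(cfg[[k]])) { cfg[[k]] <- base[[k]]; next }
    if (is.list(base[[k]]))
      for (kk in names(base[[k]]))
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- base[[k]][[kk]]
  }
  cfg
}

#' @rdname readRunConfig
#' @param config a configuration list.
#' @return \code{writeRunConfig}: the path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(config, path)
  else jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

# Instantiate the S4 parameter objects from a config list.
.configObjects <- function(config) {
  ph <- config$phantom
  list(
    phantom = PhantomConfig(gridShape = ph$gridShape,
                            spacingMm = ph$spacingMm,
                            brainSemiAxesMm = ph$brainSemiAxesMm,
                            gtvRadiusMm = ph$gtvRadiusMm,
                            gtvCentreOffsetMm = ph$gtvCentreOffsetMm,
                            infiltrationDecayMm = ph$infiltrationDecayMm,
                            noiseSd = ph$noiseSd,
                            mixingFraction = ph$mixingFraction,
                            link = ph$link, seed = config$seed),
    margins = do.call(MarginConfig, config$margins),
    model = do.call(InfiltrationModelParams, config$model),
    prescription = do.call(PrescriptionParams, config$prescription),
    targets = do.call(OptimizerTargets, config$targets),
    beam = do.call(SurrogateBeamModel, config$beam),
    tcp = TCPParams(alphaPerGy = config$tcp$alphaPerGy,
                    cConstant = config$tcp$cConstant)
  )
}

.stage <- function(name, verbose, expr) {
  t0 <- Sys.time()
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  if (verbose)
    message(sprintf("[%s] done in %.1f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full workflow for one case
#'
#' Executes simulate, preprocess, contour, probability, prescribe, plan
#' (both dose-painting and standard modes) and evaluate for a single
#' phantom case. If \code{outDir} is given, every stage's declared
#' artifacts (NIfTI volumes and masks, objective traces, DVH and metric
#' CSVs, the comparison report, and a config echo) are written there.
#'
#' @param config configuration list as from [defaultRunConfig()].
#' @param outDir optional output directory.
#' @param verbose log stage timings via \code{message()}.
#' @return A list with the phantom case, probability map, prescriptions,
#'   plans, constraint tables and the comparison report.
#' @export
runCase <- function(config = defaultRunConfig(), outDir = NULL,
                    verbose = TRUE) {
  obj <- .configObjects(config)

  case <- .stage("simulate", verbose, generatePhantom(obj$phantom))

  pp <- config$preprocess
  prep <- .stage("preprocess", verbose, {
    adc <- case@adc; rcbf <- case@rcbf
    if (isTRUE(pp$smooth)) {
      adc <- bilateralSmooth(adc, pp$spatialSdMm, pp$rangeSd)
      rcbf <- bilateralSmooth(rcbf, pp$spatialSdMm, pp$rangeSd)
    }
    if (isTRUE(pp$standardize)) {
      brain <- getStructure(case@structures, "brain")
      csf <- getStructure(case@structures, "CSF")
      zone <- binaryMask(.inMask(brain) & .inMask(case@fov) & !.inMask(csf),
                         spacing = brain@spacing, origin = brain@origin,
                         label = "standardization_zone")
      adc <- standardizeVolume(adc, zone)
      rcbf <- standardizeVolume(rcbf, zone)
    }
    if (isTRUE(pp$restrictToFov)) {
      adc <- restrictToFov(adc, case@fov)
      rcbf <- restrictToFov(rcbf, case@fov)
    }
    list(adc = adc, rcbf = rcbf)
  })

  structures <- .stage("contour", verbose, {
    s <- case@structures
    oars <- s@masks[setdiff(names(s@masks), REQUIRED_STRUCTURES)]
    buildStructureSet(gtv = getStructure(s, "GTV"),
                      brain = getStructure(s, "brain"),
                      csf = getStructure(s, "CSF"),
                      oars = oars, margins = obj$margins)
  })

  p <- .stage("probability", verbose,
              tumourProbabilityMap(prep$adc, prep$rcbf, structures,
                                   obj$model))

  rxDp <- .stage("prescribe", verbose,
                 dosePrescription(p, structures, obj$prescription))
  rxStd <- standardPrescription(structures, obj$prescription)
  rxInv <- inversePrescription(rxDp)

  constraints <- ConstraintSet()
  planDp <- .stage("plan_dose_painting", verbose,
                   optimizePlan(rxDp, structures, obj$targets, constraints,
                                obj$beam, mode = "dose_painting"))
  planStd <- .stage("plan_standard", verbose,
                    optimizePlan(rxStd, structures, obj$targets,
                                 constraints, obj$beam, mode = "standard"))

  evalRes <- .stage("evaluate", verbose, {
    list(comparison = comparePlans(planStd, planDp, rxStd, rxDp,
                                   structures, p, obj$tcp),
         constraintsDp = checkConstraints(planDp, structures, constraints),
         constraintsStd = checkConstraints(planStd, structures,
                                           constraints))
  })

  result <- list(config = config, case = case, adc = prep$adc,
                 rcbf = prep$rcbf, structures = structures, probability = p,
                 rxDp = rxDp, rxStd = rxStd, rxInv = rxInv,
                 planDp = planDp, planStd = planStd,
                 comparison = evalRes$comparison,
                 constraintsDp = evalRes$constraintsDp,
                 constraintsStd = evalRes$constraintsStd)

  if (!is.null(outDir)) .writeCaseArtifacts(result, outDir)
  result
}

.writeCaseArtifacts <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeRunConfig(result$config, file.path(outDir, "config.json"))
  writeVolume(result$adc, file.path(outDir, "adc.nii.gz"))
  writeVolume(result$rcbf, file.path(outDir, "rcbf.nii.gz"))
  writeVolume(result$probability, file.path(outDir, "probability.nii.gz"))
  writeVolume(result$rxDp, file.path(outDir, "prescription_dp.nii.gz"))
  writeVolume(result$rxInv,
              file.path(outDir, "prescription_inverse.nii.gz"))
  writeVolume(result$planDp, file.path(outDir, "plan_dp.nii.gz"))
  writeVolume(result$planStd, file.path(outDir, "plan_standard.nii.gz"))
  for (nm in structureNames(result$structures))
    writeMask(getStructure(result$structures, nm),
              file.path(outDir, paste0("mask_", nm, ".nii.gz")))
  utils::write.csv(
    data.frame(iteration = seq_along(objectiveTrace(result$planDp)),
               objective = objectiveTrace(result$planDp)),
    file.path(outDir, "objective_trace_dp.csv"), row.names = FALSE)
  utils::write.csv(result$comparison,
                   file.path(outDir, "comparison.csv"), row.names = FALSE)
  utils::write.csv(result$constraintsDp,
                   file.path(outDir, "constraints_dp.csv"),
                   row.names = FALSE)
  utils::write.csv(result$constraintsStd,
                   file.path(outDir, "constraints_standard.csv"),
                   row.names = FALSE)
  for (s in c("GTV", "CTV", "PTV")) {
    region <- getStructure(result$structures, s)
    writeDvh(dvhCurve(result$planDp, region, structure = s),
             file.path(outDir, paste0("dvh_dp_", s, ".csv")))
    writeDvh(dvhCurve(result$planStd, region, structure = s),
             file.path(outDir, paste0("dvh_standard_", s, ".csv")))
  }
  invisible(outDir)
}

#' Run a phantom cohort and summarize
#'
#' Generates \code{nCases} jittered phantom cases, runs the full per-case
#' workflow, recalibrates the TCP constant on the cohort's standard plans
#' (so the mean standard CTV TCP matches the configured survival target),
#' and tabulates cohort means, standard deviations and Wilcoxon
#' matched-pairs signed-rank p-values per (structure, metric).
#'
#' @param config configuration list.
#' @param nCases number of cases; below 3 the Wilcoxon statistics are
#'   skipped with a warning.
#' @param outDir optional output directory (per-case subdirectories plus
#'   cohort summary).
#' @param verbose log progress.
#' @return list with \code{cases} (per-case results), \code{summary}
#'   (cohort table), \code{calibratedC} and \code{perCase} (long table of
#'   per-case metric values).
#' @export
runCohort <- function(config = defaultRunConfig(), nCases = 5,
                      outDir = NULL, verbose = TRUE) {
  if (nCases < 1) stop("nCases must be >= 1", call. = FALSE)
  doStats <- nCases >= 3
  if (!doStats)
    warning("nCases < 3: Wilcoxon statistics skipped", call. = FALSE)

  baseObj <- .configObjects(config)
  results <- vector("list", nCases)
  for (i in seq_len(nCases)) {
    if (verbose) message(sprintf("=== case %d of %d ===", i, nCases))
    caseCfg <- .cohortCaseConfig(baseObj$phantom, config$seed, i)
    cfg <- config
    cfg$seed <- caseCfg@seed
    cfg$phantom$gtvRadiusMm <- caseCfg@gtvRadiusMm
    cfg$phantom$gtvCentreOffsetMm <- caseCfg@gtvCentreOffsetMm
    results[[i]] <- runCase(
      cfg, outDir = if (is.null(outDir)) NULL
      else file.path(outDir, sprintf("case_%03d", i)),
      verbose = verbose)
  }

  # recalibrate C on the cohort's standard plans over the CTV
  calCohort <- lapply(results, function(r)
    list(p = r$probability, plan = r$planStd,
         region = getStructure(r$structures, "CTV")))
  cHat <- calibrateC(calCohort, alphaPerGy = config$tcp$alphaPerGy,
                     targetTcp = config$tcp$targetTcp)
  tcpPar <- TCPParams(alphaPerGy = config$tcp$alphaPerGy, cConstant = cHat)

  perCase <- do.call(rbind, lapply(seq_len(nCases), function(i) {
    r <- results[[i]]
    cmp <- comparePlans(r$planStd, r$planDp, r$rxStd, r$rxDp,
                        r$structures, r$probability, tcpPar)
    cmp$case <- i
    cmp
  }))

  keys <- unique(perCase[, c("structure", "metric", "units")])
  summary <- do.call(rbind, lapply(seq_len(nrow(keys)), function(k) {
    sel <- perCase$structure == keys$structure[k] &
      perCase$metric == keys$metric[k]
    a <- perCase$standard[sel]
    b <- perCase$dose_painting[sel]
    pval <- NA_real_
    if (doStats) pval <- pairedWilcoxon(b, a)$p_value
    data.frame(structure = keys$structure[k], metric = keys$metric[k],
               standard_mean = mean(a), standard_sd = stats::sd(a),
               dp_mean = mean(b), dp_sd = stats::sd(b),
               p_value = pval, units = keys$units[k],
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(outDir, "cohort_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(perCase, file.path(outDir, "cohort_per_case.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(calibrated_C = cHat),
                         file.path(outDir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cases = results, summary = summary, calibratedC = cHat,
       perCase = perCase)
}
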