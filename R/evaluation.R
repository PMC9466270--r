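# Plan evaluation: quality factor, DVH and dose-volume metrics, tumour
# control probability with cohort calibration, and paired nonparametric
# comparison.

#' Quality factor of a plan against its prescription
#'
#' \code{QF = 100 - (100/n) * sum_i |D_plan,i - D_rx,i| / D_rx,i} over the
#' region's voxels: 100 minus the mean per-voxel absolute relative
#' deviation, in percent. An ideal plan scores exactly 100. The per-voxel
#' map \code{100 * (1 - |relative deviation|)} is returned alongside.
#'
#' The relative-deviation mean carries the factor 100 so that QF is on the
#' percent scale on which the ideal plan scores 100, consistent with the
#' dose-painting conformity literature.
#'
#' @param plan a \linkS4class{DosePlan} (or any ScalarVolume of dose).
#' @param rx a \linkS4class{DosePrescription}.
#' @param region a non-empty \linkS4class{BinaryMask}; the prescription
#'   must be positive there.
#' @return list with \code{qf_percent}, \code{qf_map}
#'   (\linkS4class{ScalarVolume}, NaN outside the region) and \code{n}.
#' @export
qualityFactor <- function(plan, rx, region) {
  assertSameGrid(plan = plan, prescription = rx, region = region)
  .stopIfEmpty(region, "evaluation region")
  idx <- .inMask(region)
  dp <- plan@values[idx]
  dr <- rx@values[idx]
  if (anyNA(dr) || anyNA(dp))
    stop("NaN dose inside the evaluation region", call. = FALSE)
  if (any(dr <= 0))
    stop("prescription must be positive over the evaluation region",
         call. = FALSE)
  relDev <- abs(dp - dr) / dr
  qfMapArr <- array(NaN, dim(plan@values))
  qfMapArr[idx] <- 100 * (1 - relDev)
  list(qf_percent = 100 - 100 * mean(relDev),
       qf_map = scalarVolume(qfMapArr, spacing = plan@spacing,
                             origin = plan@origin),
       n = length(dp))
}

#' Cumulative dose-volume histogram
#'
#' \code{V(d)} = fraction of the region receiving at least dose \code{d},
#' tabulated on a uniform dose grid from 0 to just above the region
#' maximum. \code{V(0) = 1} and the curve is non-increasing.
#'
#' @param plan dose volume.
#' @param region non-empty \linkS4class{BinaryMask}.
#' @param binWidthGy dose bin width (default 0.1 Gy).
#' @param structure structure name recorded in the output.
#' @return data.frame with \code{structure}, \code{dose_Gy},
#'   \code{volume_percent}.
#' @export
dvhCurve <- function(plan, region, binWidthGy = 0.1,
                     structure = region@label) {
  assertSameGrid(plan = plan, region = region)
  .stopIfEmpty(region, "DVH region")
  v <- plan@values[.inMask(region)]
  if (anyNA(v)) stop("NaN dose inside the DVH region", call. = FALSE)
  edges <- seq(0, max(v) + binWidthGy, by = binWidthGy)
  frac <- vapply(edges, function(d) mean(v >= d), numeric(1))
  data.frame(structure = structure, dose_Gy = edges,
             volume_percent = 100 * frac, stringsAsFactors = FALSE)
}

# Parse a metric label into a closure over the voxel doses.
.metricFun <- function(label) {
  if (label %in% c("Dmean", "Dmax", "Dmin"))
    return(switch(label, Dmean = mean, Dmax = max, Dmin = min))
  m <- regmatches(label, regexec("^D([0-9.]+)%$", label))[[1]]
  if (length(m) == 2) {
    x <- as.numeric(m[2])
    # dose received by at least x% of the volume: the (100-x)th percentile
    return(function(v) unname(stats::quantile(v, probs = (100 - x) / 100,
                                              type = 7)))
  }
  m <- regmatches(label, regexec("^V([0-9.]+)Gy$", label))[[1]]
  if (length(m) == 2) {
    x <- as.numeric(m[2])
    return(function(v) 100 * mean(v >= x))
  }
  stop("unknown metric label: ", label, call. = FALSE)
}

#' Dose-volume metrics over a region
#'
#' Supports \code{Dmean}, \code{Dmax}, \code{Dmin}; \code{Dx\%} (dose
#' received by at least x\% of the volume, the (100\eqn{-}x)th percentile
#' of voxel doses with linear interpolation between order statistics); and
#' \code{VxGy} (percent of volume receiving at least x Gy).
#'
#' @param plan dose volume.
#' @param region non-empty \linkS4class{BinaryMask}.
#' @param metrics character vector of metric labels.
#' @return data.frame with \code{metric}, \code{value}, \code{units}.
#' @export
doseMetrics <- function(plan, region,
                        metrics = c("Dmean", "Dmin", "Dmax", "D98%",
                                    "V60Gy", "V76Gy", "V80Gy")) {
  assertSameGrid(plan = plan, region = region)
  .stopIfEmpty(region, "metric region")
  v <- plan@values[.inMask(region)]
  if (anyNA(v)) stop("NaN dose inside the metric region", call. = FALSE)
  vals <- vapply(metrics, function(lab) .metricFun(lab)(v), numeric(1))
  units <- ifelse(grepl("^V", metrics), "%", "Gy")
  data.frame(metric = metrics, value = unname(vals), units = units,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tumour control probability
#'
#' Poisson-type model \code{TCP = exp(-C * sum_i p_i * exp(-alpha * D_i))}
#' over the region, where \code{p_i} is the tumour probability and
#' \code{D_i} the dose at voxel \code{i}. By default \code{D_i} is the
#' planned (delivered) dose; pass a \linkS4class{DosePrescription} to
#' evaluate the model on prescribed dose instead.
#'
#' @param p a \linkS4class{TumourProbabilityMap} (or probability volume).
#' @param plan dose volume (plan or prescription).
#' @param region non-empty \linkS4class{BinaryMask}, inside the CTV so that
#'   probabilities are defined.
#' @param params a \linkS4class{TCPParams}.
#' @return TCP in (0, 1].
#' @export
tcp <- function(p, plan, region, params = TCPParams()) {
  assertSameGrid(probability = p, dose = plan, region = region)
  .stopIfEmpty(region, "TCP region")
  idx <- .inMask(region)
  pv <- p@values[idx]
  dv <- plan@values[idx]
  if (anyNA(pv) || anyNA(dv))
    stop("NaN probability or dose inside the TCP region", call. = FALSE)
  exp(-params@cConstant * sum(pv * exp(-params@alphaPerGy * dv)))
}

#' Calibrate the TCP constant C against a survival target
#'
#' Finds \code{C} such that the cohort-mean CTV TCP of the standard plans
#' equals \code{targetTcp} (default 0.27, the one-year progression-free
#' survival of standard of care). Mean TCP is continuous and strictly
#' decreasing in \code{C}, so bisection on \code{log C} converges; the
#' bracket is \code{C} in \code{[1e-8, 1e3]}.
#'
#' @param cohort list of cases, each a list with elements \code{p}
#'   (probability map), \code{plan} (dose volume) and \code{region} (CTV
#'   mask).
#' @param alphaPerGy radiosensitivity (default 0.12 / Gy).
#' @param targetTcp target mean TCP in (0, 1).
#' @param tol tolerance on the achieved mean TCP (default 1e-6).
#' @return The calibrated \code{C}.
#' @export
calibrateC <- function(cohort, alphaPerGy = 0.12, targetTcp = 0.27,
                       tol = 1e-6) {
  if (length(cohort) == 0) stop("empty cohort", call. = FALSE)
  if (targetTcp <= 0 || targetTcp >= 1)
    stop("targetTcp must be in (0, 1)", call. = FALSE)
  # exponent sums are fixed; TCP_k(C) = exp(-C * S_k)
  S <- vapply(cohort, function(cs) {
    idx <- .inMask(cs$region)
    pv <- cs$p@values[idx]
    dv <- cs$plan@values[idx]
    if (anyNA(pv) || anyNA(dv))
      stop("NaN probability or dose inside a CTV", call. = FALSE)
    sum(pv * exp(-alphaPerGy * dv))
  }, numeric(1))
  meanTcp <- function(logC) mean(exp(-exp(logC) * S))
  lo <- log(1e-8); hi <- log(1e3)
  if (meanTcp(lo) < targetTcp || meanTcp(hi) > targetTcp)
    stop("target TCP not bracketed by C in [1e-8, 1e3]", call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (meanTcp(mid) > targetTcp) lo <- mid else hi <- mid
    if (abs(meanTcp(mid) - targetTcp) < tol) break
  }
  exp((lo + hi) / 2)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided test on paired differences. Zero differences are dropped; with
#' \code{n <= 25} remaining pairs and untied absolute differences the exact
#' signed-rank null distribution is used, otherwise the normal
#' approximation with tie correction. If every difference is zero the
#' result is flagged degenerate with \code{p = 1}.
#'
#' @param valuesA,valuesB paired per-case metric values (equal length
#'   \eqn{\ge 3}).
#' @return list with \code{statistic} (signed-rank sum V of positive
#'   ranks), \code{p_value}, \code{n_nonzero}, \code{degenerate},
#'   \code{method}.
#' @export
pairedWilcoxon <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(valuesA) < 3)
    stop("need at least 3 pairs", call. = FALSE)
  d <- valuesA - valuesB
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, n_nonzero = 0L,
                degenerate = TRUE, method = "degenerate"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  hasTies <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !hasTies) {
    # exact two-sided p from the signed-rank null distribution
    pLower <- stats::psignrank(V, n)
    pUpper <- stats::psignrank(V - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(pLower, pUpper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tieTab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tieTab^3 - tieTab) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = V, p_value = p, n_nonzero = as.integer(n),
       degenerate = FALSE, method = method)
}

# Metric schema used for plan comparison: per structure, the dose metrics
# of a typical planning-study report plus QF and TCP where defined.
.comparisonMetrics <- function()
  c("QF", "Dmean", "Dmin", "Dmax", "D98%", "V60Gy", "V76Gy", "V80Gy", "TCP")

#' Compare a standard and a dose-painting plan
#'
#' Builds a per-structure table of QF, Dmean, Dmin, Dmax, D98\%, V60Gy,
#' V76Gy, V80Gy and (for GTV and CTV) TCP for both plans, plus the
#' dose-painting minus standard difference. QF for each plan is computed
#' against that plan's own prescription.
#'
#' @param standardPlan,dpPlan \linkS4class{DosePlan} objects on one grid.
#' @param standardRx,dpRx the corresponding prescriptions.
#' @param structures a \linkS4class{StructureSet}.
#' @param p a \linkS4class{TumourProbabilityMap} for the TCP terms.
#' @param tcpParams a \linkS4class{TCPParams}.
#' @param targetStructures structures to evaluate (default GTV, CTV, PTV).
#' @return data.frame with columns \code{structure}, \code{metric},
#'   \code{standard}, \code{dose_painting}, \code{difference}, \code{units}.
#' @export
comparePlans <- function(standardPlan, dpPlan, standardRx, dpRx, structures,
                         p, tcpParams = TCPParams(),
                         targetStructures = c("GTV", "CTV", "PTV")) {
  assertSameGrid(standard = standardPlan, dose_painting = dpPlan)
  rows <- list()
  for (s in targetStructures) {
    region <- getStructure(structures, s)
    met <- setdiff(.comparisonMetrics(), c("QF", "TCP"))
    tabS <- doseMetrics(standardPlan, region, met)
    tabD <- doseMetrics(dpPlan, region, met)
    qfS <- qualityFactor(standardPlan, standardRx, region)$qf_percent
    qfD <- qualityFactor(dpPlan, dpRx, region)$qf_percent
    vals <- data.frame(
      structure = s,
      metric = c("QF", met),
      standard = c(qfS, tabS$value),
      dose_painting = c(qfD, tabD$value),
      units = c("%", tabS$units),
      stringsAsFactors = FALSE)
    if (s %in% c("GTV", "CTV")) {
      tS <- tcp(p, standardPlan, region, tcpParams)
      tD <- tcp(p, dpPlan, region, tcpParams)
      vals <- rbind(vals, data.frame(structure = s, metric = "TCP",
                                     standard = tS, dose_painting = tD,
                                     units = "probability",
                                     stringsAsFactors = FALSE))
    }
    rows[[s]] <- vals
  }
  out <- do.call(rbind, rows)
  out$difference <- out$dose_painting - out$standard
  rownames(out) <- NULL
  out[, c("structure", "metric", "standard", "dose_painting", "difference",
          "units")]
}
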