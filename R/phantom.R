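# Synthetic phantom cases: brain ellipsoid with skull shell, ventricular
# CSF, spherical GTV, geometric OARs, a ground-truth infiltration field, and
# ADC/rCBF maps constructed by inverting the infiltration model.

# Run expr with a fixed seed, restoring the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Coordinate arrays (mm) for a grid centred on the origin.
.gridCoords <- function(shape, spacingMm) {
  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - (shape[a] + 1) / 2) *
                 spacingMm)
  list(
    x = array(ax[[1]], shape),
    y = array(rep(ax[[2]], each = shape[1]), shape),
    z = array(rep(ax[[3]], each = shape[1] * shape[2]), shape),
    origin = vapply(ax, `[`, numeric(1), 1)
  )
}

.ellipsoid <- function(co, centre, semi) {
  ((co$x - centre[1]) / semi[1])^2 + ((co$y - centre[2]) / semi[2])^2 +
    ((co$z - centre[3]) / semi[3])^2 <= 1
}

.sphere <- function(co, centre, r) .ellipsoid(co, centre, rep(r, 3))

# Cylinder along one axis between ends a..b (mm), radius r in the
# perpendicular plane.
.cylinder <- function(co, axis, centrePerp, r, range) {
  perp <- setdiff(c("x", "y", "z"), axis)
  inPlane <- (co[[perp[1]]] - centrePerp[1])^2 +
    (co[[perp[2]]] - centrePerp[2])^2 <= r^2
  inPlane & co[[axis]] >= range[1] & co[[axis]] <= range[2]
}

.box <- function(co, centre, halfSize) {
  abs(co$x - centre[1]) <= halfSize[1] &
    abs(co$y - centre[2]) <= halfSize[2] &
    abs(co$z - centre[3]) <= halfSize[3]
}

# Probability clamp bounds: keeps the logistic inverse finite so the
# zero-noise model-inversion roundtrip is exact to floating point.
.PROB_EPS <- 1e-5

#' Generate a synthetic phantom case
#'
#' Builds a head phantom on a grid centred at the physical origin: a brain
#' ellipsoid surrounded by a thin skull shell, two ellipsoidal ventricles
#' labelled CSF, a spherical GTV, and geometric organs at risk (brainstem
#' cylinder, chiasm box, optic-nerve cylinders, lens and retina spheres),
#' all pairwise disjoint and disjoint from the GTV. The field of view is an
#' axial slab covering the GTV plus/minus 30 mm, mimicking the restricted
#' coverage of a perfusion acquisition.
#'
#' The ground-truth infiltration probability decays exponentially with
#' Euclidean distance \eqn{d} from the GTV surface,
#' \eqn{p(x) = \exp(-d(x)/\lambda)\,(1 + \epsilon(x))} with a smooth
#' perturbation \eqn{\epsilon} (Gaussian-filtered white noise, kernel sd
#' 6 mm, amplitude 0.15) for spatial heterogeneity, clamped to
#' \eqn{[10^{-5}, 1-10^{-5}]} so the link inverse stays finite; the GTV is
#' then set to exactly 1 and CSF to exactly 0. Standardized ADC and rCBF
#' maps are built by inverting the infiltration model: the noiseless linear
#' predictor \eqn{L = \mathrm{link}^{-1}(p)} is split between the two maps
#' by \code{mixingFraction}, and independent Gaussian noise of sd
#' \code{noiseSd} is added per voxel. With \code{noiseSd = 0}, applying the
#' infiltration model to the phantom maps reproduces \code{pTrue} exactly
#' away from the GTV/CSF overrides.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return A \linkS4class{PhantomCase}.
#' @export
generatePhantom <- function(config = PhantomConfig()) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  shape <- config@gridShape
  sp <- rep(config@spacingMm, 3)
  co <- .gridCoords(shape, config@spacingMm)
  origin <- co$origin

  mk <- function(arr, label) binaryMask(arr, spacing = sp, origin = origin,
                                        label = label)

  brainArr <- .ellipsoid(co, c(0, 0, 0), config@brainSemiAxesMm)
  skullArr <- .ellipsoid(co, c(0, 0, 0), config@brainSemiAxesMm + 5) &
    !.ellipsoid(co, c(0, 0, 0), config@brainSemiAxesMm + 1)
  gtvArr <- .sphere(co, config@gtvCentreOffsetMm, config@gtvRadiusMm)
  if (any(gtvArr & !brainArr))
    stop("GTV is not contained in the brain ellipsoid", call. = FALSE)
  if (!any(gtvArr))
    stop("GTV contains no voxels at this grid resolution", call. = FALSE)

  # ventricles: two ellipsoids, posterior and medial to the default GTV
  csfArr <- (.ellipsoid(co, c(-14, -20, 0), c(6, 14, 8)) |
               .ellipsoid(co, c(14, -20, 0), c(6, 14, 8))) & brainArr
  csfArr <- csfArr & !gtvArr

  # organs at risk: disjoint geometric solids, kept clear of the GTV
  oarArr <- list(
    brainstem = .cylinder(co, "z", c(0, -15), 7, c(-44, -16)),
    chiasm = .box(co, c(0, 5, -18), c(6, 4, 2)),
    optic_nerve_L = .cylinder(co, "y", c(-10, -18), 2, c(15, 40)),
    optic_nerve_R = .cylinder(co, "y", c(10, -18), 2, c(15, 40)),
    retina_L = .sphere(co, c(-16, 46, -16), 5),
    retina_R = .sphere(co, c(16, 46, -16), 5),
    lens_L = .sphere(co, c(-16, 54, -16), 2.5),
    lens_R = .sphere(co, c(16, 54, -16), 2.5)
  )
  taken <- gtvArr | csfArr
  for (nm in names(oarArr)) {
    oarArr[[nm]] <- oarArr[[nm]] & !taken
    taken <- taken | oarArr[[nm]]
  }
  oars <- Map(mk, oarArr, names(oarArr))

  # field of view: axial slab covering the GTV +/- 30 mm
  zRange <- range(co$z[gtvArr])
  fovArr <- co$z >= zRange[1] - 30 & co$z <= zRange[2] + 30
  fov <- mk(fovArr, "FOV")

  # ground-truth infiltration field
  dist <- .edt(gtvArr, sp)
  out <- .withSeed(config@seed, {
    white <- array(stats::rnorm(prod(shape)), shape)
    pert <- .gaussBlur(white, 6, sp)
    pert <- pert / stats::sd(pert[brainArr])
    q <- exp(-dist / config@infiltrationDecayMm) * (1 + 0.15 * pert)
    q <- pmin(pmax(q, .PROB_EPS), 1 - .PROB_EPS)

    linkInv <- switch(config@link, logistic = .logit,
                      `clamped-linear` = identity)
    params <- InfiltrationModelParams(link = config@link)
    L <- linkInv(q)
    adcArr <- config@mixingFraction * (L - params@intercept) /
      params@coefADC
    rcbfArr <- (1 - config@mixingFraction) * (L - params@intercept) /
      params@coefRCBF
    if (config@noiseSd > 0) {
      adcArr <- adcArr + array(stats::rnorm(prod(shape), sd = config@noiseSd),
                               shape)
      rcbfArr <- rcbfArr +
        array(stats::rnorm(prod(shape), sd = config@noiseSd), shape)
    }
    list(q = q, adc = adcArr, rcbf = rcbfArr)
  })

  pTrueArr <- out$q
  pTrueArr[gtvArr] <- 1
  pTrueArr[csfArr] <- 0

  structures <- buildStructureSet(
    gtv = mk(gtvArr, "GTV"), brain = mk(brainArr, "brain"),
    csf = mk(csfArr, "CSF"), oars = c(oars, list(skull = mk(skullArr, "skull")))
  )

  new("PhantomCase",
      adc = scalarVolume(out$adc, spacing = sp, origin = origin),
      rcbf = scalarVolume(out$rcbf, spacing = sp, origin = origin),
      structures = structures,
      pTrue = scalarVolume(pTrueArr, spacing = sp, origin = origin),
      fov = fov, seed = config@seed, config = config)
}

# Deterministic per-case config for a cohort: jitters the GTV radius
# (+/- 2 mm) and centre (+/- 5 mm per axis), with a sub-seed derived from
# (seed, index) so cohorts are reproducible independent of generation order.
.cohortCaseConfig <- function(baseConfig, seed, index) {
  jitterSeed <- .subSeed(seed, index)
  jit <- .withSeed(jitterSeed, {
    list(dr = stats::runif(1, -2, 2), dc = stats::runif(3, -5, 5))
  })
  cfg <- baseConfig
  cfg@gtvRadiusMm <- baseConfig@gtvRadiusMm + jit$dr
  cfg@gtvCentreOffsetMm <- baseConfig@gtvCentreOffsetMm + jit$dc
  cfg@seed <- as.integer((jitterSeed + 1013904223) %% 2147483647)
  validObject(cfg)
  cfg
}

#' Generate a cohort of phantom cases
#'
#' Produces \code{n} cases from a base configuration with per-case jittered
#' GTV radius and position and deterministic sub-seeds, emulating the
#' anatomical variability of a patient cohort.
#'
#' @param n number of cases, \eqn{\ge 1}.
#' @param baseConfig a \linkS4class{PhantomConfig} used as template.
#' @param seed cohort seed; sub-seeds are derived from it per case.
#' @return A list of \linkS4class{PhantomCase} objects.
#' @export
generateCohort <- function(n, baseConfig = PhantomConfig(), seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  lapply(seq_len(n), function(i)
    generatePhantom(.cohortCaseConfig(baseConfig, seed, i)))
}
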