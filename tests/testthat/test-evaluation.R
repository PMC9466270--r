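test_that("the quality factor matches hand-computed cases", {
  r1 <- mkRegion(1)
  expect_identical(
    qualityFactor(mkDose(76, r1), mkRx(80, r1), r1)$qf_percent, 95)
  r2 <- mkRegion(2)
  qf2 <- qualityFactor(mkDose(c(60, 72), r2), mkRx(c(60, 80), r2), r2)
  expect_equal(qf2$qf_percent, 95, tolerance = 1e-12)
  expect_identical(qf2$n, 2L)
  # identity => exactly 100; and 100 => identity
  set.seed(2)
  doses <- runif(40, 60, 80)
  r40 <- mkRegion(40)
  expect_identical(
    qualityFactor(mkDose(doses, r40), mkRx(doses, r40), r40)$qf_percent,
    100)
  almost <- doses; almost[1] <- almost[1] + 1e-9
  expect_lt(
    qualityFactor(mkDose(almost, r40), mkRx(doses, r40), r40)$qf_percent,
    100)
  # per-voxel map averages to the scalar
  qf <- qualityFactor(mkDose(almost, r40), mkRx(doses, r40), r40)
  expect_equal(mean(volValues(qf$qf_map)[volValues(r40) == 1L]),
               qf$qf_percent, tolerance = 1e-9)
  rxBad <- mkRx(60, r1)
  rxBad@values[volValues(r1) == 1L] <- 0   # bypasses constructor validity
  expect_error(qualityFactor(mkDose(60, r1), rxBad, r1), "positive")
})

test_that("DVH curves match the sort-based oracle and are monotone", {
  r <- mkRegion(500, seed = 3L)
  set.seed(4)
  doses <- runif(500, 0, 75)
  plan <- mkDose(doses, r)
  dvh <- dvhCurve(plan, r, binWidthGy = 0.5)
  expect_identical(dvh$volume_percent[1], 100)
  expect_true(all(diff(dvh$volume_percent) <= 0))
  expect_identical(dvh$volume_percent[nrow(dvh)], 0)
  for (k in sample(nrow(dvh), 25))
    expect_equal(dvh$volume_percent[k],
                 100 * bruteVolumeFraction(doses, dvh$dose_Gy[k]),
                 tolerance = 1e-12)
  # uniform dose: step function at the dose level
  u <- mkDose(rep(60, 500), r)
  du <- dvhCurve(u, r, binWidthGy = 0.1)
  expect_true(all(du$volume_percent[du$dose_Gy <= 60] == 100))
  expect_true(all(du$volume_percent[du$dose_Gy > 60] == 0))
  # half at 59, half at 61: V(60) = 50%
  h <- mkDose(rep(c(59, 61), each = 250), r)
  dh <- dvhCurve(h, r, binWidthGy = 0.5)
  expect_identical(dh$volume_percent[dh$dose_Gy == 60], 50)
})

test_that("dose metrics agree with direct arithmetic and sort oracles", {
  r4 <- mkRegion(4, seed = 5L)
  plan <- mkDose(c(50, 60, 70, 80), r4)
  dm <- doseMetrics(plan, r4, c("Dmean", "Dmin", "Dmax", "V60Gy", "V76Gy"))
  expect_equal(dm$value[dm$metric == "Dmean"], 65)
  expect_equal(dm$value[dm$metric == "Dmin"], 50)
  expect_equal(dm$value[dm$metric == "Dmax"], 80)
  expect_equal(dm$value[dm$metric == "V60Gy"], 75)
  expect_equal(dm$value[dm$metric == "V76Gy"], 25)

  u <- mkDose(rep(60, 4), r4)
  dmu <- doseMetrics(u, r4, c("Dmean", "Dmax", "Dmin", "D98%", "V60Gy",
                              "V76Gy", "V80Gy"))
  expect_equal(dmu$value, c(60, 60, 60, 60, 100, 0, 0))

  r1000 <- mkRegion(1000, dims = c(12L, 12L, 12L), seed = 6L)
  set.seed(7)
  doses <- rnorm(1000, 65, 6)
  p1000 <- mkDose(doses, r1000)
  for (x in c(98, 95, 50, 2)) {
    got <- doseMetrics(p1000, r1000, sprintf("D%d%%", x))$value
    expect_equal(got, bruteDxPercent(doses, x), tolerance = 1e-9)
  }
  expect_error(doseMetrics(p1000, r1000, "Q95"), "unknown metric")
})

test_that("TCP follows the closed form and its monotonicities", {
  r1 <- mkRegion(1)
  pmap <- scalarVolume(array(1, gridDim(r1)))
  zero <- mkDose(0, r1)
  expect_equal(tcp(pmap, zero, r1), exp(-0.032), tolerance = 1e-12)
  # p = 0 everywhere -> TCP = 1
  p0 <- scalarVolume(array(0, gridDim(r1)))
  expect_identical(tcp(p0, zero, r1), 1)

  r <- mkRegion(200, seed = 8L)
  set.seed(9)
  pv <- runif(200)
  dv <- runif(200, 50, 80)
  pmapR <- scalarVolume(array(0, gridDim(r)))
  pmapR@values[volValues(r) == 1L] <- pv
  base <- tcp(pmapR, mkDose(dv, r), r)
  expect_true(base > 0 && base <= 1)
  # increasing any voxel's dose never lowers TCP
  for (k in sample(200, 5)) {
    dv2 <- dv; dv2[k] <- dv2[k] + 5
    expect_gte(tcp(pmapR, mkDose(dv2, r), r), base)
  }
  # strictly decreasing in C and in p
  expect_lt(tcp(pmapR, mkDose(dv, r), r, TCPParams(cConstant = 0.064)),
            base)
  pmapHi <- pmapR
  pmapHi@values[volValues(r) == 1L] <- pmin(1, pv + 0.2)
  expect_lt(tcp(pmapHi, mkDose(dv, r), r), base)
  # closed form on many voxels
  expect_equal(base, exp(-0.032 * sum(pv * exp(-0.12 * dv))),
               tolerance = 1e-12)
})

test_that("C calibration matches the analytic solution and closes the loop", {
  r <- mkRegion(300, seed = 10L)
  set.seed(11)
  pv <- runif(300)
  pmap <- scalarVolume(array(0, gridDim(r)))
  pmap@values[volValues(r) == 1L] <- pv
  uniform <- mkDose(rep(60, 300), r)
  S <- sum(pv) * exp(-0.12 * 60)
  cGot <- calibrateC(list(list(p = pmap, plan = uniform, region = r)),
                     targetTcp = 0.27)
  expect_equal(cGot, -log(0.27) / S, tolerance = 1e-6)
  # doubling the probability mass halves C
  pmap2 <- pmap; pmap2@values <- pmap@values * 2  # probability-mass scaling
  c2 <- calibrateC(list(list(p = pmap2, plan = uniform, region = r)),
                   targetTcp = 0.27)
  expect_equal(c2, cGot / 2, tolerance = 1e-5)
  # parameter recovery on a heterogeneous synthetic cohort
  cohort <- lapply(1:4, function(i) {
    set.seed(100 + i)
    pvi <- runif(300)
    pm <- scalarVolume(array(0, gridDim(r)))
    pm@values[volValues(r) == 1L] <- pvi
    list(p = pm, plan = mkDose(runif(300, 55, 65), r), region = r)
  })
  cHat <- calibrateC(cohort, targetTcp = 0.27)
  got <- mean(vapply(cohort, function(cs)
    tcp(cs$p, cs$plan, cs$region, TCPParams(cConstant = cHat)), numeric(1)))
  expect_equal(got, 0.27, tolerance = 1e-5)
  expect_error(calibrateC(list(), 0.27), "empty")
  expect_error(calibrateC(cohort, targetTcp = 1.2), "in \\(0, 1\\)")
})

test_that("the paired Wilcoxon test matches exact enumeration and wilcox.test", {
  # five all-positive differences: two-sided exact p = 2 * (1/32)
  a <- c(2, 3, 4, 5, 6); b <- c(1, 2, 3, 4, 5) - c(0.5, 0.1, 0.3, 0.2, 0.4)
  res <- pairedWilcoxon(a, b)
  expect_equal(res$p_value, 0.0625, tolerance = 1e-12)
  expect_identical(res$method, "exact")
  # swapping the samples keeps p, mirrors the statistic
  resSwap <- pairedWilcoxon(b, a)
  expect_equal(resSwap$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(res$statistic + resSwap$statistic,
               res$n_nonzero * (res$n_nonzero + 1) / 2)
  # identical samples: degenerate, p = 1
  resDeg <- pairedWilcoxon(a, a)
  expect_true(resDeg$degenerate)
  expect_identical(resDeg$p_value, 1)
  # agreement with stats::wilcox.test on tie-free data
  set.seed(12)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(pairedWilcoxon(x, y)$p_value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # ties fall back to the corrected normal approximation
  xt <- c(1, 2, 3, 4, 5, 6); yt <- c(0, 1, 2, 3, 4, 7)
  resTie <- pairedWilcoxon(xt, yt)
  expect_identical(resTie$method, "normal-approximation")
  expect_equal(resTie$p_value,
               suppressWarnings(wilcox.test(xt, yt, paired = TRUE,
                                            correct = FALSE)$p.value),
               tolerance = 1e-12)
  expect_error(pairedWilcoxon(1:3, 1:4), "equal length")
  expect_error(pairedWilcoxon(1:2, 2:3), "at least 3")
})

test_that("plan comparison has the full metric schema and zero self-difference", {
  cs <- sharedSmallCase()
  p <- sharedSmallProbability()
  rx <- sharedSmallRx()
  rxStd <- standardPrescription(cs@structures)
  plan <- asPlan(rxStd)
  cmp <- comparePlans(plan, plan, rxStd, rxStd, cs@structures, p)
  expect_true(all(cmp$difference == 0))
  for (s in c("GTV", "CTV", "PTV")) {
    met <- cmp$metric[cmp$structure == s]
    want <- c("QF", "Dmean", "Dmin", "Dmax", "D98%", "V60Gy", "V76Gy",
              "V80Gy")
    if (s != "PTV") want <- c(want, "TCP")
    expect_setequal(met, want)
  }
  # dose painting never loses GTV TCP against the uniform plan
  dpPlan <- asPlan(rx)
  cmp2 <- comparePlans(plan, dpPlan, rxStd, rx, cs@structures, p)
  tcpRows <- cmp2[cmp2$metric == "TCP", ]
  expect_true(all(tcpRows$difference >= 0))
})
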