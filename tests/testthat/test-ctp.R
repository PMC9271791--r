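# CTP: AIF selection, truncated-SVD deconvolution, CBF-ratio core rule

ctpFixture <- function() {
  ph <- smallPhantom()
  list(
    ph = ph,
    ctp = cached("ctpSmall", makeCTPSeries(ph, noise_sd = 0,
                                           downsample = 2L))
  )
}

test_that("the AIF is found in the arterial voxels at the right time", {
  fx <- ctpFixture()
  aif <- selectAIF(fx$ctp$series, fx$ctp$brainMask)
  expect_equal(which.max(aif), which.max(fx$ctp$aif), tolerance = 1)
  # positive scale invariance: doubling enhancement selects the same curve
  s2 <- fx$ctp$series
  base <- apply(voxels(s2)[, , , 1:3], 1:3, mean)
  v2 <- voxels(s2)
  for (t in seq_along(s2@times)) {
    v2[, , , t] <- base + 2 * (v2[, , , t] - base)
  }
  doubled <- new("CTPSeries", voxels = v2, times = s2@times,
                 spacing = spacing(s2), origin = origin(s2))
  aif2 <- selectAIF(doubled, fx$ctp$brainMask)
  expect_equal(which.max(aif2), which.max(aif))
  expect_gt(cor(aif, aif2), 0.999)
})

test_that("a series without temporal variation has no bolus", {
  fx <- ctpFixture()
  d <- dim(voxels(fx$ctp$series))
  flat <- array(rep(apply(voxels(fx$ctp$series), 1:3, mean), d[4L]),
                dim = d)
  s <- new("CTPSeries", voxels = flat, times = fx$ctp$series@times,
           spacing = spacing(fx$ctp$series), origin = origin(fx$ctp$series))
  expect_error(selectAIF(s, fx$ctp$brainMask), "no bolus")
})

test_that("deconvolution recovers flow ratio, delay and an identity kernel", {
  fx <- ctpFixture()
  aif <- selectAIF(fx$ctp$series, fx$ctp$brainMask)
  maps <- cached("maps-small", deconvolveCTP(fx$ctp$series, aif,
                                             fx$ctp$brainMask))
  core <- voxels(fx$ctp$coreTruth)
  vessel <- voxels(fx$ctp$vesselMask)
  norm <- voxels(fx$ctp$brainMask) & !core & !vessel
  ratio <- median(maps@cbf[core]) / median(maps@cbf[norm & maps@tmax < 4])
  expect_equal(ratio, 0.2, tolerance = 0.1)
  dt <- diff(fx$ctp$series@times)[1L]
  # core delayed by 6 s; normal and arterial (identity kernel) at ~0
  expect_lte(abs(median(maps@tmax[core]) - 6), dt)
  expect_lte(median(maps@tmax[norm]), dt)
  expect_lte(median(maps@tmax[vessel]), dt)
})

test_that("recovered CBF is proportional to true CBF on clean data", {
  fx <- ctpFixture()
  aif <- selectAIF(fx$ctp$series, fx$ctp$brainMask)
  maps <- cached("maps-small", deconvolveCTP(fx$ctp$series, aif,
                                             fx$ctp$brainMask))
  tissue <- voxels(fx$ctp$brainMask) & !voxels(fx$ctp$vesselMask)
  fit <- summary(lm(maps@cbf[tissue] ~ fx$ctp$cbfTruth[tissue]))
  expect_gte(fit$r.squared, 0.95)
})

test_that("the core rule thresholds strictly below the fraction of normal", {
  dm <- c(6L, 6L, 4L)
  bm <- new("VoxelMask", voxels = array(TRUE, dm), spacing = c(2, 2, 2),
            origin = c(0, 0, 0))
  cbf <- array(50, dm)
  tmax <- array(0, dm)
  cbf[1, 1, 1] <- 10          # clearly core
  cbf[2, 1, 1] <- 15          # exactly 0.30 x median: excluded (strict)
  maps <- new("PerfusionMaps", cbf = cbf, tmax = tmax, brainMask = bm,
              spacing = c(2, 2, 2), origin = c(0, 0, 0))
  cm <- coreMask(maps)
  expect_true(voxels(cm)[1, 1, 1])
  expect_false(voxels(cm)[2, 1, 1])
  expect_equal(voxelCount(cm), 1L)

  # uniform flow: nothing is below 30% of itself
  maps2 <- new("PerfusionMaps", cbf = array(50, dm), tmax = tmax,
               brainMask = bm, spacing = c(2, 2, 2), origin = c(0, 0, 0))
  expect_equal(voxelCount(coreMask(maps2)), 0L)

  # no Tmax < cutoff tissue: no reference
  maps3 <- new("PerfusionMaps", cbf = cbf, tmax = array(10, dm),
               brainMask = bm, spacing = c(2, 2, 2), origin = c(0, 0, 0))
  expect_error(coreMask(maps3), "no normal tissue reference")
})

test_that("the core mask is scale-invariant and monotone in its fraction", {
  fx <- ctpFixture()
  aif <- selectAIF(fx$ctp$series, fx$ctp$brainMask)
  maps <- cached("maps-small", deconvolveCTP(fx$ctp$series, aif,
                                             fx$ctp$brainMask))
  cm1 <- coreMask(maps)
  scaled <- new("PerfusionMaps", cbf = maps@cbf * 3.7, tmax = maps@tmax,
                brainMask = maps@brainMask, spacing = spacing(maps),
                origin = maps@origin)
  expect_identical(voxels(coreMask(scaled)), voxels(cm1))
  cmLoose <- coreMask(maps, new("CoreMaskConfig", cbf_core_fraction = 0.5,
                                tmax_normal_s = 4))
  expect_true(all(voxels(cmLoose)[voxels(cm1)]))
  # and it matches the construction truth well on clean data
  expect_gte(diceCoefficient(cm1, fx$ctp$coreTruth), 0.9)
})

test_that("CTP series survive a NIfTI round-trip", {
  fx <- ctpFixture()
  f <- tempfile(fileext = ".nii.gz")
  writeCTPSeries(fx$ctp$series, f)
  back <- readCTPSeries(f)
  expect_equal(voxels(back), voxels(fx$ctp$series), tolerance = 1e-5)
  expect_equal(back@times, fx$ctp$series@times)
  expect_equal(spacing(back), spacing(fx$ctp$series))
})
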