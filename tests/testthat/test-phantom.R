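# The synthetic head phantom: determinism, ground-truth consistency, and
# densitometric fidelity of the water-uptake construction

test_that("identical spec and seed give bit-identical phantoms", {
  a <- makePhantom(smallSpec(seed = 123L))
  b <- makePhantom(smallSpec(seed = 123L))
  expect_identical(voxels(a@ncct), voxels(b@ncct))
  expect_identical(voxels(a@infarctMask), voxels(b@infarctMask))
  c2 <- makePhantom(smallSpec(seed = 124L))
  expect_false(identical(voxels(a@ncct), voxels(c2@ncct)))
})

test_that("ground-truth masks satisfy the bundle invariants", {
  ph <- smallPhantom()
  expect_false(any(voxels(ph@infarctMask) & voxels(ph@csfMask)))
  expect_true(all(voxels(ph@brainMask)[voxels(ph@infarctMask)]))
  expect_equal(ph@trueNWUPercent, 25)
  # entirely within the left hemisphere
  hs <- splitHemispheres(ph@brainMask, ph@midlineTruth)
  expect_true(all(voxels(hs$left)[voxels(ph@infarctMask)]))
})

test_that("infarct volume targeting hits the requested volume", {
  ph <- cached("vol50", makePhantom(smallSpec(infarct_volume_ml = 50,
                                              seed = 77L)))
  expect_equal(infarctVolumeMl(ph@infarctMask), 50, tolerance = 3 / 50)
  expect_error(
    makePhantom(smallSpec(infarct_volume_ml = 5000, seed = 1L)),
    "too large"
  )
})

test_that("without uptake the lesion site matches its mirror", {
  ph <- cached("w0small", makePhantom(smallSpec(uptake_fraction = 0,
                                                seed = 31L)))
  v <- voxels(ph@ncct)
  m <- voxels(ph@infarctMask)
  mir <- voxels(mirrorMask(ph@infarctMask, ph@midlineTruth))
  expect_equal(mean(v[m]), mean(v[mir]), tolerance = 0.5 / 38)
})

test_that("the uptake fraction sets the density ratio of the lesion", {
  # fine grid and a large lesion so partial-volume edge bias on the
  # ground-truth-mask means stays below the tolerance of the ratio
  ph <- cached("fineRatio", makePhantom(phantomSpec(
    shape = c(223L, 268L, 191L), spacing = c(0.7, 0.7, 0.7),
    infarct_volume_ml = 200, uptake_fraction = 0.25, noise_sd = 0,
    seed = 55L
  )))
  v <- voxels(ph@ncct)
  ratio <- mean(v[voxels(ph@infarctMask)]) /
    mean(v[voxels(mirrorMask(ph@infarctMask, ph@midlineTruth))])
  expect_equal(ratio, 0.75, tolerance = 0.01 / 0.75)
})

test_that("hemorrhagic transformation voxels are hyperdense and counted", {
  ph <- cached("htSmall", makePhantom(smallSpec(ht_fraction = 0.2,
                                                seed = 8L)))
  nHT <- voxelCount(ph@htMask)
  expect_equal(nHT, round(0.2 * voxelCount(ph@infarctMask)))
  # all HT voxels above the 40 HU infarct ceiling (draws 50-80, noise 2)
  expect_true(all(voxels(ph@ncct)[voxels(ph@htMask)] > 40))
  expect_true(all(voxels(ph@infarctMask)[voxels(ph@htMask)]))
})

test_that("head tilt rotates image and ground truth coherently", {
  ph <- cached("tiltSmall", makePhantom(smallSpec(tilt_deg = 5,
                                                  seed = 12L)))
  expect_equal(angleErrDeg(ph@midlineTruth@normal,
                           as.numeric(nwukit:::.rotZ(5) %*% c(1, 0, 0))),
               0, tolerance = 1e-6)
  # lesion density is preserved under rotation
  v <- voxels(ph@ncct)
  expect_equal(mean(v[voxels(ph@infarctMask)]), 38 * 0.75, tolerance = 0.1)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(phantomSpec(uptake_fraction = 1.2), "uptake")
  expect_error(phantomSpec(ht_fraction = -0.1), "ht_fraction")
  expect_error(phantomSpec(noise_sd = -1), "sd")
  expect_error(phantomSpec(infarct_side = "middle"), "side")
})

test_that("the CTP forward model matches its own ground truth", {
  ph <- smallPhantom()
  ctp <- cached("ctpSmall", makeCTPSeries(ph, noise_sd = 0, downsample = 2L))
  core <- voxels(ctp$coreTruth)
  norm <- voxels(ctp$brainMask) & !core & !voxels(ctp$vesselMask)
  # truth maps encode the requested ratio and delay exactly (pure voxels)
  pure <- ctp$cbfTruth[core]
  expect_equal(median(pure) / median(ctp$cbfTruth[norm]), 0.2,
               tolerance = 1e-9)
  expect_equal(unique(ctp$tmaxTruth[core]), 6)
  expect_error(makeCTPSeries(ph, time_step_s = 0), "time_step")
  expect_error(makeCTPSeries(ph, cbf_core_ratio = 1.2), "ratio")
})

test_that("deconvolving the generated series recovers the flow deficit", {
  ph <- smallPhantom()
  ctp <- cached("ctpSmall", makeCTPSeries(ph, noise_sd = 0, downsample = 2L))
  aif <- selectAIF(ctp$series, ctp$brainMask)
  maps <- deconvolveCTP(ctp$series, aif, ctp$brainMask)
  core <- voxels(ctp$coreTruth)
  norm <- voxels(ctp$brainMask) & !core & !voxels(ctp$vesselMask)
  ratio <- median(maps@cbf[core]) /
    median(maps@cbf[norm & maps@tmax < 4])
  expect_equal(ratio, 0.2, tolerance = 0.1)
})
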