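# Infarct segmentation and largest-component refinement

test_that("the standard phantom's infarct is segmented with good overlap", {
  ph <- stdPhantom()
  brain <- stdBrain(ph, "std25")
  csf <- cached("csf-std25", segmentCSF(ph@ncct, brain))
  pl <- cached("plane-std25", estimateMidline(ph@ncct, brain))
  seg <- cached("seg-std25", segmentInfarct(ph@ncct, brain, csf, pl))
  expect_gte(diceCoefficient(seg, ph@infarctMask), 0.7)
  # single connected component, disjoint from CSF, inside the HU window
  lab <- nwukit:::.labelComponents(voxels(seg), 26L)
  expect_equal(length(lab$sizes), 1L)
  expect_false(any(voxels(seg) & voxels(csf)))
  hu <- voxels(ph@ncct)[voxels(seg)]
  expect_true(all(hu >= 0 & hu <= 40))
})

test_that("no hypodensity means an empty segmentation", {
  ph <- cached("w0std", makePhantom(phantomSpec(uptake_fraction = 0,
                                                seed = 60L)))
  brain <- extractBrainMask(ph@ncct)
  csf <- segmentCSF(ph@ncct, brain)
  pl <- estimateMidline(ph@ncct, brain)
  seg <- segmentInfarct(ph@ncct, brain, csf, pl)
  expect_equal(voxelCount(seg), 0L)
})

test_that("refinement keeps only the largest of two hypodense blobs", {
  # synthetic: uniform tissue with a 40 ml and a 5 ml hypodensity
  u <- uniformHead(dim = c(70L, 80L, 60L), spacing = c(2, 2, 2),
                   noise_sd = 1, seed = 3L)
  vox <- voxels(u$volume)
  ctr <- u$center
  big <- nwukit:::.ellipsoidMask(
    (seq_len(70) - 1) * 2, (seq_len(80) - 1) * 2, (seq_len(60) - 1) * 2,
    ctr + c(-28, -15, 0), c(16, 19, 16)
  ) # ~ 40 ml
  smallb <- nwukit:::.ellipsoidMask(
    (seq_len(70) - 1) * 2, (seq_len(80) - 1) * 2, (seq_len(60) - 1) * 2,
    ctr + c(-30, 28, 8), c(8, 9, 8)
  ) # ~ 5 ml (clearly disconnected)
  vox[big & voxels(u$brain)] <- 28
  vox[smallb & voxels(u$brain)] <- 28
  vol <- new("CTVolume",
    voxels = vox, spacing = c(2, 2, 2), origin = c(0, 0, 0),
    orientation = "RAS", nativeOrientation = "RAS"
  )
  seg <- segmentInfarct(vol, u$brain, emptyMaskLike(vol),
                        midSagittalPlane(vol))
  expect_gt(sum(voxels(seg) & big), 0L)
  expect_equal(sum(voxels(seg) & smallb & !big), 0L)
})

test_that("largest-component refinement is exact and deterministic", {
  dm <- c(30L, 20L, 10L)
  m <- array(FALSE, dim = dm)
  m[2:6, 2:5, 2:6] <- TRUE             # 100 voxels
  m[20:24, 10:12, 3:4] <- TRUE         # 30 voxels
  mask <- new("VoxelMask", voxels = m, spacing = c(1, 1, 1),
              origin = c(0, 0, 0))
  out <- refineLargestComponent(mask)
  expect_equal(voxelCount(out), 100L)
  expect_true(all(voxels(out)[2:6, 2:5, 2:6]))

  # single component: unchanged; empty: empty
  single <- new("VoxelMask", voxels = m & FALSE, spacing = c(1, 1, 1),
                origin = c(0, 0, 0))
  expect_equal(voxelCount(refineLargestComponent(single)), 0L)
  m2 <- array(FALSE, dim = dm); m2[5:8, 5:8, 5:8] <- TRUE
  one <- new("VoxelMask", voxels = m2, spacing = c(1, 1, 1),
             origin = c(0, 0, 0))
  expect_identical(voxels(refineLargestComponent(one)), m2)

  # equal sizes: lower mean HU wins when a volume is given, else lower index
  m3 <- array(FALSE, dim = dm)
  m3[2:3, 2:3, 2:3] <- TRUE    # 8 voxels, first in linear order
  m3[20:21, 10:11, 5:6] <- TRUE # 8 voxels, darker
  vox <- array(38, dim = dm); vox[20:21, 10:11, 5:6] <- 20
  vol <- new("CTVolume", voxels = vox, spacing = c(1, 1, 1),
             origin = c(0, 0, 0), orientation = "RAS",
             nativeOrientation = "RAS")
  tie <- new("VoxelMask", voxels = m3, spacing = c(1, 1, 1),
             origin = c(0, 0, 0))
  withVol <- refineLargestComponent(tie, volume = vol)
  expect_true(all(which(voxels(withVol)) ==
                    which(m3 & vox == 20)))
  noVol <- refineLargestComponent(tie)
  expect_true(voxels(noVol)[2, 2, 2])
  # repeated runs identical
  expect_identical(voxels(refineLargestComponent(tie, volume = vol)),
                   voxels(withVol))
})

test_that("26-connectivity joins diagonal neighbours, 6 does not", {
  dm <- c(8L, 8L, 8L)
  m <- array(FALSE, dim = dm)
  m[2, 2, 2] <- TRUE; m[3, 3, 3] <- TRUE
  lab26 <- nwukit:::.labelComponents(m, 26L)
  lab6 <- nwukit:::.labelComponents(m, 6L)
  expect_equal(length(lab26$sizes), 1L)
  expect_equal(length(lab6$sizes), 2L)
})

test_that("mask volume converts voxel counts to ml", {
  m <- array(FALSE, dim = c(20L, 20L, 10L))
  m[1:10, 1:10, 1:10] <- TRUE          # 1000 voxels
  mask <- new("VoxelMask", voxels = m, spacing = c(1, 1, 1),
              origin = c(0, 0, 0))
  expect_equal(infarctVolumeMl(mask), 1.0)
  none <- new("VoxelMask", voxels = m & FALSE, spacing = c(1, 1, 1),
              origin = c(0, 0, 0))
  expect_equal(infarctVolumeMl(none), 0)
  ph <- cached("vol50", makePhantom(smallSpec(infarct_volume_ml = 50,
                                              seed = 77L)))
  expect_equal(infarctVolumeMl(ph@infarctMask), 50, tolerance = 3 / 50)
})
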