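# Net water uptake densitometry: the core statistic, thresholds,
# exclusion accounting, and the patch / ROI sampling estimators

test_that("NWU over ground-truth masks recovers the built-in uptake", {
  ph <- stdPhantom()
  res <- computeNWU(ph@ncct, ph@infarctMask, ph@csfMask, ph@midlineTruth)
  expect_equal(res@nwu_percent, 25, tolerance = 1.5 / 25)
  expect_equal(res@mode, "followup-infarct")
  # the defining identity
  expect_equal(res@nwu_percent,
               100 * (1 - res@d_ischemic / res@d_normal),
               tolerance = 1e-12)
  expect_equal(res@edema_volume_ml,
               res@nwu_percent / 100 * res@infarct_volume_ml,
               tolerance = 1e-9)
})

test_that("no uptake gives NWU near zero", {
  ph <- cached("w0small", makePhantom(smallSpec(uptake_fraction = 0,
                                                seed = 31L)))
  # identical treatment of both regions: the symmetric 20-80 window
  res <- computeNWU(ph@ncct, ph@infarctMask, ph@csfMask, ph@midlineTruth,
                    mode = "baseline-core")
  expect_lt(abs(res@nwu_percent), 1)
})

test_that("hemorrhagic voxels are excluded by the 40 HU ceiling", {
  ph0 <- cached("ht0", makePhantom(phantomSpec(ht_fraction = 0, seed = 7L)))
  ph3 <- cached("ht3", makePhantom(phantomSpec(ht_fraction = 0.3,
                                               seed = 7L)))
  r0 <- computeNWU(ph0@ncct, ph0@infarctMask, ph0@csfMask,
                   ph0@midlineTruth)
  r3 <- computeNWU(ph3@ncct, ph3@infarctMask, ph3@csfMask,
                   ph3@midlineTruth)
  expect_lt(abs(r0@nwu_percent - r3@nwu_percent), 1.5)
  expect_gte(r3@n_removed_threshold[["ischemic"]],
             voxelCount(ph3@htMask))
})

test_that("reverting to the 20-80 window lowers NWU on severe edema", {
  ph <- cached("w45", makePhantom(phantomSpec(uptake_fraction = 0.45,
                                              seed = 9L)))
  fracBelow20 <- mean(voxels(ph@ncct)[voxels(ph@infarctMask)] < 20)
  expect_gte(fracBelow20, 0.14)
  mod <- computeNWU(ph@ncct, ph@infarctMask, ph@csfMask, ph@midlineTruth)
  std <- computeNWU(ph@ncct, ph@infarctMask, ph@csfMask, ph@midlineTruth,
                    thresholds = thresholdConfig(infarct_hu = c(20, 80)))
  expect_lt(std@nwu_percent, mod@nwu_percent)
})

test_that("CSF dilation into the mirror region barely moves NWU", {
  ph <- stdPhantom()
  base <- computeNWU(ph@ncct, ph@infarctMask, ph@csfMask, ph@midlineTruth)
  fat <- maskFrom(nwukit:::.dilateBall(voxels(ph@csfMask), 2L), ph@ncct)
  dil <- computeNWU(ph@ncct, ph@infarctMask, fat, ph@midlineTruth)
  expect_lt(abs(dil@nwu_percent - base@nwu_percent), 1)
  expect_gte(sum(dil@n_removed_csf), sum(base@n_removed_csf))
})

test_that("degenerate regions and empty masks are rejected", {
  ph <- smallPhantom()
  tiny <- array(FALSE, dim(voxels(ph@ncct)))
  idx <- which(voxels(ph@infarctMask))[1:10]
  tiny[idx] <- TRUE
  expect_error(
    computeNWU(ph@ncct, maskFrom(tiny, ph@ncct), ph@csfMask,
               ph@midlineTruth),
    "region vanished"
  )
  expect_error(
    computeNWU(ph@ncct, emptyMaskLike(ph@ncct), ph@csfMask,
               ph@midlineTruth),
    "empty"
  )
})

test_that("midline-crossing mirrors are trimmed with a warning recorded", {
  # a lesion mask butting against the midline: its mirror overlaps it
  ph <- smallPhantom()
  dm <- dim(voxels(ph@ncct))
  ctr <- round(dm / 2)
  m <- array(FALSE, dm)
  m[(ctr[1] - 8):(ctr[1] + 2), (ctr[2] - 6):(ctr[2] + 6),
    (ctr[3] - 4):(ctr[3] + 4)] <- TRUE
  m <- m & voxels(ph@brainMask)
  res <- computeNWU(ph@ncct, maskFrom(m, ph@ncct), ph@csfMask,
                    ph@midlineTruth)
  expect_true(any(grepl("mirrored voxels", res@warnings)))
})

test_that("patch sampling estimates NWU and dilutes outside the lesion", {
  ph <- stdPhantom()
  pl <- ph@midlineTruth
  ai <- which(voxels(ph@infarctMask), arr.ind = TRUE)
  sp <- spacing(ph@ncct)
  zr <- origin(ph@ncct)[3] + (range(ai[, 3]) - 1) * sp[3]
  zc <- mean(zr)
  zin <- zc + c(-10.5, -3.5, 3.5, 10.5)
  xmid <- mean(origin(ph@ncct)[1] + (range(ai[, 1]) - 1) * sp[1])
  ymid <- mean(origin(ph@ncct)[2] + (range(ai[, 2]) - 1) * sp[2])
  lr <- abs(xmid - pl@point[1])

  inside <- patchNWU(ph@ncct,
    patchSpec(zin, lr, ymid, patch_edge_mm = 20, side = "left"),
    pl, ph@csfMask, brainMask = ph@brainMask
  )
  expect_equal(inside@nwu_percent, 25, tolerance = 2 / 25)
  expect_equal(inside@mode, "patch")

  normal <- patchNWU(ph@ncct,
    patchSpec(zin - 30, lr, ymid + 45, patch_edge_mm = 20, side = "left"),
    pl, ph@csfMask, brainMask = ph@brainMask
  )
  expect_lt(abs(normal@nwu_percent), 1)

  half <- patchNWU(ph@ncct,
    patchSpec(zin, lr, ymid, patch_edge_mm = 70, side = "left"),
    pl, ph@csfMask, brainMask = ph@brainMask
  )
  expect_gt(half@nwu_percent, 0)
  expect_lt(half@nwu_percent, 25)

  expect_error(
    patchNWU(ph@ncct, patchSpec(c(-500, 0, 10, 20), lr, ymid),
             pl, ph@csfMask),
    "outside"
  )
})

test_that("ROI sampling matches truth at lesion centers, zero elsewhere", {
  ph <- stdPhantom()
  pl <- ph@midlineTruth
  interior <- nwukit:::.erodeBall(voxels(ph@infarctMask), 6L)
  set.seed(17)
  cand <- sample(which(interior), 2000L)
  P <- nwukit:::.linearToWorld(cand, dim(interior),
                               spacing(ph@ncct), origin(ph@ncct))
  # greedy farthest-point spread so same-slice discs cannot overlap
  sel <- 1L
  for (i in 2:13) {
    d2 <- Reduce(pmin, lapply(sel, function(j) {
      (P[, 1] - P[j, 1])^2 + (P[, 2] - P[j, 2])^2 + (P[, 3] - P[j, 3])^2
    }))
    sel <- c(sel, which.max(d2))
  }
  centers <- P[sel, , drop = FALSE]
  res <- roiNWU(ph@ncct, roiSpec(centers, side = "left"), pl)
  expect_equal(res@nwu_percent, 25, tolerance = 2.5 / 25)
  expect_equal(res@mode, "roi")
  # 13 discs of 10 mm diameter at 1 mm spacing: ~78.5 voxels each
  discVox <- sum(outer((-7:7)^2, (-7:7)^2, "+") <= 25)
  expect_equal(res@infarct_volume_ml * 1000 / prod(spacing(ph@ncct)),
               13 * discVox, tolerance = 0.15)

  ctr <- nwukit:::.gridCenter(dim(interior), spacing(ph@ncct),
                              origin(ph@ncct))
  lone <- roiNWU(ph@ncct, roiSpec(rbind(ctr + c(-30, 25, -20)),
                                  side = "left"), pl)
  expect_lt(abs(lone@nwu_percent), 1.5)

  expect_error(
    roiNWU(ph@ncct, roiSpec(rbind(ctr + c(30, 0, 0)), side = "left"), pl),
    "wrong side"
  )
})

test_that("threshold configuration validates its intervals", {
  expect_error(thresholdConfig(infarct_hu = c(40, 0)), "low < high")
  tc <- thresholdConfig()
  expect_equal(tc@infarct_hu, c(0, 40))
  expect_equal(tc@baseline_core_hu, c(20, 80))
  expect_equal(tc@normal_hu, c(20, 80))
})
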