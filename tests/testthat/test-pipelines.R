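# End-to-end pipelines and the command-line interface

test_that("the follow-up pipeline measures a coarse phantom end to end", {
  ph <- smallPhantom()
  run <- cached("run-small25", runFollowupPipeline(ph@ncct))
  expect_s4_class(run$result, "NWUResult")
  expect_equal(run$result@mode, "followup-infarct")
  expect_equal(run$result@nwu_percent, 25, tolerance = 3 / 25)
  expect_gt(run$result@infarct_volume_ml, 30)
  expect_gte(diceCoefficient(run$infarct, ph@infarctMask), 0.7)
})

test_that("a scan without hypodensity stops with 'no visible infarct'", {
  u <- uniformHead(noise_sd = 2, seed = 9L)
  expect_error(runFollowupPipeline(u$volume), "no visible infarct")
})

test_that("the baseline pipeline runs the CTP-core route", {
  ph <- smallPhantom(w = 0.1, seed = 14L)
  ctp <- makeCTPSeries(ph, downsample = 2L)
  run <- runBaselinePipeline(ph@ncct, ctp$series)
  expect_equal(run$result@mode, "baseline-core")
  expect_equal(run$result@nwu_percent, 10, tolerance = 3 / 10)
  expect_s4_class(run$maps, "PerfusionMaps")
})

test_that("a perfusion study without a flow deficit has no measurable core", {
  ph <- smallPhantom()
  # near-uniform flow: the "core" is indistinguishable from normal tissue
  ctp <- makeCTPSeries(ph, cbf_core_ratio = 0.99, downsample = 2L)
  expect_error(
    suppressWarnings(runBaselinePipeline(ph@ncct, ctp$series)),
    "no measurable core"
  )
})

test_that("a baseline scan before edema develops measures NWU near zero", {
  ph <- cached("w0small", makePhantom(smallSpec(uptake_fraction = 0,
                                                seed = 31L)))
  # the lesion has a perfusion deficit but no density deficit yet
  ctp <- makeCTPSeries(ph, downsample = 2L)
  run <- suppressWarnings(runBaselinePipeline(ph@ncct, ctp$series))
  expect_lt(abs(run$result@nwu_percent), 1.5)
})

test_that("a supplied visible-infarct mask bypasses the CTP route", {
  ph <- smallPhantom()
  run <- runBaselinePipeline(ph@ncct, NULL, infarctMask = ph@infarctMask)
  expect_equal(run$result@mode, "followup-infarct")
  # coarse-grid partial volume biases truth-mask means towards zero NWU;
  # the point here is the routing, not fine accuracy
  expect_gt(run$result@nwu_percent, 20)
  expect_lt(run$result@nwu_percent, 27)
})

test_that("configuration is validated and rejects unknown keys", {
  expect_error(nwuConfig(not_a_key = 1), "unknown configuration keys")
  expect_error(nwuConfig(cbf_core_fraction = 1.5), "cbf_core_fraction")
  expect_error(nwuConfig(infarct_hu_low = 50), "infarct window")
  cfg <- nwuConfig(delta_hu = 2)
  expect_equal(cfg$delta_hu, 2)
  expect_equal(cfg$cbf_core_fraction, 0.30)
  expect_equal(cfg$tmax_normal_s, 4.0)
})

test_that("a plug-in segmenter replaces the classical method", {
  ph <- smallPhantom()
  oracle <- function(volume, brainMask, csfMask, plane) ph@infarctMask
  run <- runFollowupPipeline(ph@ncct, infarct_segmenter = oracle)
  expect_identical(voxels(run$infarct), voxels(ph@infarctMask))
  expect_gt(run$result@nwu_percent, 20)
  expect_lt(run$result@nwu_percent, 27)
})

# --- command-line interface -------------------------------------------------

test_that("the followup subcommand writes a full JSON result", {
  ph <- smallPhantom()
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(ph@ncct, f)
  out <- tempfile(fileext = ".json")
  status <- suppressMessages(nwuKit(c("followup", "--ncct", f,
                                      "--out", out)))
  expect_equal(status, 0L)
  js <- jsonlite::read_json(out)
  expect_true(is.numeric(js$nwu_percent))
  expect_equal(js$nwu_percent, 25, tolerance = 3 / 25)
  expect_true(is.numeric(js$infarct_volume_ml))
  # the resolved configuration is embedded for reproducibility
  expect_equal(js$config$cbf_core_fraction, 0.30)
  expect_equal(js$config$infarct_hu_high, 40)
})

test_that("pipeline failures exit 1, usage errors exit 2", {
  u <- uniformHead(noise_sd = 2, seed = 9L)
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(u$volume, f)
  out <- tempfile(fileext = ".json")
  expect_equal(
    suppressMessages(nwuKit(c("followup", "--ncct", f, "--out", out))),
    1L
  )
  expect_equal(suppressMessages(nwuKit(c("followup", "--out", out))), 2L)
  expect_equal(suppressMessages(nwuKit(c("frobnicate"))), 2L)
  expect_equal(
    suppressMessages(nwuKit(c("followup", "--ncct", f, "--bogus", "1"))),
    2L
  )
  expect_equal(suppressMessages(nwuKit(character(0))), 2L)
})

test_that("the evaluate subcommand reproduces the agreement statistics", {
  set.seed(2)
  ref <- data.frame(id = 1:12, value = rnorm(12, 20, 6))
  pred <- data.frame(id = 1:12, value = ref$value + rnorm(12, 0.5, 1))
  fp <- tempfile(fileext = ".csv"); fr <- tempfile(fileext = ".csv")
  write.csv(pred, fp, row.names = FALSE)
  write.csv(ref, fr, row.names = FALSE)
  out <- tempfile(fileext = ".json")
  status <- suppressMessages(nwuKit(c("evaluate", "--pred", fp,
                                      "--ref", fr, "--out", out)))
  expect_equal(status, 0L)
  js <- jsonlite::read_json(out)
  expect_equal(js$icc, icc21(pred$value, ref$value)@icc, tolerance = 1e-9)
  expect_equal(js$bias, mean(pred$value - ref$value), tolerance = 1e-9)
})

test_that("the segment subcommand writes the infarct mask", {
  ph <- smallPhantom()
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(ph@ncct, f)
  out <- tempfile(fileext = ".nii.gz")
  status <- suppressMessages(nwuKit(c("segment", "--ncct", f,
                                      "--out", out)))
  expect_equal(status, 0L)
  seg <- readMask(out, readCTVolume(f))
  expect_gte(diceCoefficient(seg, ph@infarctMask), 0.7)
})
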