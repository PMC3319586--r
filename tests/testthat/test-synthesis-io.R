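# Synthetic patients, degradation scenarios, and structured-text IO.

test_that("patient generation is deterministic under (seed, index)", {
  spec <- default_cohort_spec(seed = 99)
  r1 <- generate_patient(spec, 3)
  r2 <- generate_patient(spec, 3)
  expect_identical(r1, r2)
  r3 <- generate_patient(spec, 4)
  expect_false(identical(r1$dus_diameters, r3$dus_diameters))
})

test_that("the aortic waveform mean matches the stated cardiac output", {
  for (i in c(1, 5, 9)) {
    rec <- generate_patient(default_cohort_spec(seed = 5), i)
    wf <- rec$aortic_flow_waveform
    m <- sum(diff(wf$time) * (head(wf$flow, -1) + tail(wf$flow, -1)) / 2) /
      diff(range(wf$time))
    expect_equal(60 * m, rec$mean_flows[["aorta"]], tolerance = 0.01)
  }
})

test_that("generated vessels taper distally and flows are consistent", {
  rec <- generate_patient(default_cohort_spec(seed = 5), 2)
  dus <- rec$dus_diameters
  for (v in unique(dus$vessel_id)) {
    st <- dus[dus$vessel_id == v, ]
    st <- st[order(st$position), ]
    expect_true(all(diff(st$diameter) <= 1e-12))
  }
  mf <- rec$mean_flows
  expect_equal(mf[["radial"]] + mf[["ulnar"]], mf[["brachial"]],
               tolerance = 1e-9)
  expect_gte(mf[["aorta"]], mf[["brachial"]])
})

test_that("the default cohort spans adequate and inadequate cephalic veins", {
  cohort <- generate_cohort(default_cohort_spec())
  expect_length(cohort, 25)
  status <- vapply(cohort, function(r) {
    unname(caliber_screen(r)["distal_cephalic"])
  }, "")
  expect_true(any(status == "adequate"))
  expect_true(any(status == "inadequate"))
})

test_that("record validation rejects inconsistent measurements", {
  rec <- fixture_patient()
  bad <- rec; bad$cardiac_period <- 2.5
  expect_error(validate_patient_record(bad), "cardiac period")
  bad <- rec; bad$mean_flows[["brachial"]] <- 2 * bad$mean_flows[["aorta"]]
  expect_error(validate_patient_record(bad), "aortic flow")
  bad <- rec; bad$mean_flows[["radial"]] <- 1.2 * bad$mean_flows[["brachial"]]
  expect_error(validate_patient_record(bad), "exceeds the brachial")
  bad <- rec; bad$aortic_flow_waveform$flow <- 2 * bad$aortic_flow_waveform$flow
  expect_error(validate_patient_record(bad), "waveform mean inconsistent")
  bad <- rec; bad$map_pressure <- 5
  expect_error(validate_patient_record(bad), "venous pressure")
})

test_that("a thrombosed cephalic vein makes cephalic configurations unsimulable", {
  rec <- degrade_patient(fixture_patient(), "thrombosed_cephalic")
  pers <- personalize_patient(rec)
  expect_error(build_domain("RC-AVF", rec$side, pers$geometries),
               "incomplete domain.*cephalic")
  expect_error(build_domain("BC-AVF", rec$side, pers$geometries),
               "incomplete domain.*cephalic")
  expect_no_error(build_domain("BB-AVF", rec$side, pers$geometries))
  expect_no_error(build_domain("preoperative", rec$side, pers$geometries))
})

test_that("a small radial artery fails the calibre screen", {
  rec <- degrade_patient(fixture_patient(), "small_radial")
  expect_identical(unname(caliber_screen(rec)["radial"]), "inadequate")
})

test_that("a missing station falls back to constant extrapolation", {
  rec <- degrade_patient(fixture_patient(), "missing_station")
  dus <- rec$dus_diameters
  st <- dus[dus$vessel_id == "distal_ulnar", ]
  expect_identical(nrow(st), 1L)
  pers <- personalize_patient(rec)
  g <- pers$geometries$distal_ulnar
  f <- interpolate_diameters(g$diameter_profile, g$length)
  expect_equal(f(0), f(g$length)) # constant profile
  expect_no_error(build_domain("preoperative", rec$side, pers$geometries))
})

test_that("patient records round-trip through the YAML schema", {
  rec <- fixture_patient()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_patient_record(rec, path)
  back <- read_patient_record(path)
  expect_identical(back$patient_id, rec$patient_id)
  expect_identical(back$side, rec$side)
  expect_equal(back$mean_flows, rec$mean_flows, tolerance = 1e-9)
  expect_equal(back$dus_diameters$diameter, rec$dus_diameters$diameter,
               tolerance = 1e-9)
  expect_equal(back$aortic_flow_waveform, rec$aortic_flow_waveform,
               tolerance = 1e-9)
  expect_error(read_patient_record(write_uncertainty_spec(
    default_uncertainty_spec(rec), withr::local_tempfile(fileext = ".yaml"))),
    "not a patient record")
})

test_that("uncertainty specifications round-trip through YAML", {
  spec <- default_uncertainty_spec(fixture_patient())
  path <- withr::local_tempfile(fileext = ".yaml")
  write_uncertainty_spec(spec, path)
  back <- read_uncertainty_spec(path)
  expect_identical(back$path, spec$path)
  expect_equal(back$half_width, spec$half_width, tolerance = 1e-12)
  expect_identical(back$relative, spec$relative)
})

test_that("network domain specifications round-trip through YAML", {
  pers <- fixture_personalization()
  rec <- fixture_patient()
  pre <- fixture_preop()
  net <- attach_terminals(build_domain("RC-AVF", rec$side, pers$geometries),
                          pre$wk)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network(net, path)
  back <- read_network(path)
  expect_identical(back$configuration, net$configuration)
  expect_equal(back$branches$R, net$branches$R, tolerance = 1e-9)
  expect_equal(back$terminals$R_wk, net$terminals$R_wk, tolerance = 1e-9)
  expect_equal(back$anastomosis$elem$angle, net$anastomosis$elem$angle)
})

test_that("waveform CSV helpers round-trip", {
  wf <- fixture_patient()$aortic_flow_waveform
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(wf, path)
  expect_equal(read_waveform_csv(path), wf, tolerance = 1e-9)
})

test_that("the command-line synth subcommand writes reproducible cohorts", {
  cli <- system.file("cli", "avfplan.R", package = "avfplan")
  expect_true(nzchar(cli))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  run <- function(dir) {
    system2("Rscript", c(cli, "synth", "--out", dir, "--n", "2",
                         "--seed", "11"),
            stdout = TRUE, stderr = TRUE, env = env)
  }
  run(d1); run(d2)
  f1 <- file.path(d1, "patient-01.yaml"); f2 <- file.path(d2, "patient-01.yaml")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(file.path(d1, "provenance.json")))
  rec <- read_patient_record(f1)
  expect_s3_class(rec, "patient_record")
})
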