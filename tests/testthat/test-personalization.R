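# Diameter interpolation, wall thickness, stiffness from distensibility,
# geometric scaling, anastomosis placement, calibre screening, windkessels.

test_that("diameter interpolation is linear, continuous and reproduces stations", {
  f <- interpolate_diameters(data.frame(position = c(0, 10),
                                        diameter = c(3, 4)), 10)
  expect_equal(f(5), 3.5)
  expect_equal(f(c(0, 10)), c(3, 4))

  # single station: constant everywhere
  f1 <- interpolate_diameters(data.frame(position = 5, diameter = 3), 10)
  expect_equal(f1(c(0, 5, 10)), c(3, 3, 3))

  # linear extrapolation, checked against an independent least-squares fit
  st <- data.frame(position = c(0, 10), diameter = c(4, 3))
  fit <- lm(diameter ~ position, data = st)
  f2 <- interpolate_diameters(st, 20)
  expect_equal(f2(20), unname(predict(fit, data.frame(position = 20))),
               tolerance = 1e-12)
  expect_equal(f2(20), 2)

  # continuity at stations
  st3 <- data.frame(position = c(0, 4, 10), diameter = c(4, 2.5, 3))
  f3 <- interpolate_diameters(st3, 10)
  expect_equal(f3(4 - 1e-9), f3(4 + 1e-9), tolerance = 1e-6)

  # extrapolation floor prevents nonphysical diameters
  expect_equal(f2(40), 0.5)

  expect_error(interpolate_diameters(data.frame(position = numeric(0),
                                                diameter = numeric(0)),
                                     10, vessel_id = "radial"),
               "missing vessel measurement: radial")
})

test_that("wall thickness applies the fixed ratios and is homogeneous in radius", {
  expect_equal(wall_thickness("axillary_brachial", 2.0), 0.30)
  expect_equal(wall_thickness("left_subclavian", 2.0), 0.30)
  expect_equal(wall_thickness("radial", 1.5), 0.30)
  expect_equal(wall_thickness("interosseus", 1.0), 0.20)
  expect_equal(wall_thickness("distal_cephalic", 2.0), 0.20)
  expect_equal(wall_thickness("basilic", 2.0), 0.20)
  for (v in c("radial", "thoracic_aorta", "proximal_cephalic")) {
    expect_equal(wall_thickness(v, 3.4), 2 * wall_thickness(v, 1.7),
                 tolerance = 1e-12)
  }
  expect_error(wall_thickness("femoral", 2), "unknown vessel")
})

test_that("Young's modulus inverts a prescribed distensibility exactly", {
  period <- 1
  tt <- seq(0, period, length.out = 200)
  p <- 80 + 40 * (1 + sin(2 * pi * tt - pi / 2)) / 2 # 80..120 mmHg
  D <- 1.2e-3 # 1/mmHg
  d0 <- 4.2
  dw <- data.frame(time = tt, diameter = d0 * sqrt(1 + D * (p - min(p))))
  pw <- data.frame(time = tt, pressure = p)
  h <- 0.15 * d0 / 2
  E <- youngs_modulus_from_distensibility(dw, pw, wall_thickness = h)
  E_expected <- 3 / (2 * D * 0.15) * 133.322 / 1000 # kPa
  expect_equal(E, E_expected, tolerance = 1e-6)

  # more distension at fixed pulse pressure means a softer wall
  dw2 <- data.frame(time = tt, diameter = d0 * sqrt(1 + 2 * D * (p - min(p))))
  expect_lt(youngs_modulus_from_distensibility(dw2, pw, wall_thickness = h), E)

  dw0 <- data.frame(time = tt, diameter = rep(d0, length(tt)))
  expect_error(youngs_modulus_from_distensibility(dw0, pw, wall_thickness = h),
               "rigid vessel")
})

test_that("the brachial modulus is applied to all arterial arm segments", {
  pers <- fixture_personalization()
  for (v in c("axillary_brachial", "radial", "proximal_ulnar",
              "distal_ulnar", "interosseus")) {
    expect_equal(pers$geometries[[v]]$youngs_modulus, pers$arm_E)
  }
  lit <- literature_geometry()
  expect_equal(pers$geometries$thoracic_aorta$youngs_modulus,
               lit$E_kPa[lit$vessel_id == "thoracic_aorta"])
  expect_equal(pers$geometries$basilic$youngs_modulus,
               lit$E_kPa[lit$vessel_id == "basilic"])
})

test_that("aortic geometry scales multiplicatively with the measured subclavian", {
  lit <- literature_geometry()
  lit_subcl <- lit$diameter_mm[lit$vessel_id == "left_subclavian"]
  dus <- data.frame(vessel_id = "left_subclavian", position = 1.7,
                    diameter = lit_subcl)
  s1 <- scale_aortic_geometry(lit, dus, "left")
  expect_equal(attr(s1, "factor"), 1)
  expect_equal(s1[["thoracic_aorta"]],
               lit$diameter_mm[lit$vessel_id == "thoracic_aorta"])

  dus$diameter <- 1.10 * lit_subcl
  s2 <- scale_aortic_geometry(lit, dus, "left")
  expect_equal(as.vector(s2), as.vector(s1) * 1.10, tolerance = 1e-12)
})

test_that("venous lengths equal the arterial lengths at the same level", {
  lit <- literature_geometry()
  len <- function(v) lit$length_cm[lit$vessel_id == v]
  expect_equal(len("distal_cephalic"), len("radial"))
})

test_that("anastomosis placement is 5 cm proximal to the wrist or elbow", {
  g <- list(radial = vessel_geometry("radial", 22,
                                     data.frame(position = 0, diameter = 2.8),
                                     0.2, 900),
            axillary_brachial = vessel_geometry(
              "axillary_brachial", 40,
              data.frame(position = 0, diameter = 5), 0.15, 900))
  rc <- place_anastomosis("RC-AVF", g)
  expect_identical(rc$artery, "radial")
  expect_equal(rc$position, 17)
  expect_equal(rc$angle, 45)
  expect_equal(rc$angle_range, c(30, 60))
  bc <- place_anastomosis("BC-AVF", g)
  expect_identical(bc$artery, "axillary_brachial")
  expect_equal(bc$position, 35)

  g$radial <- vessel_geometry("radial", 4,
                              data.frame(position = 0, diameter = 2.8),
                              0.2, 900)
  expect_error(place_anastomosis("RC-AVF", g), "shorter than")
})

test_that("the calibre screen uses the station minimum with strict inequality", {
  rec <- fixture_patient()
  rec$dus_diameters <- data.frame(
    vessel_id = c("distal_cephalic", "distal_cephalic",
                  "radial", "radial", "basilic"),
    position = c(5, 20, 1, 20, 5),
    diameter = c(2.5, 2.2, 1.8, 2.4, 2.0)
  )
  sc <- caliber_screen(rec)
  expect_identical(unname(sc["distal_cephalic"]), "adequate")
  expect_identical(unname(sc["radial"]), "inadequate") # min 1.8 <= 2
  expect_identical(unname(sc["basilic"]), "inadequate") # exactly 2.0
})

test_that("terminal resistance follows Ohm's law when upstream vessels are wide", {
  rec <- fixture_patient()
  rec$map_pressure <- 100
  rec$mean_flows <- c(aorta = rec$mean_flows[["aorta"]],
                      brachial = 100, radial = 60, ulnar = 40)
  # inflate every measured vessel so the serial viscous resistance vanishes
  wide <- as.list(setNames(rep(20, length(unique(rec$dus_diameters$vessel_id))),
                           unique(rec$dus_diameters$vessel_id)))
  pers <- personalize_patient(rec, overrides = list(diameter_scale = wide))
  net <- build_domain("preoperative", rec$side, pers$geometries)
  wk <- personalize_windkessels(net, 100, rec$mean_flows, venous_pressure = 10)
  r_radial <- wk$Z_wk[wk$vessel_id == "radial"] + wk$R_wk[wk$vessel_id == "radial"]
  expect_equal(r_radial, (100 - 10) / 1.0, tolerance = 5e-3) # 60 ml/min = 1 ml/s
  expect_equal(wk$Z_wk / (wk$Z_wk + wk$R_wk), rep(0.1, nrow(wk)),
               tolerance = 1e-9)
  expect_equal(wk$R_wk * wk$C_wk, rep(1.5, nrow(wk)), tolerance = 1e-9)
})

test_that("arm terminal flow targets sum to the brachial flow", {
  pre <- fixture_preop()
  res <- pre$result
  rec <- fixture_patient()
  arm_terms <- vessel_mean_flow(res, "radial") +
    vessel_mean_flow(res, "distal_ulnar") +
    vessel_mean_flow(res, "interosseus")
  expect_equal(arm_terms, rec$mean_flows[["brachial"]], tolerance = 5e-3)
})

test_that("inconsistent measurements are rejected", {
  pre <- fixture_preop()
  rec <- fixture_patient()
  bad <- rec$mean_flows
  bad["brachial"] <- bad["aorta"] * 1.5
  expect_error(personalize_windkessels(pre$network, rec$map_pressure, bad),
               "inconsistent measurements")
  # a vanishing perfusion pressure leaves no room for the modeled segments
  expect_error(personalize_windkessels(pre$network, rec$venous_pressure + 0.1,
                                       rec$mean_flows),
               "inconsistent measurements")
})
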