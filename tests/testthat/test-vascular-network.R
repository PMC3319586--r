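# Discretization, element formulas and domain construction.

test_that("segment count follows the ceiling rule and conserves length", {
  set.seed(11)
  for (len in c(5, 12, runif(40, 0.1, 100))) {
    g <- vessel_geometry("radial", len,
                         data.frame(position = 0, diameter = 3), 0.2, 900)
    segs <- discretize_vessel(g)
    expect_identical(nrow(segs), as.integer(ceiling(len / 5)))
    expect_equal(sum(segs$seg_length), len, tolerance = 1e-9)
    expect_true(all(segs$seg_length <= 5 + 1e-12))
    expect_equal(length(unique(segs$seg_length)), 1L)
  }
})

test_that("midpoint diameters come from linear interpolation of the profile", {
  g <- vessel_geometry("radial", 12,
                       data.frame(position = c(0, 12), diameter = c(4, 3)),
                       0.2, 900)
  segs <- discretize_vessel(g)
  expect_equal(segs$midpoint, c(2, 6, 10))
  expect_equal(segs$diameter, 4 - (4 - 3) / 12 * c(2, 6, 10),
               tolerance = 1e-12)
  expect_equal(segs$diameter, c(3.833333333, 3.5, 3.166666667),
               tolerance = 1e-8)
})

test_that("element values match an independent hand calculation", {
  # 5 cm, 4 mm, h/r 0.15, E 900 kPa, mu 3e-3 Pa.s, rho 1000 kg/m^3:
  # R = 8 mu l/(pi r^4) = 2.387324e7 Pa.s/m^3 = 0.17906453 mmHg.s/ml
  # L = rho l/(pi r^2) = 3.978874e6 Pa.s^2/m^3 = 0.029844089 mmHg.s^2/ml
  # C = 3 pi r^3 l/(2 E h) = 6.981317e-12 m^3/Pa = 9.3076315e-4 ml/mmHg
  el <- segment_elements(5, 4, 0.15, 900, blood_properties())
  expect_equal(el$R, 0.1790645315, tolerance = 1e-8)
  expect_equal(el$L, 0.0298440886, tolerance = 1e-8)
  expect_equal(el$C, 9.307631461e-4, tolerance = 1e-8)
})

test_that("elements obey the transmission-line scaling laws", {
  blood <- blood_properties()
  base <- segment_elements(5, 4, 0.15, 900, blood)
  # doubling diameter: R / 16, L / 4
  d2 <- segment_elements(5, 8, 0.15, 900, blood)
  expect_equal(d2$R, base$R / 16, tolerance = 1e-12)
  expect_equal(d2$L, base$L / 4, tolerance = 1e-12)
  # zero length: all elements vanish
  z <- segment_elements(0, 4, 0.15, 900, blood)
  expect_identical(c(z$R, z$L, z$C), c(0, 0, 0))
  # random sweep: R ~ l/d^4, L ~ l/d^2, C ~ l d^3/(E h), h = ratio * d/2
  set.seed(21)
  k0 <- NULL
  for (i in 1:25) {
    l <- runif(1, 0.5, 10); d <- runif(1, 1, 20)
    hr <- runif(1, 0.05, 0.45); E <- runif(1, 100, 2000)
    el <- segment_elements(l, d, hr, E, blood)
    k <- c(el$R * d^4 / l, el$L * d^2 / l,
           el$C * E * (hr * d / 2) / (l * d^3))
    if (is.null(k0)) k0 <- k else expect_equal(k, k0, tolerance = 1e-9)
  }
})

test_that("serial composition of equal segments preserves the total elements", {
  g <- vessel_geometry("radial", 23, data.frame(position = 0, diameter = 2.8),
                       0.2, 900)
  segs <- discretize_vessel(g)
  whole <- segment_elements(23, 2.8, 0.2, 900, blood_properties())
  expect_equal(sum(segs$R), whole$R, tolerance = 1e-9)
  expect_equal(sum(segs$L), whole$L, tolerance = 1e-9)
  expect_equal(sum(segs$C), whole$C, tolerance = 1e-9)
})

test_that("anastomosis pressure drop is odd, quadratic and linear in K", {
  el <- anastomosis_element(45, venous_limb_area = 5, distal_limb_area = 4)
  expect_identical(anastomosis_pressure_drop(el, 0, "venous"), 0)
  set.seed(31)
  for (q in runif(10, -30, 30)) {
    dp <- anastomosis_pressure_drop(el, q, "venous")
    expect_equal(anastomosis_pressure_drop(el, -q, "venous"), -dp,
                 tolerance = 1e-12)
    expect_true(dp * q >= 0)
  }
  # quadratic growth
  expect_equal(anastomosis_pressure_drop(el, 20, "venous"),
               4 * anastomosis_pressure_drop(el, 10, "venous"),
               tolerance = 1e-12)
  # doubling K doubles the drop
  el2 <- anastomosis_element(45, 5, 4, K30 = 1.2, K60 = 2.4)
  expect_equal(anastomosis_pressure_drop(el2, 10, "venous"),
               2 * anastomosis_pressure_drop(el, 10, "venous"),
               tolerance = 1e-12)
  # K interpolates linearly in the angle
  expect_equal(el$loss_coefficients$venous, 0.9)
  expect_equal(anastomosis_element(30, 5, 4)$loss_coefficients$venous, 0.6)
  expect_equal(anastomosis_element(60, 5, 4)$loss_coefficients$venous, 1.2)
})

test_that("build_domain is deterministic and respects the configuration", {
  pers <- fixture_personalization()
  rec <- fixture_patient()
  n1 <- build_domain("RC-AVF", rec$side, pers$geometries)
  n2 <- build_domain("RC-AVF", rec$side, pers$geometries)
  expect_identical(n1, n2)
  expect_false(is.null(n1$anastomosis))
  expect_identical(n1$anastomosis$host, "radial")

  pre <- build_domain("preoperative", rec$side, pers$geometries)
  expect_null(pre$anastomosis)
  expect_false(any(pre$branches$vessel_id %in%
                     c("distal_cephalic", "median_cubital",
                       "proximal_cephalic", "basilic",
                       "axillary_subclavian_vein")))
  # the venous trajectory ends at the external prescribed-pressure node
  expect_true(any(n1$branches$to == 0))
  expect_false(any(pre$branches$to == 0))
})

test_that("a missing required vessel raises an incomplete-domain error", {
  pers <- fixture_personalization()
  rec <- fixture_patient()
  g <- pers$geometries
  g$basilic <- NULL
  expect_error(build_domain("BB-AVF", rec$side, g),
               "incomplete domain: basilic vein")
  expect_no_error(build_domain("RC-AVF", rec$side, g))
  g$distal_cephalic <- NULL
  expect_error(build_domain("RC-AVF", rec$side, g),
               "incomplete domain: distal cephalic vein")
})

test_that("geometry and element validation rejects nonphysical inputs", {
  expect_error(vessel_geometry("radial", -1,
                               data.frame(position = 0, diameter = 3),
                               0.2, 900), "length")
  expect_error(vessel_geometry("radial", 10,
                               data.frame(position = 0, diameter = -3),
                               0.2, 900), "diameters")
  expect_error(vessel_geometry("radial", 10,
                               data.frame(position = 12, diameter = 3),
                               0.2, 900), "stations")
  expect_error(vessel_geometry("radial", 10,
                               data.frame(position = 0, diameter = 3),
                               0.6, 900), "wall thickness")
  expect_error(segment_elements(5, 0, 0.15, 900), "diameter")
  expect_error(anastomosis_element(120, 5, 4), "angle")
})
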