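# Helical-spring rigidities and equivalent beam moduli.

test_that("loop count follows the tight-winding closure", {
  expect_equal(loops_from_length(0.0381, 0.0381), 1)
  expect_equal(loops_from_length(100, 0.0381), 100 / 0.0381,
               tolerance = 1e-12)
  # linearity in l
  expect_equal(loops_from_length(200, 0.0381),
               2 * loops_from_length(100, 0.0381))
  expect_error(loops_from_length(-1, 0.0381), "positive")
  expect_error(loops_from_length(10, 0), "positive")
})

test_that("spring rigidities match independent arithmetic and scale correctly", {
  wire <- wire_spec(axium$D1, axium$Ew, axium$Gw)
  sec <- secondary_spec(axium$D2, l = 100, wire = wire)
  rig <- spring_rigidities(wire, sec)
  # frozen from direct evaluation of the closed forms (l = n D1)
  expect_equal(rig$Dcomp, 3.301825e-2, tolerance = 1e-5)
  expect_equal(rig$Dshear, 9.261217e-2, tolerance = 1e-5)
  expect_equal(rig$Dflex, 8.222783e-4, tolerance = 1e-5)
  # the shear/compressive ratio is exactly Ew/Gw
  expect_equal(rig$Dshear / rig$Dcomp, axium$Ew / axium$Gw,
               tolerance = 1e-14)
  # doubling n at fixed l halves all three rigidities
  sec2 <- secondary_spec(axium$D2, l = 100, n = 2 * sec$n, wire = wire)
  rig2 <- spring_rigidities(wire, sec2)
  expect_equal(rig2$Dcomp, rig$Dcomp / 2, tolerance = 1e-12)
  expect_equal(rig2$Dflex, rig$Dflex / 2, tolerance = 1e-12)
  # equal moduli: Dshear = Dcomp and Dflex reduces to E D1^4 l/(48 n D2)
  wr <- wire_spec(0.05, 100, 99.9999)
  sc <- secondary_spec(0.4, l = 50, wire = wr)
  rg <- spring_rigidities(wr, sc)
  expect_equal(rg$Dshear, rg$Dcomp, tolerance = 1e-4)
  expect_equal(rg$Dflex, 1e3 * 100 * 0.05^4 * 50 / (48 * sc$n * 0.4),
               tolerance = 1e-4)
})

test_that("rigidities scale as D1^5 under the tight-winding closure", {
  k <- vapply(c(1, 2), function(s) {
    w <- wire_spec(axium$D1 * s, axium$Ew, axium$Gw)
    sec <- secondary_spec(axium$D2 * 10, l = 100, wire = w)
    spring_rigidities(w, sec)$Dcomp
  }, numeric(1))
  expect_equal(k[2] / k[1], 2^5, tolerance = 1e-10)
  # with n fixed (closure broken) the scaling is D1^4
  k4 <- vapply(c(1, 2), function(s) {
    w <- wire_spec(axium$D1 * s, axium$Ew, axium$Gw)
    sec <- secondary_spec(axium$D2 * 10, l = 100, n = 500, wire = w)
    spring_rigidities(w, sec)$Dcomp
  }, numeric(1))
  expect_equal(k4[2] / k4[1], 2^4, tolerance = 1e-10)
})

test_that("beam sections follow the closed-form annulus/disc formulas", {
  s1 <- beam_section(axium$D1, axium$D2, "ANNULUS_OUTER_D2")
  expect_equal(s1$Ab, 3.0403e-2, tolerance = 1e-4)
  expect_equal(s1$Ib, 2.5072e-4, tolerance = 2e-4)
  expect_equal(s1$J, 2 * s1$Ib)
  s2 <- beam_section(axium$D1, axium$D2, "ANNULUS_AROUND_D2")
  expect_equal(s2$Ib, 5.458e-4, tolerance = 1e-3)
  # D1 = D2/2 degenerates the outer annulus to a solid disc
  s3 <- beam_section(0.2, 0.4, "ANNULUS_OUTER_D2")
  s4 <- beam_section(0.2, 0.4, "SOLID_D2")
  expect_equal(s3$Ab, s4$Ab, tolerance = 1e-12)
  expect_equal(s3$Ib, s4$Ib, tolerance = 1e-12)
  expect_error(beam_section(0.3, 0.4, "ANNULUS_OUTER_D2"),
               "ANNULUS_OUTER_D2")
})

test_that("equivalent moduli reproduce the printed coil values", {
  props <- coil_beam_properties(axium$D1, axium$D2, l = 100,
                                Ew = axium$Ew, Gw = axium$Gw)
  # flexural calibration (annulus around D2) vs printed 1.52e-3 GPa
  expect_equal(props$material$Eb, 1.52e-3, tolerance = 0.015)
  # shear calibration (solid D2, lambda = 0.75) vs printed 1.85e-3 GPa
  expect_equal(props$material$Gb, 1.85e-3, tolerance = 0.01)
  # both Eb candidates are recorded
  expect_equal(props$material$Eb_flex, props$material$Eb)
  expect_true(props$material$Eb_axial > 0)
  # five orders of magnitude softer than the platinum wire
  expect_equal(round(log10(axium$Ew / props$material$Eb)), 5)
  # unit case of the shear equation
  rig <- structure(list(Dcomp = 1, Dshear = 1, Dflex = 1),
                   class = "spring_rigidities")
  sec <- structure(list(convention = "SOLID_D2", Ab = 1, Ib = 1, J = 2,
                        lam = 1), class = "beam_section")
  em <- equivalent_moduli(rig, sec)
  expect_equal(em$Gb, 1e-3, tolerance = 1e-12)
})

test_that("effective density conserves coil mass per unit length", {
  wire <- wire_spec(axium$D1, axium$Ew, axium$Gw, rho_w = 21.45)
  sec <- secondary_spec(axium$D2, l = 100, wire = wire)
  sect <- beam_section(axium$D1, axium$D2, "ANNULUS_OUTER_D2")
  d <- effective_density(wire, sec, sect)
  # (pi/4 D1^2) * (pi (D2-D1)/D1) * rho_w
  expect_equal(d$mass_per_length, 0.512, tolerance = 1e-3)
  expect_equal(d$rho_eff * sect$Ab, d$mass_per_length, tolerance = 1e-12)
  # linear in the wire density
  d2 <- effective_density(wire_spec(axium$D1, axium$Ew, axium$Gw,
                                    rho_w = 42.9), sec, sect)
  expect_equal(d2$rho_eff, 2 * d$rho_eff, tolerance = 1e-12)
})

test_that("coil specification files round-trip through YAML and JSON", {
  spec <- list(d1_mm = 0.0381, d2_mm = 0.2921, d3_mm = 5, length_cm = 2,
               E_wire_gpa = 230, G_wire_gpa = 82)
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(spec, fy)
  sp <- read_coil_spec(fy)
  expect_equal(sp$D3, 5)
  expect_equal(sp$l, 20)  # cm converted to mm
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(spec, fj, auto_unbox = TRUE)
  sp2 <- read_coil_spec(fj)
  expect_equal(sp2$l, sp$l)
  expect_error(coil_spec(D3 = 0.2, l = 10), "D3")
})
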