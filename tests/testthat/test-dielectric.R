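test_that("structural constants follow from geometry and materials", {
  sc <- structural_constants(sensor_geometry(), material_constants())
  expect_equal(sc$B, 1000 / 600)            # density ratio
  expect_lt(sc$A, 0)                        # water dominates grain permittivity
  expect_gt(sc$D, 0)
  expect_gt(sc$F_const, 0)

  # vanishing-solid limit: as pore ratio -> 1, A and D vanish and the cell
  # tends to the air-only capacitance F
  sc1 <- structural_constants(sensor_geometry(pore_ratio = 1 - 1e-9),
                              material_constants())
  expect_lt(abs(sc1$A) / abs(sc$A), 1e-8)
  expect_lt(sc1$D / sc$D, 1e-8)
  expect_equal(capacitance_from_moisture(0.5, sc1), sc1$F_const,
               tolerance = 1e-6)

  expect_error(sensor_geometry(pore_ratio = 1), "pore_ratio")
  expect_error(sensor_geometry(plate_area = 0), "plate_area")
  expect_error(sensor_geometry(plate_spacing = -1), "plate_spacing")
  expect_error(material_constants(eps_water = 2), "eps_water > eps_cereal")
})

test_that("closed form matches the volume-fraction mixing oracle", {
  set.seed(42)
  for (k in 1:200) {
    geom <- random_geometry()
    mat <- random_materials()
    sc <- structural_constants(geom, mat)
    w <- runif(1, 0, 0.99)
    expect_equal(capacitance_from_moisture(w, sc),
                 oracle_capacitance(w, geom, mat),
                 tolerance = 1e-12)
  }
})

test_that("physical limits match the two-phase closed forms", {
  geom <- sensor_geometry()
  mat <- material_constants()
  sc <- structural_constants(geom, mat)
  k <- geom$plate_area * mat$eps0 / geom$plate_spacing
  e <- geom$pore_ratio
  # dry grain + air
  expect_equal(capacitance_from_moisture(0, sc),
               k * ((1 - e) * mat$eps_cereal + e * mat$eps_air),
               tolerance = 1e-14)
  # all water + air (open limit)
  expect_equal(capacitance_from_moisture(1 - 1e-12, sc),
               k * ((1 - e) * mat$eps_water + e * mat$eps_air),
               tolerance = 1e-9)
  expect_equal(unname(capacitance_range(sc)),
               c(capacitance_from_moisture(0, sc), sc$D + sc$F_const))
})

test_that("capacitance is strictly increasing in moisture", {
  sc <- structural_constants()
  cc <- capacitance_from_moisture(seq(0.01, 0.99, by = 0.01), sc)
  expect_true(all(diff(cc) > 0))
})

test_that("moisture_from_capacitance is the exact inverse", {
  set.seed(7)
  for (k in 1:1000) {
    sc <- structural_constants(random_geometry(), random_materials())
    w <- runif(1, 0, 0.999)
    w_back <- moisture_from_capacitance(capacitance_from_moisture(w, sc), sc)
    expect_lt(abs(w_back - w), 1e-10)
  }
  sc <- structural_constants()
  expect_equal(moisture_from_capacitance(sc$c_dry, sc), 0)
  expect_error(moisture_from_capacitance(sc$c_dry * 0.5, sc),
               "attainable interval")
  expect_error(moisture_from_capacitance(sc$c_wet, sc), "attainable interval")
  expect_error(capacitance_from_moisture(1, sc), "\\[0, 1\\)")
})

test_that("empirical linear calibration reproduces its printed coefficients", {
  expect_equal(linear_calibration(0), 17.28085)
  expect_equal(linear_calibration(1) - linear_calibration(0), 0.30744)
  expect_equal(linear_calibration(10), 20.35525)
  expect_error(linear_calibration(101), "\\[0, 100\\]")
  expect_error(linear_calibration(-1), "\\[0, 100\\]")
})
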