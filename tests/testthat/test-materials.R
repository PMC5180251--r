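test_that("power-law properties evaluate a*r^b + c and reject bad radii", {
  rho_law <- power_law_property(8900, 0.08, -5.93)
  E_law <- power_law_property(223e9, 0.082)

  expect_equal(eval_power_law(rho_law, 1.0), 8894.07)
  expect_equal(eval_power_law(E_law, 1.0), 223e9)
  # frozen against 20-digit arbitrary-precision evaluation
  expect_equal(eval_power_law(rho_law, 0.8), 8736.6014964653348,
               tolerance = 1e-12)
  expect_equal(eval_power_law(E_law, 0.9), 221081676281.58821,
               tolerance = 1e-12)

  expect_error(eval_power_law(rho_law, 0), "positive")
  expect_error(eval_power_law(rho_law, -1), "positive")
})

test_that("grading law hits the constituents exactly at both surfaces for any index", {
  law <- grading_law(material_dacron(), material_pu(), index = 1)
  for (n in c(0.2, 0.5, 1, 2, 5)) {
    law <- grading_law(material_dacron(), material_pu(), index = n)
    at0 <- grade(law, 0); at1 <- grade(law, 1)
    expect_identical(at0$E, 1.9e6)
    expect_identical(at0$nu, 0.37)
    expect_identical(at0$rho, 1380)
    expect_identical(at1$E, 25e6)
    expect_identical(at1$nu, 0.49)
    expect_identical(at1$rho, 1200)
  }
  # linear midpoint
  expect_equal(grade(grading_law(material_dacron(), material_pu(), 1), 0.5)$E,
               13.45e6)
})

test_that("graded modulus is monotone in xi and in the index", {
  xi <- seq(0, 1, length.out = 41)
  for (n in c(0.2, 0.5, 1, 2, 5)) {
    E <- grade(grading_law(material_dacron(), material_pu(), n), xi)$E
    expect_true(all(diff(E) > 0))
  }
  # at fixed interior xi, xi^n decreases with n, pulling E toward the inner value
  Es <- vapply(c(0.2, 0.5, 1, 2, 5), function(n)
    grade(grading_law(material_dacron(), material_pu(), n), 0.3)$E, 0)
  expect_true(all(diff(Es) < 0))
})

test_that("grading law rejects out-of-range coordinates and indexes", {
  law <- grading_law(material_dacron(), material_pu(), 1)
  expect_error(grade(law, -0.01), "\\[0, 1\\]")
  expect_error(grade(law, 1.01), "\\[0, 1\\]")
  expect_error(grading_law(material_dacron(), material_pu(), 0), "> 0")
  expect_error(grading_law(material_dacron(), material_pu(), -2), "> 0")
})

test_that("layered wall partitions [0,1] with half-open layers and a closed top", {
  w <- layered_wall(list(material("intima", 1e6, 0.45, 1090),
                         material("media", 2e6, 0.45, 1090),
                         material("adventitia", 3e6, 0.45, 1090)))
  expect_equal(w$fractions, c(0.1, 0.6, 0.3))
  expect_identical(layer_property(w, 0)$name, "intima")
  expect_identical(layer_property(w, 0.05)$name, "intima")
  expect_identical(layer_property(w, 0.1)$name, "media")   # half-open boundary
  expect_identical(layer_property(w, 0.7)$name, "adventitia")
  expect_identical(layer_property(w, 1.0)$name, "adventitia")
  # every xi maps to exactly one layer
  xi <- seq(0, 1, length.out = 101)
  names <- vapply(xi, function(x) layer_property(w, x)$name, "")
  expect_true(all(names %in% c("intima", "media", "adventitia")))
  expect_error(layer_property(w, 1.5), "\\[0, 1\\]")
  expect_error(layered_wall(list(steel()), fractions = c(0.9)), "sum to 1")
})

test_that("material validation catches invalid properties and caps nu = 0.5", {
  expect_error(material("x", E = -1, nu = 0.3, rho = 1000), "positive")
  expect_error(material("x", E = 1e6, nu = 0.6, rho = 1000), "0, 0.5")
  expect_error(material("x", E = 1e6, nu = 0.3, rho = 0), "positive")
  expect_warning(m <- material("wall", E = 1e6, nu = 0.5, rho = 1090),
                 "capped")
  expect_equal(m$nu, 0.4995)
})

test_that("radial property field dispatches all wall models consistently", {
  r <- seq(0.8, 1.0, length.out = 5)
  hom <- radial_property_field(homogeneous_wall(steel()), r, 0.8, 1.0)
  expect_equal(hom$E, rep(200e9, 5))

  lin <- radial_property_field(grading_law(material_dacron(), material_pu(), 1),
                               r, 0.8, 1.0)
  expect_equal(lin$E, seq(1.9e6, 25e6, length.out = 5))

  pl <- radial_property_field(validation_wall(), r, 0.8, 1.0)
  expect_equal(pl$E, 223e9 * r^0.082)
  expect_equal(pl$rho, 8900 * r^0.08 - 5.93)

  expect_error(radial_property_field(homogeneous_wall(steel()),
                                     numeric(0), 0.8, 1.0), "empty")
  expect_error(radial_property_field(homogeneous_wall(steel()),
                                     c(0.7, 0.9), 0.8, 1.0), "outside")
})
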