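test_that("half-sine inlet pressure reproduces amplitude, zeros and period", {
  expect_equal(sinusoid_pressure(0.5, 16000), 16000)
  expect_equal(sinusoid_pressure(0, 16000), 0)
  expect_equal(sinusoid_pressure(1 / 6, 16000), 8000)
  w <- waveform_sinusoid(16000)
  t <- seq(0, 2, by = 0.05)
  expect_equal(eval_waveform(w, t), eval_waveform(w, t + 2))  # 2 s period
  expect_error(waveform_sinusoid(0), "> 0")
  expect_error(sinusoid_pressure(-0.1), "non-negative")
})

test_that("tabulated waveforms interpolate linearly and extend periodically", {
  w <- waveform_tabulated(c(0, 0.25, 0.5, 0.75), c(0, 100, 50, 10),
                          period = 1, seam_tol = 0.2)
  expect_equal(eval_waveform(w, 0.125), 50)
  expect_equal(eval_waveform(w, 1.25), 100)
  expect_error(waveform_tabulated(c(0, 0.2, 0.1), c(0, 1, 2)), "increasing")
  expect_error(waveform_tabulated(c(0, 0.5), c(0, 1000)), "seam")
})

test_that("Poiseuille gradient matches the closed form and its limits", {
  expect_equal(poiseuille_gradient(0, 0.0035, 0.0168), 0)
  expect_equal(poiseuille_gradient(1e-4, 0, 0.0168), 0)
  # frozen against arbitrary-precision arithmetic
  expect_equal(poiseuille_gradient(1e-4, 0.0035, 0.0168), -11.188478502190479,
               tolerance = 1e-12)
  expect_error(poiseuille_gradient(1e-4, 0.0035, 0), "positive")
})

test_that("thin-wall stress, strain and wall shear follow their definitions", {
  expect_equal(thinwall_hoop_stress(0, 0.0168, 0.00232), 0)
  expect_equal(thinwall_hoop_stress(16000, 0.0168, 0.00232), 115862.06896551724,
               tolerance = 1e-12)
  expect_equal(thinwall_hoop_stress(32000, 0.0168, 0.00232),
               2 * thinwall_hoop_stress(16000, 0.0168, 0.00232))
  expect_equal(hoop_strain(0.0168, 0.0168), 0)
  expect_equal(hoop_strain(1.1 * 0.0168, 0.0168), 0.1)
  expect_equal(hoop_strain(0.0184, 0.0168), 0.095238095238095238,
               tolerance = 1e-12)
  expect_equal(wall_shear(0.0035, 0, 0.01), 0)
  expect_equal(wall_shear_from_Q(0.0035, 11.91), 0.041685)
  expect_equal(wall_shear(2 * 0.0035, 1, 0.01), 2 * wall_shear(0.0035, 1, 0.01))
  expect_error(wall_shear(0.0035, 1, 0), "positive")
  expect_error(thinwall_hoop_stress(1, 1, 0), "positive")
})

test_that("equilibrium radius solves the distension balance and matches bisection", {
  fp <- aorta_flow_params()
  expect_equal(equilibrium_radius(0, fp), fp$r_in)
  # rigid limit
  fp_rigid <- flow_params(E_in = 1e15, r_in = 0.0168, r_out = 0.01912)
  expect_equal(equilibrium_radius(16000, fp_rigid), 0.0168, tolerance = 1e-9)
  # independent bisection oracle on the balance residual
  P <- 2000
  resid <- function(r) P * r / fp$t_wall - fp$E_in * (r - fp$r_in) / fp$r_in
  r_bis <- uniroot(resid, c(fp$r_in, 2 * fp$r_in), tol = 1e-14)$root
  expect_equal(equilibrium_radius(P, fp), r_bis, tolerance = 1e-10)
  # residual changes sign across the root (uniqueness on the validity interval)
  expect_gt(resid(fp$r_in), 0)
  expect_lt(resid(2 * fp$r_in), 0)
  # beyond the distension limit
  expect_error(equilibrium_radius(fp$E_in * fp$t_wall / fp$r_in * 1.01, fp),
               "distension")
})

test_that("zero flow or zero viscosity reproduces the inlet waveform everywhere", {
  w <- waveform_sinusoid(16000)
  x <- seq(0, 0.05, length.out = 11)
  t <- seq(0, 1, by = 0.1)
  for (fp in list(flow_params(E_in = 1.9e6, r_in = 0.0168, r_out = 0.01912, Q_vol = 0),
                  flow_params(mu = 0, E_in = 1.9e6, r_in = 0.0168, r_out = 0.01912))) {
    P <- axial_pressure_profile(w, fp, x, t)
    expect_equal(P, matrix(rep(eval_waveform(w, t), each = 11), 11, 11),
                 ignore_attr = TRUE)
  }
})

test_that("axial profile is non-increasing in x and converges under march refinement", {
  w <- waveform_sinusoid(16000)
  fp <- aorta_flow_params()
  x <- seq(0, 0.05, length.out = 21)
  P <- axial_pressure_profile(w, fp, x, c(0.3, 0.5))
  expect_true(all(diff(P[, 1]) <= 0))
  expect_true(all(diff(P[, 2]) <= 0))
  # fine fourth-order march vs coarse: self-convergence within 0.1%
  P_coarse <- axial_pressure_profile(w, fp, x, 0.5, n_march = 20)
  P_fine <- axial_pressure_profile(w, fp, x, 0.5, n_march = 400)
  expect_lt(max(abs(P_coarse - P_fine)) / max(abs(P_fine)), 1e-3)
  # periodicity of the sinusoid-driven field
  P2 <- axial_pressure_profile(w, fp, x, c(0.3, 0.5) + 2)
  expect_equal(P, P2, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("reconstructed exponential decay mode matches the inlet scale and decays", {
  w <- waveform_sinusoid(16000)
  fp <- aorta_flow_params()
  x <- seq(0, 0.05, length.out = 11)
  P <- axial_pressure_profile(w, fp, x, 0.5, mode = "exponential")
  expect_equal(P[1, 1], 16000)
  expect_true(all(diff(P[, 1]) < 0))
  tau <- wall_shear_from_Q(fp$mu, fp$Q_shear)
  expect_equal(P[11, 1], 16000 * exp(-2 * tau * 0.05 / (fp$E_in * fp$t_wall)))
})
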