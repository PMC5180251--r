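test_that("zero pressure and zero gravity give the zero solution", {
  scn <- small_scenario()
  sol <- solve_static(scn, 0)
  expect_equal(max(abs(sol$u_r)), 0, tolerance = 1e-18)
  expect_equal(max(abs(sol$s_tt)), 0, tolerance = 1e-9)
})

test_that("Lame closed form satisfies its own boundary conditions", {
  geo <- vessel_geometry(0.8, 1.0, 2)
  lam <- lame_solution(geo, 200e9, 0.3, 16000, r = c(0.8, 1.0))
  expect_equal(lam$s_rr[1], -16000)
  expect_equal(lam$s_rr[2], 0, tolerance = 1e-9)
  # frozen closed-form hoop stress at the bore
  expect_equal(lam$s_tt[1], 72888.888888888889, tolerance = 1e-12)
})

test_that("static homogeneous solve matches Lame at mid-length of a slender cylinder", {
  # slenderness L/h = 40: the clamped-end bending boundary layer
  # (length ~ sqrt(r h) ~ 0.4 m) has decayed by mid-length
  for (m in list(c("dqm", 13, 25), c("fd", 41, 121))) {
    scn <- scenario(vessel_geometry(0.8, 1.0, 8), homogeneous_wall(steel()),
                    waveform_sinusoid(16000),
                    solver = list(method = m[1], n_r = as.integer(m[2]),
                                  n_z = as.integer(m[3])))
    sol <- solve_static(scn, 16000)
    iz <- which.min(abs(sol$z - 4))
    lam <- lame_solution(scn$geometry, 200e9, 0.3, 16000, r = sol$r)
    expect_lt(max(abs(sol$u_r[, iz, 1] - lam$u_r)) / max(abs(lam$u_r)), 0.01)
    expect_lt(max(abs(sol$s_tt[, iz, 1] - lam$s_tt)) / max(abs(lam$s_tt)), 0.01)
  }
})

test_that("recovered tractions honour the boundary conditions after a dynamic solve", {
  scn <- small_scenario(t_end = 0.3)
  sol <- solve_scenario(scn)
  nz <- length(sol$z); nt <- length(sol$t)
  interior_z <- 2:(nz - 1)
  P_t <- eval_waveform(scn$loading, sol$t)
  smax <- max(abs(sol$s_tt), abs(sol$s_rr), abs(sol$s_zz))
  # inner surface carries -P, outer surface is traction free
  for (k in c(2, nt)) {
    expect_lt(max(abs(sol$s_rr[1, interior_z, k] + P_t[k])), 1e-6 * smax)
    expect_lt(max(abs(sol$s_rr[length(sol$r), interior_z, k])), 1e-6 * smax)
    expect_lt(max(abs(sol$s_rz[1, interior_z, k])), 1e-6 * smax)
    expect_lt(max(abs(sol$s_rz[length(sol$r), interior_z, k])), 1e-6 * smax)
  }
  # clamped ends
  expect_equal(max(abs(sol$u_r[, c(1, nz), ])), 0, tolerance = 1e-12)
  expect_equal(max(abs(sol$u_z[, c(1, nz), ])), 0, tolerance = 1e-12)
})

test_that("response is linear in the load amplitude", {
  scn1 <- small_scenario(t_end = 0.2)
  scn2 <- small_scenario(t_end = 0.2)
  scn2$loading <- waveform_sinusoid(32000)
  s1 <- solve_scenario(scn1)
  s2 <- solve_scenario(scn2)
  expect_equal(max(abs(s2$u_r)), 2 * max(abs(s1$u_r)),
               tolerance = 1e-10)
  expect_equal(max(abs(s2$s_tt)), 2 * max(abs(s1$s_tt)),
               tolerance = 1e-10)
})

test_that("solution is z-symmetric for symmetric loading and clamped ends", {
  sol <- solve_scenario(small_scenario(n_z = 13, t_end = 0.2))
  nz <- length(sol$z)
  flip <- nz:1
  expect_equal(sol$u_r, sol$u_r[, flip, ], tolerance = 1e-8)
  expect_equal(sol$u_z, -sol$u_z[, flip, ], tolerance = 1e-8)
})

test_that("the two discretizations converge toward each other under refinement", {
  e_coarse <- static_cross_error(c(9, 15), c(21, 81))
  e_fine <- static_cross_error(c(13, 21), c(41, 161))
  expect_true(all(e_fine < e_coarse))
})

test_that("Newmark stepper: zero load stays at rest, constant load relaxes to statics", {
  K <- Matrix::Matrix(rbind(c(2, -1), c(-1, 2)), sparse = TRUE)
  mass <- c(1, 1)
  st <- newmark_stepper(K, mass, dt = 0.05)
  state <- st$init(c(0, 0))
  for (i in 1:50) state <- st$step(state, c(0, 0))
  expect_equal(state$u, c(0, 0))

  # stiffness-proportional damping drives the response to K^-1 F
  std <- newmark_stepper(K, mass, dt = 0.05, rayleigh = c(0.5, 0.5))
  F <- c(1, 0)
  state <- std$init(F)
  for (i in 1:2000) state <- std$step(state, F)
  expect_equal(state$u, as.numeric(Matrix::solve(K, F)), tolerance = 1e-6)
})

test_that("undamped average-acceleration stepping keeps the discrete energy bounded", {
  K <- Matrix::Matrix(rbind(c(2, -1), c(-1, 2)), sparse = TRUE)
  mass <- c(1, 1)
  st <- newmark_stepper(K, mass, dt = 0.05)
  state <- list(u = c(1, 0.5), v = c(0, 0), a = -as.numeric(K %*% c(1, 0.5)))
  energy <- function(s) 0.5 * sum(s$v^2) + 0.5 * sum(s$u * as.numeric(K %*% s$u))
  e0 <- energy(state)
  # three periods of the slowest mode (omega = 1, T = 2 pi)
  drift <- replicate(ceiling(3 * 2 * pi / 0.05), {
    state <<- st$step(state, c(0, 0)); energy(state)
  })
  expect_lt(max(abs(drift - e0)) / e0, 0.01)
})

test_that("halving the time step changes the validation response by well under 1%", {
  s1 <- solve_scenario(validation_scenario("dqm", 9, 13, dt = 0.01, L = 2))
  s2 <- solve_scenario(validation_scenario("dqm", 9, 13, dt = 0.005, L = 2))
  k1 <- length(s1$t); k2 <- length(s2$t)
  expect_equal(s1$t[k1], s2$t[k2])
  iz <- (length(s1$z) + 1) %/% 2
  # compare the mid-length radial displacement profile at the final time
  ref <- max(abs(s1$u_r))
  expect_lt(max(abs(s1$u_r[, iz, k1] - s2$u_r[, iz, k2])) / ref, 0.01)
})

test_that("non-finite growth is reported as an instability naming the step", {
  K <- Matrix::Matrix(diag(2), sparse = TRUE)
  st <- newmark_stepper(K, c(1, 1), dt = 0.1)
  state <- st$init(c(0, 0))
  expect_error(st$step(state, c(NaN, 0), label = "7"), "non-finite.*7")
})
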