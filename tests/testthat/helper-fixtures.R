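# shared fixtures: small, fast configurations used across test files

steel <- function() material("steel", E = 200e9, nu = 0.3, rho = 7800)

small_scenario <- function(method = "dqm", n_r = 9, n_z = 13, L = 2,
                           material = homogeneous_wall(steel()),
                           t_end = 0.2, dt = 0.01, gravity = 0) {
  scenario(vessel_geometry(0.8, 1.0, L), material, waveform_sinusoid(16000),
           gravity = gravity,
           time = list(start = 0, end = t_end, dt = dt),
           solver = list(method = method, n_r = n_r, n_z = n_z))
}

small_aorta <- function(method = "dqm", t_end = 0.3, ...) {
  aorta_scenario(method = method, t_end = t_end, ...)
}

# static mid-thickness cross-solver discrepancy at a given resolution pair
static_cross_error <- function(dqm_grid, fd_grid, scn_fun = validation_scenario,
                               P = 16000) {
  dq <- solve_static(scn_fun("dqm", dqm_grid[1], dqm_grid[2]), P)
  fd <- solve_static(scn_fun("fd", fd_grid[1], fd_grid[2]), P)
  solution_discrepancy(fd, dq)
}
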