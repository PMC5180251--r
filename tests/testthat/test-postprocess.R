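test_that("von Mises stress has the closed-form values and invariances", {
  expect_equal(von_mises(5, 5, 5, 0), 0)            # hydrostatic
  expect_equal(von_mises(7, 0, 0, 0), 7)            # uniaxial
  expect_equal(von_mises(-1, 2, 0, 0), sqrt(7))     # frozen arithmetic
  # invariant under adding any hydrostatic state
  s <- c(3e4, -1e4, 2e4, 5e3)
  for (p in c(-1e5, 1e5)) {
    expect_equal(von_mises(s[1] + p, s[2] + p, s[3] + p, s[4]),
                 von_mises(s[1], s[2], s[3], s[4]))
  }
  # plane principal states: |s1 - s2| pattern with s3 = (s1+s2)/2 removed
  expect_equal(von_mises(10, -10, 0, 0), sqrt(300))
  expect_gte(min(von_mises(rnorm(50), rnorm(50), rnorm(50), rnorm(50))), 0)
})

test_that("nondimensionalization matches the defined scales and round-trips", {
  sol <- solve_scenario(small_scenario(t_end = 0.2))
  scales <- nondim_scales(te = 2, L = 2, r_i = 0.8, h = 0.2, P0 = 16000)
  nd <- nondim(sol, scales)
  expect_equal(nd$T, sol$t / 2)
  expect_equal(nd$Z, sol$z / 2)
  expect_equal(nd$R, sol$r / 0.8)
  expect_equal(nd$S_tt, sol$s_tt / 16000)
  # frozen worked value: u_r = 1e-6 m with K = 10 GPa, P0 = 16 kPa, h = 0.2 m
  one <- sol; one$u_r[] <- 1e-6
  expect_equal(nondim(one, scales)$Ur[1], 3.125)
  # round trip is the identity within 1e-12 relative
  back <- redim(nd)
  expect_equal(back$u_r, sol$u_r, tolerance = 1e-12)
  expect_equal(back$s_zz, sol$s_zz, tolerance = 1e-12)
  expect_equal(back$t, sol$t, tolerance = 1e-12)
  expect_error(nondim_scales(te = 0, L = 1, r_i = 1, h = 1, P0 = 1), "positive")
})

test_that("profile extraction is nearest-node and bit-stable", {
  sol <- solve_scenario(small_scenario(t_end = 0.2))
  ir <- 3; iz <- 5; it <- length(sol$t)
  p <- extract_profile(sol, "u_r", "length",
                       at = list(r = sol$r[ir], t = sol$t[it]))
  expect_identical(p$u_r, sol$u_r[ir, , it])      # stored values, untouched
  expect_equal(attr(p, "at")$r, sol$r[ir])
  # fixed ends: length profile vanishes at both ends
  expect_equal(p$u_r[c(1, length(sol$z))], c(0, 0))
  # thickness profile of s_rr runs from -P at the bore to ~0 outside
  pt <- extract_profile(sol, "s_rr", "thickness",
                        at = list(z = sol$z[iz], t = sol$t[it]))
  P_t <- eval_waveform(sol$scenario$loading, sol$t[it])
  expect_equal(pt$s_rr[1], -P_t, tolerance = 1e-6 * max(abs(sol$s_tt)))
  expect_lt(abs(pt$s_rr[length(sol$r)]), 1e-6 * max(abs(sol$s_tt)))
  # von Mises profile is available as a derived field
  pv <- extract_profile(sol, "von_mises", "thickness",
                        at = list(z = sol$z[iz], t = sol$t[it]))
  expect_equal(pv$von_mises,
               von_mises(sol$s_rr[, iz, it], sol$s_tt[, iz, it],
                         sol$s_zz[, iz, it], sol$s_rz[, iz, it]))
  expect_error(extract_profile(sol, "u_r", "time", at = list(r = 2)), "outside")
})

test_that("peak times pick the discrete argmax with earliest-tie-break", {
  t <- seq(0, 1, by = 0.01)
  expect_equal(peak_times(t, sin(pi * t)), 0.5)
  tri <- c(0, 1, 2, 3, 2, 1, 0)
  expect_equal(peak_times(seq_along(tri), tri), 4)
  two <- c(0, 5, 1, 5, 0)
  expect_equal(peak_times(seq_along(two), two), 2)  # earlier of two maxima
  expect_warning(out <- peak_times(1:5, rep(2, 5)), "no unique peak")
  expect_true(is.na(out))
})
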