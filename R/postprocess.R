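#' Nondimensionalization scales
#'
#' Scales used to report dimensionless results: time by the loading
#' duration `te`, axial position by the length `L`, radius by the internal
#' radius `r_i`, radial displacement as `Ur = u_r * K / (P0 * h)` with the
#' fixed stress scale `K = 10 GPa`, and stresses as `S_i = sigma_i / P0`.
#'
#' @param te loading duration, s.
#' @param L vessel length, m.
#' @param r_i internal radius, m.
#' @param h wall thickness, m.
#' @param P0 pressure scale, Pa.
#' @param K stress scale, Pa (fixed 10 GPa by convention).
#' @return An object of class `fgm_scales`.
#' @export
nondim_scales <- function(te, L, r_i, h, P0, K = 1e10) {
  vals <- c(te = te, L = L, r_i = r_i, h = h, P0 = P0, K = K)
  if (any(vals <= 0)) stop("all nondimensionalization scales must be positive", call. = FALSE)
  structure(as.list(vals), class = "fgm_scales")
}

#' Nondimensionalize a field solution
#'
#' @param sol an `fgm_solution`.
#' @param scales an [nondim_scales()].
#' @return list with dimensionless grids `T`, `Z`, `R` and fields `Ur`,
#'   `S_rr`, `S_tt`, `S_zz`, `S_rz`; carries the scales for [redim()].
#' @export
nondim <- function(sol, scales) {
  stopifnot(inherits(scales, "fgm_scales"))
  s <- scales
  structure(list(
    T = sol$t / s$te, Z = sol$z / s$L, R = sol$r / s$r_i,
    Ur = sol$u_r * s$K / (s$P0 * s$h),
    S_rr = sol$s_rr / s$P0, S_tt = sol$s_tt / s$P0,
    S_zz = sol$s_zz / s$P0, S_rz = sol$s_rz / s$P0,
    scales = s), class = "fgm_nondim")
}

#' Re-dimensionalize a nondimensional field set
#'
#' Exact inverse of [nondim()].
#'
#' @param nd an `fgm_nondim`.
#' @return list with `t`, `z`, `r`, `u_r` and the four stress fields in SI.
#' @export
redim <- function(nd) {
  stopifnot(inherits(nd, "fgm_nondim"))
  s <- nd$scales
  list(t = nd$T * s$te, z = nd$Z * s$L, r = nd$R * s$r_i,
       u_r = nd$Ur * s$P0 * s$h / s$K,
       s_rr = nd$S_rr * s$P0, s_tt = nd$S_tt * s$P0,
       s_zz = nd$S_zz * s$P0, s_rz = nd$S_rz * s$P0)
}

#' von Mises equivalent stress
#'
#' For the axisymmetric stress state (radial, circumferential, axial and
#' the r-z shear component):
#' \deqn{\sigma_{vM} = \sqrt{\tfrac12\left[(\sigma_{rr}-\sigma_{\theta\theta})^2
#'  + (\sigma_{\theta\theta}-\sigma_{zz})^2 + (\sigma_{zz}-\sigma_{rr})^2\right]
#'  + 3\sigma_{rz}^2}.}
#' Invariant under adding a hydrostatic state; equals the applied stress
#' for a uniaxial state.
#'
#' @param s_rr,s_tt,s_zz,s_rz stress components, Pa (vectorized).
#' @return equivalent stress, Pa, >= 0.
#' @export
von_mises <- function(s_rr, s_tt, s_zz, s_rz = 0) {
  sqrt(((s_rr - s_tt)^2 + (s_tt - s_zz)^2 + (s_zz - s_rr)^2) / 2 + 3 * s_rz^2)
}

nearest_index <- function(grid, value) {
  which.min(abs(grid - value))[1]
}

#' Extract a 1D profile from a field solution
#'
#' Nearest-node extraction (no interpolation, so values match the stored
#' field bit-for-bit): a profile of any stored field along the vessel
#' length, through the wall thickness, or in time, at fixed values of the
#' remaining coordinates. "Mid-thickness" is the node closest to
#' `(r_in + r_out) / 2`.
#'
#' @param sol an `fgm_solution`.
#' @param field field name: one of `"u_r"`, `"u_z"`, `"s_rr"`, `"s_tt"`,
#'   `"s_zz"`, `"s_rz"`, `"von_mises"`.
#' @param axis profile direction: `"length"`, `"thickness"` or `"time"`.
#' @param at named list fixing the other coordinates, e.g.
#'   `list(r = 0.018, t = 2.2)`; each must lie inside the corresponding
#'   grid range.
#' @return data.frame with the running coordinate and the field value;
#'   the fixed (snapped) coordinates are recorded as attributes `at`.
#' @export
extract_profile <- function(sol, field = "u_r",
                            axis = c("length", "thickness", "time"),
                            at = list()) {
  axis <- match.arg(axis)
  grids <- list(r = sol$r, z = sol$z, t = sol$t)
  for (nm in names(at)) {
    g <- grids[[nm]]
    if (at[[nm]] < min(g) - 1e-12 || at[[nm]] > max(g) + 1e-12) {
      stop(sprintf("coordinate %s = %g outside the solution domain", nm, at[[nm]]),
           call. = FALSE)
    }
  }
  vals <- if (field == "von_mises") {
    von_mises(sol$s_rr, sol$s_tt, sol$s_zz, sol$s_rz)
  } else {
    sol[[field]]
  }
  pick <- function(nm, default) {
    if (!is.null(at[[nm]])) nearest_index(grids[[nm]], at[[nm]])
    else nearest_index(grids[[nm]], default)
  }
  mid_r <- (min(sol$r) + max(sol$r)) / 2
  mid_z <- (min(sol$z) + max(sol$z)) / 2
  snapped <- list()
  if (axis == "length") {
    ir <- pick("r", mid_r); it <- pick("t", max(sol$t))
    out <- data.frame(z = sol$z, value = vals[ir, , it])
    snapped <- list(r = sol$r[ir], t = sol$t[it])
  } else if (axis == "thickness") {
    iz <- pick("z", mid_z); it <- pick("t", max(sol$t))
    out <- data.frame(r = sol$r, value = vals[, iz, it])
    snapped <- list(z = sol$z[iz], t = sol$t[it])
  } else {
    ir <- pick("r", mid_r); iz <- pick("z", mid_z)
    out <- data.frame(t = sol$t, value = vals[ir, iz, ])
    snapped <- list(r = sol$r[ir], z = sol$z[iz])
  }
  names(out)[2] <- field
  attr(out, "at") <- snapped
  out
}

#' Times of the maxima of a time series
#'
#' Discrete argmax with plateau ties broken to the earliest time.
#'
#' @param time sample times, s (>= 3 samples).
#' @param values series values.
#' @param tol values within `tol * diff(range(values))` of the maximum
#'   count as tied.
#' @return time of the (earliest) maximum, s; `NA` with a warning when the
#'   series is constant (no unique peak).
#' @export
peak_times <- function(time, values, tol = 0) {
  stopifnot(length(time) == length(values), length(time) >= 3)
  rng <- diff(range(values))
  if (rng == 0) {
    warning("constant series: no unique peak", call. = FALSE)
    return(NA_real_)
  }
  thr <- max(values) - tol * rng
  time[which(values >= thr)[1]]
}
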