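#' Inlet pressure waveforms
#'
#' Two inlet loading models are supported: the half-sine systolic surrogate
#' `P(t) = P0 sin(pi t)` (period 2 s), and an arbitrary tabulated waveform
#' (e.g. a digitized physiological pressure trace) interpolated linearly in
#' time and extended periodically.
#'
#' @param P0 amplitude, Pa, > 0.
#' @return An object of class `fgm_waveform`; call it via [eval_waveform()].
#' @examples
#' w <- waveform_sinusoid(16000)
#' eval_waveform(w, 0.5)  # 16000 Pa, systolic peak
#' @export
waveform_sinusoid <- function(P0 = 16000) {
  if (!is.finite(P0) || P0 <= 0) stop("amplitude P0 must be > 0", call. = FALSE)
  structure(list(kind = "sinusoid", P0 = P0, period = 2),
            class = "fgm_waveform")
}

#' @rdname waveform_sinusoid
#' @param time,value sample times (s, strictly increasing, starting at 0)
#'   and values (Pa or m/s).
#' @param period period of the periodic extension, s; defaults to the last
#'   sample time.
#' @param seam_tol maximum allowed jump between the last sample and the
#'   first sample of the next period, as a fraction of the value range.
#' @export
waveform_tabulated <- function(time, value, period = NULL, seam_tol = 0.05) {
  stopifnot(length(time) == length(value), length(time) >= 2)
  if (any(diff(time) <= 0)) stop("sample times must be strictly increasing", call. = FALSE)
  if (is.null(period)) period <- time[length(time)]
  if (period < time[length(time)]) stop("period shorter than the sample span", call. = FALSE)
  seam <- abs(value[length(value)] - value[1])
  rng <- diff(range(value))
  if (rng > 0 && seam > seam_tol * rng) {
    stop(sprintf(
      "periodic extension discontinuous at the seam (jump %.3g, %.1f%% of range)",
      seam, 100 * seam / rng), call. = FALSE)
  }
  structure(list(kind = "tabulated", time = time, value = value, period = period),
            class = "fgm_waveform")
}

#' Evaluate a waveform
#'
#' @param w an `fgm_waveform`.
#' @param t time(s), s, >= 0.
#' @return waveform value(s) at `t`.
#' @export
eval_waveform <- function(w, t) {
  stopifnot(inherits(w, "fgm_waveform"))
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  if (w$kind == "sinusoid") {
    sinusoid_pressure(t, w$P0)
  } else {
    tm <- t %% w$period
    tt <- w$time; vv <- w$value
    if (w$period > tt[length(tt)]) {   # close the period at the seam
      tt <- c(tt, w$period); vv <- c(vv, vv[1])
    }
    stats::approx(tt, vv, xout = tm, rule = 2)$y
  }
}

#' Half-sine inlet pressure
#'
#' `P(t) = P0 sin(pi t)`: a 1-second systolic upstroke-and-decay with a
#' 2-second period. Negative values during the second half-period are passed
#' through unchanged; callers clamp if their model requires.
#'
#' @param t time, s, >= 0.
#' @param P0 amplitude, Pa.
#' @return pressure, Pa.
#' @export
sinusoid_pressure <- function(t, P0 = 16000) {
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  P0 * sin(pi * t)
}

#' Reduced-order flow parameters
#'
#' Parameters of the lumen model. Note the two distinct flow quantities:
#' `Q_shear` (1/s) is the velocity-to-distance ratio entering the wall shear
#' relation tau = mu * Q_shear, while `Q_vol` (m^3/s) is the volumetric rate
#' driving the Poiseuille axial pressure gradient. They are never
#' interchangeable and are therefore separate fields; when `Q_vol` is
#' omitted it defaults to a mean inlet velocity `U` times the lumen area.
#'
#' @param mu dynamic viscosity, Pa s.
#' @param t_wall thin-wall thickness used by the distension closure, m.
#' @param E_in elastic modulus at the inner wall surface, Pa.
#' @param r_in,r_out lumen (inner-wall) and outer-wall radii, m.
#' @param Q_shear velocity-to-distance ratio, 1/s.
#' @param Q_vol volumetric flow rate, m^3/s; default `U * pi * r_in^2`.
#' @param U mean inlet velocity used for the `Q_vol` default, m/s.
#' @return An object of class `fgm_flow_params`.
#' @export
flow_params <- function(mu = 0.0035, t_wall = 0.00232, E_in, r_in, r_out,
                        Q_shear = 11.91, Q_vol = NULL, U = 0.1) {
  stopifnot(mu >= 0, t_wall > 0, r_out > r_in, r_in > 0, E_in > 0)
  if (is.null(Q_vol)) Q_vol <- U * pi * r_in^2
  structure(list(mu = mu, t_wall = t_wall, E_in = E_in, r_in = r_in,
                 r_out = r_out, Q_shear = Q_shear, Q_vol = Q_vol, U = U),
            class = "fgm_flow_params")
}

#' Poiseuille axial pressure gradient
#'
#' `dP/dx = -8 mu Q / (pi r^4)` for laminar Newtonian flow in a tube of
#' local radius r.
#'
#' @param Q_vol volumetric flow rate, m^3/s.
#' @param mu dynamic viscosity, Pa s.
#' @param r local lumen radius, m, > 0.
#' @return pressure gradient, Pa/m (negative for forward flow).
#' @export
poiseuille_gradient <- function(Q_vol, mu, r) {
  if (any(r <= 0)) stop("lumen radius must be positive", call. = FALSE)
  -8 * mu * Q_vol / (pi * r^4)
}

#' Thin-wall hoop stress
#'
#' `sigma = P r / t` for a pressurized thin-walled tube.
#'
#' @param P lumen pressure, Pa.
#' @param r local radius, m.
#' @param t_wall wall thickness, m, > 0.
#' @return circumferential stress, Pa.
#' @export
thinwall_hoop_stress <- function(P, r, t_wall) {
  if (any(t_wall <= 0)) stop("wall thickness must be positive", call. = FALSE)
  P * r / t_wall
}

#' Circumferential (hoop) strain
#'
#' `(r - r_in) / r_in`: relative distension of the lumen.
#'
#' @param r current radius, m.
#' @param r_in unloaded reference radius, m, > 0.
#' @return strain, dimensionless.
#' @export
hoop_strain <- function(r, r_in) {
  if (any(r_in <= 0)) stop("reference radius must be positive", call. = FALSE)
  (r - r_in) / r_in
}

#' Wall shear stress
#'
#' Couette estimate `tau = mu U / d` with U the near-wall flow velocity and
#' d the distance over which it develops; `wall_shear_from_Q()` uses the
#' velocity-to-distance ratio directly, `tau = mu * Q_shear`.
#'
#' @param mu dynamic viscosity, Pa s.
#' @param U flow velocity, m/s.
#' @param d distance travelled by the flow at the wall, m, > 0.
#' @return shear stress, Pa.
#' @export
wall_shear <- function(mu, U, d) {
  if (any(d <= 0)) stop("distance d must be positive", call. = FALSE)
  mu * U / d
}

#' @rdname wall_shear
#' @param Q_shear velocity-to-distance ratio U/d, 1/s.
#' @export
wall_shear_from_Q <- function(mu, Q_shear = 11.91) mu * Q_shear

#' Local distension equilibrium radius
#'
#' Solves the local static balance between pressure-induced thin-wall hoop
#' stress and linear-elastic strain, `P r / t = E_in (r - r_in) / r_in`,
#' for the loaded radius r(x). The balance is linear in r with the closed
#' form `r = E_in t r_in / (E_in t - P r_in)`, valid while
#' `P < E_in t / r_in` (beyond that the linear thin-wall model predicts
#' unbounded distension and the model is flagged invalid).
#'
#' @param P local lumen pressure, Pa (may be negative; the tube contracts).
#' @param params an [flow_params()] object.
#' @return loaded radius, m.
#' @export
equilibrium_radius <- function(P, params) {
  stopifnot(inherits(params, "fgm_flow_params"))
  Et <- params$E_in * params$t_wall
  denom <- Et - P * params$r_in
  if (any(denom <= 0)) {
    stop("pressure beyond the distension limit of the thin-wall balance",
         call. = FALSE)
  }
  Et * params$r_in / denom
}

#' Axial-and-time varying lumen pressure field
#'
#' For each requested time, marches the Poiseuille gradient
#' `dP/dx = -8 mu Q_vol / (pi r(x)^4)` downstream from the inlet value
#' `waveform(t)` with a classical fourth-order Runge-Kutta step, the local
#' radius r(x) closing the system either through the static distension
#' balance ([equilibrium_radius()]) or through a caller-supplied wall shape
#' (used by the fluid-structure coupling loop, where r comes from the
#' structural solve).
#'
#' An exponential-decay closed form
#' `P(x,t) = P0(t) exp(-2 tau x / (E_in t_wall))` is available as
#' `mode = "exponential"` for comparison; it is a reconstructed surrogate
#' profile, not the integrated model.
#'
#' @param waveform inlet [waveform_sinusoid()]/[waveform_tabulated()].
#' @param params [flow_params()].
#' @param x_grid increasing axial positions, m, starting at 0 (the inlet).
#' @param t_grid times, s.
#' @param radius_fn optional `function(x, P)` returning the local lumen
#'   radius, m; default uses [equilibrium_radius()].
#' @param n_march number of fixed RK4 substeps across the full length
#'   (default 200).
#' @param mode `"march"` (default) or `"exponential"`.
#' @return matrix P with `length(x_grid)` rows and `length(t_grid)` columns,
#'   with attributes `x` and `t`.
#' @export
axial_pressure_profile <- function(waveform, params, x_grid, t_grid,
                                   radius_fn = NULL, n_march = 200,
                                   mode = c("march", "exponential")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "fgm_flow_params"),
            length(x_grid) >= 1, length(t_grid) >= 1)
  if (x_grid[1] != 0) stop("axial grid must start at the inlet x = 0", call. = FALSE)
  if (any(diff(x_grid) <= 0) && length(x_grid) > 1) {
    stop("axial grid must be increasing", call. = FALSE)
  }
  L <- x_grid[length(x_grid)]
  P0t <- eval_waveform(waveform, t_grid)

  if (mode == "exponential") {
    tau <- wall_shear_from_Q(params$mu, params$Q_shear)
    decay <- exp(-2 * tau * x_grid / (params$E_in * params$t_wall))
    out <- outer(decay, P0t)
  } else if (params$Q_vol == 0 || params$mu == 0 || L == 0) {
    out <- matrix(rep(P0t, each = length(x_grid)),
                  nrow = length(x_grid))
  } else {
    if (is.null(radius_fn)) {
      radius_fn <- function(x, P) equilibrium_radius(P, params)
    }
    dPdx <- function(x, P) poiseuille_gradient(params$Q_vol, params$mu,
                                               radius_fn(x, P))
    h <- L / n_march
    xm <- seq(0, L, by = h)
    out <- matrix(0, length(x_grid), length(t_grid))
    for (k in seq_along(t_grid)) {
      P <- numeric(length(xm))
      P[1] <- P0t[k]
      for (i in seq_len(length(xm) - 1)) {
        x <- xm[i]; y <- P[i]
        k1 <- dPdx(x, y)
        k2 <- dPdx(x + h / 2, y + h * k1 / 2)
        k3 <- dPdx(x + h / 2, y + h * k2 / 2)
        k4 <- dPdx(x + h, y + h * k3)
        P[i + 1] <- y + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
      }
      out[, k] <- stats::approx(xm, P, xout = x_grid)$y
    }
  }
  dimnames(out) <- NULL
  attr(out, "x") <- x_grid
  attr(out, "t") <- t_grid
  out
}
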