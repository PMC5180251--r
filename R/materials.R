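#' Constituent material
#'
#' A linear-elastic isotropic biomaterial described by its elastic modulus,
#' Poisson's ratio and mass density.
#'
#' Poisson's ratio 0.5 (exact incompressibility, as quoted for the natural
#' aortic wall) makes the standard linear-elastic constitutive matrix
#' singular; such values are capped at `nu_cap` (default 0.4995) with a
#' warning, which reproduces the near-incompressible response without a
#' mixed formulation.
#'
#' @param name label for the material.
#' @param E elastic modulus, Pa. Must be positive.
#' @param nu Poisson's ratio, dimensionless, in (0, 0.5].
#' @param rho mass density, kg/m^3. Must be positive.
#' @param nu_cap effective upper bound applied to `nu`.
#' @return An object of class `fgm_material` with fields `name`, `E`, `nu`
#'   (possibly capped), `rho`.
#' @examples
#' pu <- material("PU", E = 25e6, nu = 0.49, rho = 1200)
#' dacron <- material("Dacron", E = 1.9e6, nu = 0.37, rho = 1380)
#' @export
material <- function(name, E, nu, rho, nu_cap = 0.4995) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(E) || E <= 0) stop("elastic modulus E must be positive", call. = FALSE)
  if (!is.finite(nu) || nu <= 0 || nu > 0.5) {
    stop("Poisson's ratio must lie in (0, 0.5]", call. = FALSE)
  }
  if (!is.finite(rho) || rho <= 0) stop("density rho must be positive", call. = FALSE)
  if (nu > nu_cap) {
    warning(sprintf("Poisson's ratio %.4f capped at %.4f (near-incompressible limit)",
                    nu, nu_cap), call. = FALSE)
    nu <- nu_cap
  }
  structure(list(name = name, E = E, nu = nu, rho = rho),
            class = "fgm_material")
}

#' @export
print.fgm_material <- function(x, ...) {
  cat(sprintf("<material '%s'>  E = %.4g Pa, nu = %.4g, rho = %.4g kg/m^3\n",
              x$name, x$E, x$nu, x$rho))
  invisible(x)
}

#' Power-law radial property
#'
#' Radial distribution of a scalar material property of the form
#' `a * r^b + c`, the family used for the graded validation wall
#' (density 8900 r^0.08 - 5.93 kg/m^3, modulus 223e9 r^0.082 Pa).
#'
#' @param a coefficient, in the property's units.
#' @param b dimensionless exponent.
#' @param c additive offset, in the property's units (default 0).
#' @return An object of class `fgm_power_law`.
#' @seealso [eval_power_law()]
#' @export
power_law_property <- function(a, b, c = 0) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  structure(list(a = a, b = b, c = c), class = "fgm_power_law")
}

#' Evaluate a power-law property at radius r
#'
#' @param law an [power_law_property()] object.
#' @param r radial coordinate(s), m; must be strictly positive.
#' @return `a * r^b + c`, vectorized over `r`.
#' @examples
#' rho_law <- power_law_property(8900, 0.08, -5.93)
#' eval_power_law(rho_law, 1.0)  # 8894.07 kg/m^3
#' @export
eval_power_law <- function(law, r) {
  stopifnot(inherits(law, "fgm_power_law"))
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("power law is only defined for positive radii", call. = FALSE)
  }
  law$a * r^law$b + law$c
}

#' Functionally graded material law
#'
#' Grades every property from an inner to an outer constituent across the
#' normalized wall-thickness coordinate xi in [0, 1] as
#' `p(xi) = p_inner + (p_outer - p_inner) * xi^n`, where `n > 0` is the
#' heterogeneous index controlling how steeply the transition happens.
#' The quadratic ("parabolic") profile is the special case `n = 2`; the
#' continuous family is what a sweep over the heterogeneous index requires.
#'
#' @param inner,outer [material()] objects at xi = 0 and xi = 1.
#' @param index heterogeneous index n, dimensionless, strictly positive.
#' @return An object of class `fgm_grading_law`.
#' @examples
#' law <- grading_law(material("Dacron", 1.9e6, 0.37, 1380),
#'                    material("PU", 25e6, 0.49, 1200), index = 0.2)
#' grade(law, 0)$E / 1e6  # 1.9 MPa, inner constituent exactly
#' @export
grading_law <- function(inner, outer, index = 1) {
  stopifnot(inherits(inner, "fgm_material"), inherits(outer, "fgm_material"))
  if (!is.finite(index) || index <= 0) {
    stop("heterogeneous index must be > 0", call. = FALSE)
  }
  structure(list(inner = inner, outer = outer, index = index),
            class = "fgm_grading_law")
}

#' Evaluate a grading law at a normalized thickness coordinate
#'
#' @param law a [grading_law()].
#' @param xi normalized thickness coordinate(s) in [0, 1]; 0 is the inner
#'   wall surface, 1 the outer.
#' @return list with numeric vectors `E` (Pa), `nu`, `rho` (kg/m^3).
#' @export
grade <- function(law, xi) {
  stopifnot(inherits(law, "fgm_grading_law"))
  if (any(!is.finite(xi)) || any(xi < 0) || any(xi > 1)) {
    stop("normalized thickness coordinate must lie in [0, 1]", call. = FALSE)
  }
  w <- xi^law$index
  # endpoints exact by construction: 0^n = 0, 1^n = 1 for n > 0
  blend <- function(p_in, p_out) p_in + (p_out - p_in) * w
  list(E   = blend(law$inner$E,   law$outer$E),
       nu  = blend(law$inner$nu,  law$outer$nu),
       rho = blend(law$inner$rho, law$outer$rho))
}

#' Layered vessel wall
#'
#' Piecewise-constant radial wall model: an ordered list of layers, each a
#' fraction of the total thickness with its own material. The default
#' fractions 0.1/0.6/0.3 follow the 1:6:3 thickness ratio of the intima,
#' media and adventitia of the natural arterial wall.
#'
#' @param materials list of [material()] objects, innermost first.
#' @param fractions numeric thickness fractions, strictly positive, summing
#'   to 1 (within 1e-12). Defaults to `c(0.1, 0.6, 0.3)` when three
#'   materials are supplied.
#' @return An object of class `fgm_layered_wall`.
#' @export
layered_wall <- function(materials, fractions = NULL) {
  stopifnot(is.list(materials), length(materials) >= 1L,
            all(vapply(materials, inherits, TRUE, "fgm_material")))
  if (is.null(fractions)) {
    if (length(materials) == 3L) {
      fractions <- c(0.1, 0.6, 0.3)
    } else {
      fractions <- rep(1 / length(materials), length(materials))
    }
  }
  if (length(fractions) != length(materials)) {
    stop("one thickness fraction per layer is required", call. = FALSE)
  }
  if (any(fractions <= 0)) stop("thickness fractions must be positive", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-12) {
    stop("thickness fractions must sum to 1", call. = FALSE)
  }
  structure(list(materials = materials, fractions = fractions),
            class = "fgm_layered_wall")
}

#' Look up the layer material at a normalized thickness coordinate
#'
#' Layer k occupies the half-open span `[cum_{k-1}, cum_k)` of the
#' normalized thickness; the last layer is closed at 1.
#'
#' @param wall a [layered_wall()].
#' @param xi normalized thickness coordinate in [0, 1] (scalar).
#' @return the [material()] of the layer containing `xi`.
#' @export
layer_property <- function(wall, xi) {
  stopifnot(inherits(wall, "fgm_layered_wall"), length(xi) == 1L)
  if (!is.finite(xi) || xi < 0 || xi > 1) {
    stop("normalized thickness coordinate must lie in [0, 1]", call. = FALSE)
  }
  edges <- cumsum(wall$fractions)
  k <- findInterval(xi, c(0, edges), rightmost.closed = TRUE,
                    left.open = FALSE)
  # findInterval with left-closed bins matches the half-open convention;
  # xi == 1 falls in the last bin because rightmost.closed = TRUE
  wall$materials[[min(k, length(wall$materials))]]
}

#' Homogeneous wall model
#'
#' @param mat a single [material()] used through the whole thickness.
#' @return An object of class `fgm_homogeneous`.
#' @export
homogeneous_wall <- function(mat) {
  stopifnot(inherits(mat, "fgm_material"))
  structure(list(material = mat), class = "fgm_homogeneous")
}

#' Power-law wall model
#'
#' Wall whose modulus and density follow [power_law_property()] laws of the
#' physical radius, with a constant Poisson's ratio — the configuration of
#' the graded validation cylinder.
#'
#' @param E_law,rho_law [power_law_property()] objects for modulus (Pa) and
#'   density (kg/m^3) as functions of the physical radius in m.
#' @param nu constant Poisson's ratio.
#' @return An object of class `fgm_power_law_wall`.
#' @export
power_law_wall <- function(E_law, rho_law, nu) {
  stopifnot(inherits(E_law, "fgm_power_law"), inherits(rho_law, "fgm_power_law"))
  if (!is.finite(nu) || nu <= 0 || nu > 0.5) {
    stop("Poisson's ratio must lie in (0, 0.5]", call. = FALSE)
  }
  structure(list(E_law = E_law, rho_law = rho_law, nu = min(nu, 0.4995)),
            class = "fgm_power_law_wall")
}

#' Radial property field over a grid
#'
#' Maps physical radii to the normalized thickness coordinate
#' `xi = (r - r_in) / (r_out - r_in)` and evaluates the wall model there,
#' returning nodal arrays of modulus, Poisson's ratio and density.
#'
#' @param model a [homogeneous_wall()], [grading_law()], [layered_wall()]
#'   or [power_law_wall()] object.
#' @param r numeric vector of radii, m, all inside `[r_in, r_out]`.
#' @param r_in,r_out wall inner/outer radii, m.
#' @return list of numeric vectors `E`, `nu`, `rho`, one value per node.
#' @export
radial_property_field <- function(model, r, r_in, r_out) {
  if (length(r) == 0L) stop("empty radius grid", call. = FALSE)
  stopifnot(r_out > r_in, r_in > 0)
  if (any(r < r_in - 1e-12) || any(r > r_out + 1e-12)) {
    stop("radius grid extends outside the wall", call. = FALSE)
  }
  xi <- pmin(pmax((r - r_in) / (r_out - r_in), 0), 1)
  if (inherits(model, "fgm_homogeneous")) {
    m <- model$material
    n <- length(r)
    list(E = rep(m$E, n), nu = rep(m$nu, n), rho = rep(m$rho, n))
  } else if (inherits(model, "fgm_grading_law")) {
    grade(model, xi)
  } else if (inherits(model, "fgm_layered_wall")) {
    mats <- lapply(xi, function(x) layer_property(model, x))
    list(E   = vapply(mats, `[[`, 0, "E"),
         nu  = vapply(mats, `[[`, 0, "nu"),
         rho = vapply(mats, `[[`, 0, "rho"))
  } else if (inherits(model, "fgm_power_law_wall")) {
    list(E   = eval_power_law(model$E_law, r),
         nu  = rep(model$nu, length(r)),
         rho = eval_power_law(model$rho_law, r))
  } else {
    stop("unknown wall material model", call. = FALSE)
  }
}

#' Reference constituents and property laws
#'
#' Convenience constructors for the configurations used throughout:
#' `material_pu()` and `material_dacron()` are the two graft constituents
#' (modulus in MPa: 25 and 1.9; Poisson 0.49 and 0.37; density 1200 and
#' 1380 kg/m^3); `validation_wall()` is the graded steel-like validation
#' cylinder wall (power-law density and modulus, Poisson 0.3).
#'
#' @return a [material()] or wall-model object.
#' @export
material_pu <- function() material("PU", E = 25e6, nu = 0.49, rho = 1200)

#' @rdname material_pu
#' @export
material_dacron <- function() material("Dacron", E = 1.9e6, nu = 0.37, rho = 1380)

#' @rdname material_pu
#' @export
validation_wall <- function() {
  power_law_wall(E_law   = power_law_property(223e9, 0.082),
                 rho_law = power_law_property(8900, 0.08, -5.93),
                 nu = 0.3)
}
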