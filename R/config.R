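#' Read and write scenario configuration files
#'
#' Scenarios are stored as structured YAML. Material definitions use the
#' keys `name`, `E_Pa`, `nu`, `rho_kg_m3`; grading settings live under
#' `material: {model: grading, grading: {index, inner, outer}}`; layered
#' walls under `material: {model: layered, layers: [{fraction, material}]}`.
#' Parsing and serialization round-trip exactly, and [scenario_hash()]
#' stamps outputs with a provenance fingerprint of the parsed scenario.
#'
#' @param path file path of the YAML config.
#' @return [read_scenario_config()] returns an [scenario()] (plus
#'   [flow_params()] as attribute `"flow"` when a `flow:` block is
#'   present); [write_scenario_config()] returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  scenario_from_config(cfg)
}

material_from_config <- function(m) {
  material(m$name %||% "material", E = m$E_Pa, nu = m$nu, rho = m$rho_kg_m3)
}

material_to_config <- function(m) {
  list(name = m$name, E_Pa = m$E, nu = m$nu, rho_kg_m3 = m$rho)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_scenario_config
#' @param cfg a list with the parsed configuration (as from
#'   `yaml::read_yaml`).
#' @export
scenario_from_config <- function(cfg) {
  g <- cfg$geometry
  geometry <- vessel_geometry(g$r_in_m, g$r_out_m, g$L_m)

  mt <- cfg$material
  mat <- switch(mt$model,
    homogeneous = homogeneous_wall(material_from_config(mt$homogeneous)),
    grading = grading_law(material_from_config(mt$grading$inner),
                          material_from_config(mt$grading$outer),
                          index = mt$grading$index),
    layered = layered_wall(
      lapply(mt$layers, function(l) material_from_config(l$material)),
      fractions = vapply(mt$layers, function(l) l$fraction, 0)),
    power_law = power_law_wall(
      power_law_property(mt$power_law$E$a, mt$power_law$E$b, mt$power_law$E$c %||% 0),
      power_law_property(mt$power_law$rho$a, mt$power_law$rho$b, mt$power_law$rho$c %||% 0),
      nu = mt$power_law$nu),
    stop("unknown material model: ", mt$model, call. = FALSE))

  ld <- cfg$loading
  loading <- if ((ld$waveform %||% "sinusoid") == "sinusoid") {
    waveform_sinusoid(ld$P0_Pa %||% 16000)
  } else {
    waveform_tabulated(ld$time_s, ld$value, period = ld$period_s)
  }

  scn <- scenario(geometry, mat, loading,
                  gravity = ld$gravity_m_s2 %||% 0,
                  time = list(start = cfg$time$start_s %||% 0,
                              end = cfg$time$end_s %||% 2,
                              dt = cfg$time$dt_s %||% 0.01),
                  solver = cfg$solver %||% list())
  if (!is.null(cfg$flow)) {
    fl <- cfg$flow
    attr(scn, "flow") <- flow_params(
      mu = fl$mu_Pa_s %||% 0.0035, t_wall = fl$t_wall_m %||% 0.00232,
      E_in = fl$E_in_Pa, r_in = geometry$r_in, r_out = geometry$r_out,
      Q_shear = fl$Q_shear_per_s %||% 11.91,
      Q_vol = fl$Q_vol_m3_s, U = fl$U_m_s %||% 0.2)
  }
  scn
}

#' @rdname read_scenario_config
#' @param scn an [scenario()].
#' @export
scenario_to_config <- function(scn) {
  mat <- scn$material
  mt <- if (inherits(mat, "fgm_homogeneous")) {
    list(model = "homogeneous", homogeneous = material_to_config(mat$material))
  } else if (inherits(mat, "fgm_grading_law")) {
    list(model = "grading",
         grading = list(index = mat$index,
                        inner = material_to_config(mat$inner),
                        outer = material_to_config(mat$outer)))
  } else if (inherits(mat, "fgm_layered_wall")) {
    list(model = "layered",
         layers = Map(function(f, m) list(fraction = f, material = material_to_config(m)),
                      mat$fractions, mat$materials))
  } else {
    list(model = "power_law",
         power_law = list(E = mat$E_law[c("a", "b", "c")],
                          rho = mat$rho_law[c("a", "b", "c")],
                          nu = mat$nu))
  }
  ld <- if (scn$loading$kind == "sinusoid") {
    list(waveform = "sinusoid", P0_Pa = scn$loading$P0,
         gravity_m_s2 = scn$gravity)
  } else {
    list(waveform = "tabulated", time_s = scn$loading$time,
         value = scn$loading$value, period_s = scn$loading$period,
         gravity_m_s2 = scn$gravity)
  }
  out <- list(
    geometry = list(r_in_m = scn$geometry$r_in, r_out_m = scn$geometry$r_out,
                    L_m = scn$geometry$L),
    material = mt,
    loading = ld,
    time = list(start_s = scn$time$start, end_s = scn$time$end,
                dt_s = scn$time$dt),
    solver = scn$solver)
  fl <- attr(scn, "flow")
  if (!is.null(fl)) {
    out$flow <- list(mu_Pa_s = fl$mu, t_wall_m = fl$t_wall, E_in_Pa = fl$E_in,
                     Q_shear_per_s = fl$Q_shear, Q_vol_m3_s = fl$Q_vol,
                     U_m_s = fl$U)
  }
  out
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(scn, path) {
  yaml::write_yaml(scenario_to_config(scn), path, precision = 15)
  invisible(path)
}

#' Provenance fingerprint of a scenario
#'
#' Polynomial rolling hash (mod 2^31 - 1) over the serialized scenario
#' configuration, written into output file headers so that every artifact
#' names the exact scenario that produced it.
#'
#' @param scn an [scenario()].
#' @return 8-hex-digit character scalar.
#' @export
scenario_hash <- function(scn) {
  bytes <- as.integer(serialize(scenario_to_config(scn), NULL, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647  # exact in doubles
  sprintf("%08x", h)
}
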