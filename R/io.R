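#' Read and write tabulated waveforms
#'
#' Two-column delimited text (`time_s`, `value`), the exchange format for
#' user-supplied physiological pressure or velocity traces.
#'
#' @param path file path.
#' @param w an `fgm_waveform` of kind "tabulated".
#' @return [read_waveform()] returns a [waveform_tabulated()];
#'   [write_waveform()] returns `path` invisibly.
#' @export
read_waveform <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  waveform_tabulated(d$time_s, d$value)
}

#' @rdname read_waveform
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "fgm_waveform"), w$kind == "tabulated")
  utils::write.table(data.frame(time_s = w$time, value = w$value),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a field solution as long-format delimited text
#'
#' One row per (r, z, t) node with all displacement and stress components;
#' the header records the solver and scenario fingerprint.
#'
#' @param sol an `fgm_solution`.
#' @param path output file path.
#' @param times optional subset of times to export (nearest stored slices).
#' @return `path`, invisibly.
#' @export
write_field_solution <- function(sol, path, times = NULL) {
  kt <- if (is.null(times)) seq_along(sol$t) else
    vapply(times, function(tv) nearest_index(sol$t, tv), 0L)
  rows <- do.call(rbind, lapply(kt, function(k) {
    data.frame(r_m = rep(sol$r, times = length(sol$z)),
               z_m = rep(sol$z, each = length(sol$r)),
               t_s = sol$t[k],
               u_r_m = as.vector(sol$u_r[, , k]),
               u_z_m = as.vector(sol$u_z[, , k]),
               s_rr_Pa = as.vector(sol$s_rr[, , k]),
               s_tt_Pa = as.vector(sol$s_tt[, , k]),
               s_zz_Pa = as.vector(sol$s_zz[, , k]),
               s_rz_Pa = as.vector(sol$s_rz[, , k]))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# solver: %s  scenario: %s", sol$solver,
                     scenario_hash(sol$scenario)), con)
  utils::write.table(rows, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a 1D profile as two-column delimited text
#'
#' The header names the fixed coordinates the profile was extracted at.
#'
#' @param profile a data.frame from [extract_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  at <- attr(profile, "at")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(at)) {
    writeLines(sprintf("# fixed: %s",
                       paste(sprintf("%s = %.8g", names(at), unlist(at)),
                             collapse = ", ")), con)
  }
  utils::write.table(profile, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a lumen pressure field as long-format delimited text
#'
#' @param P pressure matrix (nx x nt) with `x`/`t` attributes, as returned
#'   by [axial_pressure_profile()], or the `pressure` element of an
#'   [fsi_couple()] result together with explicit `x`, `t`.
#' @param path output file path.
#' @param x,t coordinate vectors when `P` carries no attributes.
#' @return `path`, invisibly.
#' @export
write_pressure_field <- function(P, path, x = attr(P, "x"), t = attr(P, "t")) {
  stopifnot(length(x) == nrow(P), length(t) == ncol(P))
  d <- data.frame(x_m = rep(x, times = length(t)),
                  t_s = rep(t, each = length(x)),
                  P_Pa = as.vector(P))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
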