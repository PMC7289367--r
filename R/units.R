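#' Physical scale constants of the VWF model
#'
#' The core of the package is dimensionless: shear enters as
#' \eqn{\tilde\tau = k \tau d / 4\sigma} and time as
#' \eqn{\tilde t = t / \sqrt{4 m_0 / 15 \sigma \pi}}, where `k` is the
#' dimensionless drag coefficient of the globule, `d` the subunit size,
#' `sigma` the effective surface-tension coefficient of the globule and `m0`
#' the subunit mass.  No physical defaults are provided — the model's source
#' gives no numeric values for these constants, so any physical-unit output is
#' conditional on user-supplied ones.  The derived scales are computed in the
#' constructor from the primitives (stress scale \eqn{4\sigma/(k d)}, time
#' scale \eqn{\sqrt{4 m_0 / 15 \sigma \pi}}) and the object is immutable, so
#' they can never go stale; either may also be supplied directly (e.g. by
#' [calibrate_stress_scale()], which pins only the stress scale).
#'
#' @param k Dimensionless drag coefficient (`> 0`).
#' @param d Subunit size, length units (`> 0`).
#' @param sigma Effective surface tension, force/length (`> 0`).
#' @param m0 Subunit mass (`> 0`).
#' @param stress_scale,time_scale Direct overrides; used when the primitives
#'   are unknown.
#' @return An object of class `vwf_physical_scale` with elements `k`, `d`,
#'   `sigma`, `m0`, `stress_scale`, `time_scale` (`NA` where underdetermined).
#' @export
physical_scale <- function(k = NULL, d = NULL, sigma = NULL, m0 = NULL,
                           stress_scale = NULL, time_scale = NULL) {
  chk <- function(x, name) {
    if (!is.null(x)) {
      if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
        abort(sprintf("`%s` must be a positive scalar.", name),
          class = "vwfdyn_domain_error"
        )
      }
    }
    x %||% NA_real_
  }
  k <- chk(k, "k")
  d <- chk(d, "d")
  sigma <- chk(sigma, "sigma")
  m0 <- chk(m0, "m0")
  stress_scale <- chk(stress_scale, "stress_scale")
  time_scale <- chk(time_scale, "time_scale")
  if (is.na(stress_scale) && !is.na(k) && !is.na(d) && !is.na(sigma)) {
    stress_scale <- 4 * sigma / (k * d)
  }
  if (is.na(time_scale) && !is.na(m0) && !is.na(sigma)) {
    time_scale <- sqrt(4 * m0 / (15 * sigma * pi))
  }
  structure(
    list(
      k = k, d = d, sigma = sigma, m0 = m0,
      stress_scale = stress_scale, time_scale = time_scale
    ),
    class = "vwf_physical_scale"
  )
}

#' @export
print.vwf_physical_scale <- function(x, ...) {
  cat("<vwf_physical_scale>\n")
  cat(sprintf(
    "  k = %s, d = %s, sigma = %s, m0 = %s\n",
    format(x$k), format(x$d), format(x$sigma), format(x$m0)
  ))
  cat(sprintf(
    "  stress scale 4*sigma/(k*d) = %s, time scale sqrt(4*m0/(15*sigma*pi)) = %s\n",
    format(x$stress_scale), format(x$time_scale)
  ))
  invisible(x)
}

need_scale <- function(scale, field) {
  if (is.null(scale) || !inherits(scale, "vwf_physical_scale") ||
    !is.finite(scale[[field]])) {
    abort(sprintf("a physical_scale with a finite `%s` is required.", field),
      class = "vwfdyn_domain_error"
    )
  }
  scale[[field]]
}

#' Convert shear stress between physical and dimensionless form
#'
#' \eqn{\tilde\tau = k \tau d / 4\sigma = \tau / \mathrm{stress\_scale}} and
#' its inverse.
#'
#' @param tau_physical Physical shear stress (same units as the scale, e.g.
#'   dyn/cm^2), `>= 0`.  Vectorized.
#' @param tau Dimensionless shear.  Vectorized.
#' @param scale A [physical_scale()] with a finite stress scale.
#' @return The converted value(s).
#' @export
stress_to_dimensionless <- function(tau_physical, scale) {
  check_nonneg(tau_physical, "tau_physical")
  tau_physical / need_scale(scale, "stress_scale")
}

#' @rdname stress_to_dimensionless
#' @export
stress_from_dimensionless <- function(tau, scale) {
  check_nonneg(tau, "tau")
  tau * need_scale(scale, "stress_scale")
}

#' Convert time between physical and dimensionless form
#'
#' \eqn{\tilde t = t / \sqrt{4 m_0 / 15 \sigma \pi}} and its inverse.  The
#' squared time scale \eqn{4 m_0 / 15 \sigma \pi} is the prefactor that
#' renders the inertial term of the equation of motion dimensionless
#' (\eqn{m_0/\sigma} has units of time squared).
#'
#' @param t_physical Physical time, `>= 0`.  Vectorized.
#' @param t Dimensionless time.  Vectorized.
#' @inheritParams stress_to_dimensionless
#' @return The converted value(s).
#' @export
time_to_dimensionless <- function(t_physical, scale) {
  check_nonneg(t_physical, "t_physical")
  t_physical / need_scale(scale, "time_scale")
}

#' @rdname time_to_dimensionless
#' @export
time_from_dimensionless <- function(t, scale) {
  check_nonneg(t, "t")
  t * need_scale(scale, "time_scale")
}

#' Unfolding force on the globular part
#'
#' The shear-driven force that peels the molecule open,
#' \eqn{F_{un} = k \pi r^2 \tau}: the shear stress acting over the globule
#' cross-section, scaled by the drag coefficient.
#'
#' @param r Globule radius (`> 0`).  Vectorized.
#' @param tau_physical Physical shear stress (`>= 0`).
#' @param k Dimensionless drag coefficient.
#' @return Force, in the unit system of the inputs.
#' @export
unfolding_force <- function(r, tau_physical, k = 1) {
  check_nonneg(tau_physical, "tau_physical")
  if (any(!is.finite(r)) || any(r <= 0)) {
    abort("`r` must be positive.", class = "vwfdyn_domain_error")
  }
  k * pi * r^2 * tau_physical
}

#' Folding force from effective surface tension
#'
#' \eqn{F_f = \sigma \pi d (1 - d/2r)}: zero at the single-subunit radius
#' `r = d/2`, monotonically increasing in `r` and saturating at
#' \eqn{\sigma \pi d}.
#'
#' @inheritParams unfolding_force
#' @param d Subunit size (`> 0`).
#' @param sigma Effective surface tension (`> 0`).
#' @return Force, in the unit system of the inputs.
#' @export
folding_force <- function(r, d, sigma) {
  check_pos(d, "d")
  check_pos(sigma, "sigma")
  if (any(!is.finite(r)) || any(r < d / 2)) {
    abort("`r` must be at least the single-subunit radius d/2.",
      class = "vwfdyn_domain_error"
    )
  }
  sigma * pi * d * (1 - d / (2 * r))
}

#' Calibrate the stress scale from a known activation threshold
#'
#' Convenience heuristic (not a model result): pins the fold-catastrophe shear
#' \eqn{\tilde\tau_c = 4/27} of the dimensionless model to a user-supplied
#' physical steady-activation stress, so
#' \eqn{\mathrm{stress\_scale} = \tau_{phys} / (4/27)}.  With the commonly
#' cited steady threshold of 80 dyn/cm^2 this gives a stress scale of 540
#' dyn/cm^2.  The individual constants `k`, `d`, `sigma` remain unknown, so
#' the returned scale carries no time scale.
#'
#' @param tau_physical_at_tauc Physical shear stress at which steady-flow
#'   activation is observed (`> 0`).
#' @return A [physical_scale()] fragment with only `stress_scale` set.
#' @examples
#' calibrate_stress_scale(80)$stress_scale # 540
#' @export
calibrate_stress_scale <- function(tau_physical_at_tauc) {
  check_pos(tau_physical_at_tauc, "tau_physical_at_tauc")
  physical_scale(stress_scale = tau_physical_at_tauc / (4 / 27))
}

#' Read a plain-text key = value configuration file
#'
#' Recognised keys: `N` (required for model-dependent commands), `k`, `d`,
#' `sigma`, `m0`, `restitution`, `wall`, `rtol`, `atol`.  Lines starting with
#' `#` and blank lines are ignored.
#'
#' @param path Path to the configuration file.
#' @return A named list of parsed values (numerics where they parse).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "vwfdyn_csv_missing")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      abort(sprintf("malformed config line: %s", ln), class = "vwfdyn_domain_error")
    }
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}
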