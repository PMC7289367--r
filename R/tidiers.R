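#' Tidy a simulated trajectory
#'
#' @param x A `vwf_trajectory`.
#' @param ... Unused.
#' @return The sample tibble (`t`, `q`, `qdot`, `tau`, `u`).
#' @method tidy vwf_trajectory
#' @export
tidy.vwf_trajectory <- function(x, ...) {
  x$samples
}

#' One-row summary of a simulated trajectory
#'
#' @inheritParams tidy.vwf_trajectory
#' @return A one-row tibble with the final state, event counts and the
#'   complete-unfolding flag.
#' @method glance vwf_trajectory
#' @export
glance.vwf_trajectory <- function(x, ...) {
  fin <- x$samples[nrow(x$samples), ]
  tibble::tibble(
    N = x$params$N,
    fully_unfolded = x$fully_unfolded,
    n_samples = nrow(x$samples),
    n_events = nrow(x$events),
    t_start = x$samples$t[1],
    t_final = fin$t,
    q_final = fin$q,
    qdot_final = fin$qdot,
    u_final = fin$u,
    energy_final = total_energy(fin$q, fin$qdot, 0)
  )
}

#' Tidy a potential landscape: one row per critical point
#'
#' @param x A `vwf_landscape`.
#' @param ... Unused.
#' @return A tibble with columns `point`, `q`, `u`, `energy`, `stable`.
#' @method tidy vwf_landscape
#' @export
tidy.vwf_landscape <- function(x, ...) {
  p <- x$params
  point <- c("unfolded", "folded")
  q <- c(0, p$q_m)
  energy <- c(0, x$U_qm)
  stable <- c(TRUE, identical(x$regime, "folded_bistable"))
  if (!is.na(x$q_barrier)) {
    point <- c(point, "barrier")
    q <- c(q, x$q_barrier)
    energy <- c(energy, x$U_barrier)
    stable <- c(stable, FALSE)
  }
  if (!is.na(x$q_partial)) {
    point <- c(point, "partial")
    q <- c(q, x$q_partial)
    energy <- c(energy, potential_energy(x$q_partial, x$tau))
    stable <- c(stable, TRUE)
  }
  out <- tibble::tibble(
    point = point, q = q,
    u = unfolding_degree(pmin(q, p$q_m), p),
    energy = energy, stable = stable
  )
  out[order(out$q), ]
}

#' @rdname tidy.vwf_landscape
#' @method glance vwf_landscape
#' @export
glance.vwf_landscape <- function(x, ...) {
  tibble::tibble(
    N = x$params$N, tau = x$tau, regime = x$regime,
    q_barrier = x$q_barrier, q_partial = x$q_partial,
    U_barrier = x$U_barrier, U_qm = x$U_qm
  )
}

#' Tidy an activation report: one row per criterion
#'
#' @param x A `vwf_activation_report`.
#' @param ... Unused.
#' @return A tibble with columns `criterion`, `value`, `met`.
#' @method tidy vwf_activation_report
#' @export
tidy.vwf_activation_report <- function(x, ...) {
  tibble::tibble(
    criterion = c(
      "cumulative_shear_necessary", "momentum_sufficient",
      "complete_unfolding"
    ),
    value = c(x$css, x$qdot_out, x$residual_momentum),
    met = c(x$necessary_met, x$momentum_sufficient_met, x$fully_unfolded)
  )
}

#' @rdname tidy.vwf_activation_report
#' @method glance vwf_activation_report
#' @export
glance.vwf_activation_report <- function(x, ...) {
  tibble::tibble(
    N = x$params$N,
    activated = x$activated,
    fully_unfolded = x$fully_unfolded,
    css = x$css,
    css0 = x$css0,
    necessary_met = x$necessary_met,
    momentum_sufficient_met = x$momentum_sufficient_met,
    residual_momentum = x$residual_momentum,
    qdot_out = x$qdot_out,
    t_out = x$t_out
  )
}

#' Tidy a critical-duration curve
#'
#' @param x A `vwf_critical_curve`.
#' @param ... Unused.
#' @return The `(tau_m, t_F, never)` tibble with the hyperbola product
#'   `css_product = tau_m * t_F` appended.
#' @method tidy vwf_critical_curve
#' @export
tidy.vwf_critical_curve <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$css_product <- out$tau_m * out$t_F
  out
}

#' @rdname tidy.vwf_critical_curve
#' @method glance vwf_critical_curve
#' @export
glance.vwf_critical_curve <- function(x, ...) {
  tibble::tibble(
    N = attr(x, "params")$N,
    tau_hash = attr(x, "tau_hash"),
    css0 = attr(x, "css0"),
    n_points = nrow(x),
    n_never = sum(x$never)
  )
}
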