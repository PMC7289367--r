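#' Cumulative shear stress along a trajectory
#'
#' The time integral \eqn{CSS = \int_{t_{in}}^{t_{out}} \tilde\tau(\tilde t)\,
#' d\tilde t} of the shear a platelet experiences between entering and leaving
#' the high-shear zone.  Exact: closed form for analytic waveforms,
#' trapezoidal (also exact) for piecewise-linear sampled profiles.  Spans
#' extending beyond the profile support integrate zero shear there.
#'
#' @param profile A `vwf_shear_profile`.
#' @param t_in,t_out Integration bounds; default the profile support.
#' @return The dimensionless cumulative shear stress.
#' @export
cumulative_shear <- function(profile, t_in = NULL, t_out = NULL) {
  stopifnot(inherits(profile, "vwf_shear_profile"))
  t_in <- t_in %||% profile$support[1]
  t_out <- t_out %||% profile$support[2]
  if (!(t_in < t_out)) {
    abort("`t_in` must precede `t_out`.", class = "vwfdyn_domain_error")
  }
  profile$integral(t_in, t_out)
}

#' Critical cumulative shear stress threshold
#'
#' Closed-form activation threshold as a function of multimer size,
#' \deqn{CSS_0(N) = (3N/2)^{1/3}\sqrt{\frac{7}{4} + \frac{1}{4}(3N/2)^{-8/3}
#'   - 2\,(3N/2)^{-1/3}},}
#' algebraically identical to
#' \eqn{\sqrt{2(\tilde U_0(1) - \tilde U_0(q_m))}/q_m^{3/7}}: the cumulative
#' shear needed to impart the separatrix momentum to a molecule starting
#' folded, with the shear coupling bounded by its folded-state value.
#' Strictly increasing in `N` — larger multimers need a stronger impact.
#' A necessary, not sufficient, condition for complete unfolding.
#'
#' @inheritParams unfolding_degree
#' @return The dimensionless threshold \eqn{CSS_0}.
#' @examples
#' css0(vwf_multimer(36)) # ~ 4.176
#' @export
css0 <- function(params) {
  params <- as_vwf_multimer(params)
  a <- 1.5 * params$N
  a^(1 / 3) * sqrt(7 / 4 + 0.25 * a^(-8 / 3) - 2 * a^(-1 / 3))
}

#' Necessary condition for complete unfolding
#'
#' `TRUE` iff the cumulative shear stress over the profile support strictly
#' exceeds the threshold [css0()] for this multimer size.  Necessary but not
#' sufficient: a long weak profile can satisfy it without ever unfolding the
#' molecule.
#'
#' @inheritParams cumulative_shear
#' @inheritParams unfolding_degree
#' @return Logical.
#' @export
necessary_condition <- function(profile, params) {
  cumulative_shear(profile) > css0(params)
}

#' Momentum sufficient condition for complete unfolding
#'
#' `TRUE` iff the exit momentum is directed toward unfolding and exceeds the
#' separatrix momentum in magnitude: \eqn{\dot q_{out} < 0} and
#' \eqn{|\dot q_{out}| > |\dot q_A|}.  A state leaving the high-shear zone
#' with such momentum is guaranteed (for conservative free motion) to reach
#' the totally unfolded state.
#'
#' @param qdot_out Momentum at exit from the high-shear zone.
#' @inheritParams unfolding_degree
#' @return Logical.
#' @export
momentum_sufficient_condition <- function(qdot_out, params) {
  params <- as_vwf_multimer(params)
  qdot_out < 0 & abs(qdot_out) > saddle_momentum(params)
}

#' Amplitude asymptote of the critical-duration curve
#'
#' The unique shear \eqn{\tilde\tau_\#} in \eqn{(\tilde\tau_*, \tilde\tau_c)}
#' at which the from-rest energy of the folded state equals the barrier
#' energy, \eqn{\tilde U_{\tilde\tau}(q_m) =
#' \tilde U_{\tilde\tau}(q_{barrier})}.  A sustained shear above it unfolds a
#' resting folded molecule in finite time; below it, no rectangular impulse of
#' that amplitude unfolds it however long it lasts — the vertical asymptote of
#' the critical-duration curve.  Exact within the conservative model (no
#' damping), which is what makes the asymptote sharp.
#'
#' @inheritParams unfolding_degree
#' @return The dimensionless amplitude \eqn{\tilde\tau_\#}.
#' @export
tau_threshold <- function(params) {
  params <- as_vwf_multimer(params)
  resid <- function(tt) {
    ls <- landscape_at(tt, params)
    ls$U_qm - ls$U_barrier
  }
  lo <- tau_star(params) * (1 + 1e-9)
  hi <- tau_c(params) * (1 - 1e-9)
  uniroot(resid, c(lo, hi), tol = 1e-14)$root
}

#' Critical rectangular-impulse duration
#'
#' The minimal duration of a rectangular shear impulse of amplitude `tau_m`
#' that drives a molecule from the folded state at rest across the zero-shear
#' separatrix by switch-off — the boundary between impulses that do and do
#' not unfold it completely.  Located as the first time, along the constant-
#' shear trajectory from rest, at which the free-motion energy
#' \eqn{E_0 = \dot q^2/2 + \tilde U_0(q)} reaches the saddle energy
#' \eqn{\tilde U_0(1)}; under constant shear \eqn{E_0} is monotone on the
#' inward leg, so this first crossing is the critical duration, and the
#' integrator's root location finds it far more tightly than `rel_tol`.
#' Returns `Inf` ("never") for amplitudes at or below the asymptote
#' [tau_threshold()].
#'
#' @param tau_m Impulse amplitude, `> 0`.
#' @inheritParams unfolding_degree
#' @param rel_tol Requested relative tolerance on the critical duration
#'   (the event location is tighter; kept as a validated contract).
#' @param rtol,atol Integrator tolerances.
#' @return The critical duration \eqn{\tilde t_F}, or `Inf`.
#' @examples
#' critical_duration(10, vwf_multimer(36)) # ~ 0.42, close to css0 / 10
#' @export
critical_duration <- function(tau_m, params, rel_tol = 1e-6,
                              rtol = 1e-10, atol = 1e-10) {
  params <- as_vwf_multimer(params)
  check_pos(tau_m, "tau_m")
  if (tau_m <= tau_threshold(params)) {
    return(Inf)
  }
  q_m <- params$q_m
  rhs <- function(t, y, parms) {
    q <- max(y[1L], 0)
    list(c(y[2L], -tau_m * q^(3 / 7) + q^(1 / 7) - 1))
  }
  groot <- function(t, y, parms) {
    q <- max(y[1L], 0)
    y[2L]^2 / 2 + potential_energy(q, 0) - 0.125
  }
  tt <- max(20, 10 * css0(params) / tau_m)
  for (i in seq_len(25L)) {
    out <- deSolve::lsodar(
      y = c(q_m, 0), times = c(0, tt), func = rhs, parms = NULL,
      rtol = rtol, atol = atol, rootfunc = groot, maxsteps = 1000000
    )
    istate <- attr(out, "istate")
    if (!is.null(istate) && istate[1] < 0) {
      abort("LSODAR failed while locating the critical duration.",
        class = "vwfdyn_numeric_error"
      )
    }
    troot <- attr(out, "troot")
    if (!is.null(troot) && length(troot) > 0L && !is.na(troot[1])) {
      return(troot[1])
    }
    tt <- 2 * tt
  }
  abort("critical duration did not converge within the iteration cap.",
    class = "vwfdyn_numeric_error"
  )
}

#' Critical-duration curve over an amplitude grid
#'
#' Tabulates [critical_duration()] over a grid of rectangular-impulse
#' amplitudes and attaches the asymptote [tau_threshold()] and the hyperbola
#' constant [css0()].  Every finite row satisfies
#' \eqn{\tilde\tau_m \tilde t_F \ge CSS_0}, with the product converging to
#' \eqn{CSS_0} from above as the amplitude grows (the impulsive limit, where
#' the molecule barely moves before acquiring the separatrix momentum);
#' rows at or below the asymptote are flagged `never`.
#'
#' @inheritParams unfolding_degree
#' @param tau_grid Positive amplitudes.
#' @inheritParams critical_duration
#' @return A tibble of class `vwf_critical_curve` with columns `tau_m`, `t_F`
#'   (`Inf` where unfolding never happens) and `never`; attributes `params`,
#'   `tau_hash` and `css0`.
#' @export
critical_curve <- function(params, tau_grid, rel_tol = 1e-6) {
  params <- as_vwf_multimer(params)
  check_nonneg(tau_grid, "tau_grid")
  if (length(tau_grid) == 0L || any(tau_grid <= 0)) {
    abort("`tau_grid` must be a non-empty vector of positive amplitudes.",
      class = "vwfdyn_domain_error"
    )
  }
  t_f <- purrr::map_dbl(tau_grid, critical_duration,
    params = params, rel_tol = rel_tol
  )
  out <- tibble::tibble(tau_m = tau_grid, t_F = t_f, never = !is.finite(t_f))
  attr(out, "params") <- params
  attr(out, "tau_hash") <- tau_threshold(params)
  attr(out, "css0") <- css0(params)
  class(out) <- c("vwf_critical_curve", class(out))
  out
}

#' Classify a shear profile: does it activate the platelet?
#'
#' Runs the full pipeline for one shear history: simulates the equation of
#' motion from the folded state at rest over the profile support, and reports
#' the activation verdict together with every criterion.  The ground truth is
#' whether the molecule unfolds completely — either the trajectory contacts
#' `q = 0` during the profile, or the state at switch-off lies below the
#' zero-shear separatrix (an exact energy criterion for the subsequent free
#' motion).  The residual momentum at complete unfolding is taken at origin
#' contact when it happens during the simulation, and from the free-motion
#' energy \eqn{|\dot q| = \sqrt{2 E_0}} otherwise.  The momentum sufficient
#' condition is evaluated at the profile's last sample time.
#'
#' @inheritParams cumulative_shear
#' @inheritParams unfolding_degree
#' @param boundary A [boundary_spec()].
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `vwf_activation_report`: a list with `activated`
#'   and `fully_unfolded` (identical verdicts), `css`, `css0`,
#'   `necessary_met`, `momentum_sufficient_met`, `residual_momentum`, and the
#'   underlying `trajectory`.
#' @examples
#' classify_profile(shear_rectangular(10, 1), vwf_multimer(36))$activated
#' @export
classify_profile <- function(profile, params, boundary = boundary_spec(),
                             rtol = 1e-9, atol = 1e-9) {
  params <- as_vwf_multimer(params)
  traj <- simulate_unfolding(profile, params,
    boundary = boundary,
    t_end = profile$support[2], rtol = rtol, atol = atol
  )
  fin <- traj$samples[nrow(traj$samples), ]
  contact <- traj$fully_unfolded
  sep_end <- isTRUE(separatrix_test(fin$q, fin$qdot, params))
  unfolds <- contact || sep_end
  residual <- NA_real_
  if (contact) {
    oc <- traj$events[traj$events$kind == "ORIGIN_CONTACT", ]
    residual <- abs(oc$qdot[1])
  } else if (unfolds) {
    residual <- sqrt(2 * total_energy(fin$q, fin$qdot, 0))
  }
  css <- cumulative_shear(profile)
  structure(
    list(
      activated = unfolds,
      fully_unfolded = unfolds,
      css = css,
      css0 = css0(params),
      necessary_met = css > css0(params),
      momentum_sufficient_met = momentum_sufficient_condition(fin$qdot, params),
      residual_momentum = residual,
      qdot_out = fin$qdot,
      t_out = fin$t,
      params = params,
      boundary = boundary,
      trajectory = traj
    ),
    class = "vwf_activation_report"
  )
}

#' @export
print.vwf_activation_report <- function(x, ...) {
  cat(sprintf(
    "<vwf_activation_report> N = %d: %s\n",
    x$params$N, if (x$activated) "ACTIVATED (complete unfolding)" else "not activated"
  ))
  cat(sprintf(
    "  CSS = %.6g %s CSS0 = %.6g (necessary condition %s)\n",
    x$css, if (x$necessary_met) ">" else "<=", x$css0,
    if (x$necessary_met) "met" else "not met"
  ))
  cat(sprintf(
    "  momentum sufficient condition at exit: %s (qdot_out = %.6g)\n",
    x$momentum_sufficient_met, x$qdot_out
  ))
  if (!is.na(x$residual_momentum)) {
    cat(sprintf("  residual momentum at complete unfolding: %.6g\n", x$residual_momentum))
  }
  invisible(x)
}
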