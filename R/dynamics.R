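#' Boundary conditions at the ends of the conformational domain
#'
#' At the totally unfolded boundary `q = 0` the molecule-platelet collision is
#' characterised by a restitution coefficient `e`: `e = 0` is irreversible
#' adhesion (the trajectory terminates in the unfolded absorbing state), `e =
#' 1` an elastic bounce, intermediate values a partially elastic collision.
#' At the folded boundary `q = q_m` the wall is either `"sticky"` (the
#' outward momentum is absorbed and the molecule is held folded while the
#' landscape presses it against the wall) or `"reflect"` (momentum negated).
#'
#' @param restitution Restitution coefficient at the origin, in `[0, 1]`.
#'   Default 0: once fully unfolded, the molecule stays unfolded.
#' @param wall `"sticky"` (default) or `"reflect"` behaviour at `q = q_m`.
#' @return An object of class `vwf_boundary`.
#' @export
boundary_spec <- function(restitution = 0, wall = c("sticky", "reflect")) {
  wall <- match.arg(wall)
  if (!is.numeric(restitution) || length(restitution) != 1L ||
    !is.finite(restitution) || restitution < 0 || restitution > 1) {
    abort("`restitution` must be a scalar in [0, 1].", class = "vwfdyn_domain_error")
  }
  structure(list(restitution = restitution, wall = wall), class = "vwf_boundary")
}

#' Phase-space state of the conformational coordinate
#'
#' @param q Dimensionless coordinate.
#' @param qdot Dimensionless momentum (signed; negative = unfolding).
#' @param t Dimensionless time (default 0).
#' @return A one-row tibble with columns `t`, `q`, `qdot`.
#' @export
vwf_state <- function(q, qdot, t = 0) {
  tibble::tibble(t = t, q = q, qdot = qdot)
}

as_state_row <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, all(c("q", "qdot") %in% names(x)))
    list(t = if ("t" %in% names(x)) x$t else 0, q = x$q, qdot = x$qdot)
  } else if (is.numeric(x) && length(x) %in% 2:3) {
    list(t = if (length(x) == 3L) x[3] else 0, q = x[1], qdot = x[2])
  } else {
    abort("`initial` must be a vwf_state() row or a numeric c(q, qdot[, t]).",
      class = "vwfdyn_domain_error"
    )
  }
}

#' Total mechanical energy of a state
#'
#' \eqn{E = \dot q^2/2 + \tilde U_{\tilde\tau}(q)}.  Conserved along the
#' motion on spans of constant shear without boundary contact.
#'
#' @param q,qdot Phase-space coordinates (vectorized).
#' @param tau Dimensionless shear (default 0, the free-motion potential).
#' @return Dimensionless energy.
#' @export
total_energy <- function(q, qdot, tau = 0) {
  qdot^2 / 2 + potential_energy(q, tau)
}

#' Will a state unfold completely under zero shear?
#'
#' Decides, from energy alone, whether the forward orbit of a phase-space
#' state reaches the totally unfolded boundary `q = 0` under zero shear and no
#' dissipation — i.e. whether the state lies below the separatrix through the
#' saddle `q = 1`.  For `q >= 1` the state must move inward with
#' super-saddle energy (`qdot < 0` and \eqn{E_0 > \tilde U_0(1) = 1/8}); for
#' `q < 1` any non-outward motion reaches the origin, and outward motion
#' returns and unfolds unless its energy carries it over the saddle into the
#' folded basin.  The energy inequality is exact for conservative motion — no
#' integration to `q = 0` is needed.
#'
#' @param q,qdot Phase-space coordinates (vectorized); `0 <= q <= q_m`.
#' @param params A [vwf_multimer()] (or subunit count).
#' @return Logical: `TRUE` where the state leads to complete unfolding.
#' @export
separatrix_test <- function(q, qdot, params) {
  params <- as_vwf_multimer(params)
  check_nonneg(q, "q")
  if (any(q > params$q_m * (1 + 1e-12))) {
    abort("`q` must not exceed q_m.", class = "vwfdyn_domain_error")
  }
  u_s <- 0.125
  e0 <- total_energy(q, qdot, 0)
  ifelse(q < 1, qdot <= 0 | e0 < u_s, qdot < 0 & e0 > u_s)
}

# Right-hand side and boundary root functions for deSolve.  q is clamped to
# zero inside the force evaluation only, so that adaptive steps probing
# marginally past the origin (before the event is located) stay finite.
make_rhs <- function(tau_fun) {
  function(t, y, parms) {
    q <- max(y[1L], 0)
    list(c(y[2L], -tau_fun(t) * q^(3 / 7) + q^(1 / 7) - 1))
  }
}

rk4_step <- function(f, t, y, h) {
  k1 <- f(t, y, NULL)[[1]]
  k2 <- f(t + h / 2, y + h / 2 * k1, NULL)[[1]]
  k3 <- f(t + h / 2, y + h / 2 * k2, NULL)[[1]]
  k4 <- f(t + h, y + h * k3, NULL)[[1]]
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Integrate the unfolding equation of motion under a shear profile
#'
#' Integrates \eqn{\ddot q = -\tilde\tau(\tilde t)\, q^{3/7} + q^{1/7} - 1}
#' with an adaptive solver (LSODAR) and dense event location at the physical
#' boundaries.  Integration is split at the profile's non-smooth points so
#' switch-on/off times are hit exactly.  On contact with `q = 0` the boundary
#' restitution applies (`e = 0` terminates in the unfolded absorbing state;
#' `e > 0` reverses the momentum scaled by `e`).  On outward contact with
#' `q = q_m` a `"sticky"` wall zeroes the momentum — and holds the molecule
#' folded while the landscape presses it against the wall, releasing it when
#' the shear exceeds the detachment value — while `"reflect"` negates it.
#' Separatrix crossings (the zero-shear energy test of [separatrix_test()]
#' turning true) are recorded as events.
#'
#' @param profile A `vwf_shear_profile` (see [shear_rectangular()] and
#'   friends).
#' @param params A [vwf_multimer()] (or subunit count).
#' @param initial Initial state ([vwf_state()] row or `c(q, qdot)`), default
#'   the folded state at rest at the start of the profile support.
#' @param boundary A [boundary_spec()].
#' @param t_end End of the integration span; defaults to the end of the
#'   profile support.
#' @param rtol,atol Relative/absolute integrator tolerances.  The defaults
#'   (`1e-9`) are tight because momenta of order \eqn{10^2}–\eqn{10^3} and
#'   energies of order \eqn{10^4} must be resolved against a saddle energy of
#'   `1/8`.
#' @param n_out Approximate number of reported samples across the span.
#' @param method `"adaptive"` (default) or `"verlet"`, a fixed-step velocity
#'   Verlet mode retained to audit the energy drift of the adaptive solver.
#' @param dt Fixed step for the Verlet mode (default: span / 20000).
#' @param max_events Safety cap on boundary events.
#' @return An object of class `vwf_trajectory`: list with `samples` (tibble
#'   `t`, `q`, `qdot`, `tau`, `u`), `events` (tibble `kind`, `t`, `qdot` with
#'   kinds `SEPARATRIX_CROSS`, `ORIGIN_CONTACT`, `WALL_CONTACT`),
#'   `fully_unfolded` (reached `q = 0`), plus the `params` and `boundary`
#'   used.
#' @examples
#' p <- vwf_multimer(36)
#' traj <- simulate_unfolding(shear_rectangular(10, 1), p, t_end = 5)
#' traj$fully_unfolded
#' @export
simulate_unfolding <- function(profile, params, initial = NULL,
                               boundary = boundary_spec(), t_end = NULL,
                               rtol = 1e-9, atol = 1e-9, n_out = 400L,
                               method = c("adaptive", "verlet"), dt = NULL,
                               max_events = 10000L) {
  method <- match.arg(method)
  params <- as_vwf_multimer(params)
  stopifnot(inherits(profile, "vwf_shear_profile"))
  stopifnot(inherits(boundary, "vwf_boundary"))
  q_m <- params$q_m
  if (is.null(initial)) initial <- vwf_state(q_m, 0, t = profile$support[1])
  ini <- as_state_row(initial)
  if (!is.finite(ini$q) || ini$q < 0 || ini$q > q_m * (1 + 1e-12)) {
    abort("initial q must lie in [0, q_m].", class = "vwfdyn_domain_error")
  }
  if (is.null(t_end)) t_end <- profile$support[2]
  if (!is.finite(t_end) || t_end <= ini$t) {
    abort("`t_end` must be finite and greater than the initial time.",
      class = "vwfdyn_domain_error"
    )
  }
  if (any(!is.finite(profile$fun(seq(ini$t, t_end, length.out = 17))))) {
    abort("shear profile evaluates to non-finite values on the span.",
      class = "vwfdyn_domain_error"
    )
  }
  if (method == "verlet") {
    return(simulate_verlet(profile, params, ini, boundary, t_end, dt, n_out))
  }

  tau_fun <- profile$fun
  rhs <- make_rhs(tau_fun)
  groot <- function(t, y, parms) c(y[1L], y[1L] - q_m)
  t0 <- ini$t
  span <- t_end - t0
  base_dt <- span / n_out
  brk <- sort(unique(c(
    t0, t_end,
    profile$breaks[profile$breaks > t0 & profile$breaks < t_end]
  )))

  q <- min(ini$q, q_m)
  qd <- ini$qdot
  t_cur <- t0
  sample_list <- list(matrix(c(t_cur, q, qd), nrow = 1))
  ev_kind <- character(0)
  ev_t <- numeric(0)
  ev_qd <- numeric(0)
  fully_unfolded <- FALSE
  terminated <- FALSE
  n_events <- 0L

  add_samples <- function(m) {
    sample_list[[length(sample_list) + 1L]] <<- m
  }
  add_event <- function(kind, t, qdot) {
    ev_kind <<- c(ev_kind, kind)
    ev_t <<- c(ev_t, t)
    ev_qd <<- c(ev_qd, qdot)
    n_events <<- n_events + 1L
    if (n_events > max_events) {
      abort("boundary event cap exceeded; the trajectory appears degenerate.",
        class = "vwfdyn_numeric_error"
      )
    }
  }
  # Advance one small high-order step off a boundary so the root finder never
  # starts on (or within rounding of) one of its own roots.  The step size is
  # chosen to move q by a fixed small displacement, resolvable against q_m.
  nudge <- function(seg_end, scale = 1) {
    rem <- seg_end - t_cur
    if (rem <= 0) {
      return(invisible(NULL))
    }
    a <- abs(acceleration(max(q, 0), tau_fun(t_cur)))
    target <- max(1e-9, 1e-10 * q_m) * scale
    h1 <- if (abs(qd) > 1e-14) target / abs(qd) else Inf
    h2 <- if (a > 1e-14) sqrt(2 * target / a) else Inf
    h <- min(h1, h2, base_dt, rem / 2)
    h <- max(h, min(1e-8, rem / 2))
    y <- rk4_step(rhs, t_cur, c(q, qd), h)
    t_cur <<- t_cur + h
    q <<- y[1]
    qd <<- y[2]
    invisible(NULL)
  }
  # Carry a freshly bounced state analytically from q = 0 out of the
  # non-Lipschitz zone (the q^(1/7) force term defeats polynomial steppers
  # when restarting at the origin).  Energy quadrature at frozen shear: exact
  # on constant-shear stretches, and asymptotically exact in general because
  # the shear coupling q^(3/7) vanishes at the origin.
  hop_off_origin <- function(seg_end) {
    v <- abs(qd)
    tau0 <- tau_fun(t_cur)
    q_exit <- min(1e-3, v^2 / 8)
    while (q_exit > 1e-12 && 2 * potential_energy(q_exit, tau0) > 0.5 * v^2) {
      q_exit <- q_exit / 4
    }
    dt_hop <- tryCatch(
      stats::integrate(
        function(qq) 1 / sqrt(pmax(v^2 - 2 * potential_energy(qq, tau0), 1e-300)),
        0, q_exit,
        rel.tol = 1e-12
      )$value,
      error = function(e) Inf
    )
    if (q_exit <= 1e-12 || !is.finite(dt_hop) || t_cur + dt_hop > seg_end) {
      nudge(seg_end)
      return(invisible(NULL))
    }
    t_cur <<- t_cur + dt_hop
    q <<- q_exit
    qd <<- sqrt(v^2 - 2 * potential_energy(q_exit, tau0))
    add_samples(matrix(c(t_cur, q, qd), nrow = 1))
    invisible(NULL)
  }
  # earliest time in [ta, tb] where the landscape stops pressing the molecule
  # against the folded wall (acceleration at q_m turns negative), or NA
  find_release <- function(ta, tb) {
    h <- function(t) acceleration(q_m, tau_fun(t))
    tg <- seq(ta, tb, length.out = 129L)
    hv <- h(tg)
    if (hv[1] < 0) {
      return(ta)
    }
    i <- which(hv < 0)[1]
    if (is.na(i)) {
      return(NA_real_)
    }
    uniroot(h, c(tg[i - 1L], tg[i]), tol = 1e-13 * max(1, abs(tb)))$root
  }

  for (k in seq_len(length(brk) - 1L)) {
    if (terminated) break
    seg_end <- brk[k + 1L]
    guard <- 0L
    while (!terminated && t_cur < seg_end - 1e-13 * max(1, abs(seg_end))) {
      guard <- guard + 1L
      if (guard > max_events + 100L) {
        abort("integration stalled inside a segment.", class = "vwfdyn_numeric_error")
      }
      pinned <- boundary$wall == "sticky" &&
        abs(q - q_m) <= 1e-9 * q_m && abs(qd) <= 1e-7 &&
        acceleration(q_m, tau_fun(t_cur + 1e-12 * max(1, abs(t_cur)))) >= 0
      if (pinned) {
        t_rel <- find_release(t_cur, seg_end)
        hold_end <- if (is.na(t_rel)) seg_end else t_rel
        if (hold_end > t_cur) {
          ts <- seq(t_cur, hold_end,
            length.out = max(2L, min(50L, ceiling((hold_end - t_cur) / base_dt) + 1L))
          )
          add_samples(cbind(ts, q_m, 0))
        }
        t_cur <- hold_end
        q <- q_m
        qd <- 0
        next
      }
      # avoid starting LSODAR exactly on a boundary root
      if (q <= max(atol, 1e-12) || q >= q_m * (1 - 1e-14)) nudge(seg_end)
      if (t_cur >= seg_end - 1e-13 * max(1, abs(seg_end))) break
      attempt <- 0L
      repeat {
        n_pts <- max(3L, min(2000L, ceiling((seg_end - t_cur) / base_dt) + 2L))
        times <- seq(t_cur, seg_end, length.out = n_pts)
        out <- tryCatch(
          deSolve::lsodar(
            y = c(q, qd), times = times, func = rhs, parms = NULL,
            rtol = rtol, atol = atol, rootfunc = groot, maxsteps = 500000
          ),
          error = identity
        )
        if (!inherits(out, "error")) break
        # a root coinciding with the start point: step a little further off it
        attempt <- attempt + 1L
        if (attempt > 8L) {
          abort(paste("LSODAR failed:", conditionMessage(out)),
            class = "vwfdyn_numeric_error"
          )
        }
        nudge(seg_end, scale = 10^attempt)
        if (t_cur >= seg_end - 1e-13 * max(1, abs(seg_end))) break
      }
      if (inherits(out, "error")) next
      istate <- attr(out, "istate")
      if (!is.null(istate) && istate[1] < 0) {
        abort(sprintf("LSODAR failed with istate = %d (tolerances not met).", istate[1]),
          class = "vwfdyn_numeric_error"
        )
      }
      m <- unclass(out)[, 1:3, drop = FALSE]
      if (nrow(m) > 1L) add_samples(m[-1L, , drop = FALSE])
      last <- m[nrow(m), ]
      troot <- attr(out, "troot")
      t_cur <- last[1]
      q <- last[2]
      qd <- last[3]
      if (is.null(troot) || length(troot) == 0L || all(is.na(troot))) {
        # reached seg_end without boundary contact
        next
      }
      # boundary event at t_cur; classify by position (q_m >> 0).  The root
      # is located to integrator precision; snapping q onto the boundary
      # folds the residual potential into the momentum so contacts are
      # exactly energy-consistent.
      # polish the contact state: the root-time interpolant is an order
      # coarser than regular output, so re-integrate the last inter-sample
      # span at tight tolerance before snapping onto the boundary
      if (nrow(m) >= 2L) {
        t_prev <- m[nrow(m) - 1L, 1]
        if (t_cur > t_prev) {
          outp <- tryCatch(
            deSolve::lsodar(
              y = m[nrow(m) - 1L, 2:3], times = c(t_prev, t_cur), func = rhs,
              parms = NULL, rtol = 1e-12, atol = 1e-12, maxsteps = 100000
            ),
            error = identity
          )
          if (!inherits(outp, "error") && nrow(outp) == 2L) {
            q <- outp[2L, 2L]
            qd <- outp[2L, 3L]
          }
        }
      }
      tau_now <- tau_fun(t_cur)
      snap_sample <- function(qv, qdv) {
        sm <- sample_list[[length(sample_list)]]
        sm[nrow(sm), 2:3] <- c(qv, qdv)
        sample_list[[length(sample_list)]] <<- sm
      }
      if (q < q_m / 2) {
        # inside the clamped-force region (q < 0) the effective potential is
        # linear in q, so the snapped momentum follows from energy either way
        pot <- if (q >= 0) potential_energy(q, tau_now) else q
        qd <- -sqrt(max(0, qd^2 + 2 * pot))
        add_event("ORIGIN_CONTACT", t_cur, qd)
        fully_unfolded <- TRUE
        q <- 0
        snap_sample(0, qd)
        if (boundary$restitution == 0) {
          terminated <- TRUE
        } else {
          qd <- -boundary$restitution * qd
          if (abs(qd) < 1e-10) {
            terminated <- TRUE # settled at the origin
          } else {
            hop_off_origin(seg_end)
          }
        }
      } else {
        if (qd > 0) {
          qd <- sqrt(max(0, qd^2 + 2 * (potential_energy(q, tau_now) -
            potential_energy(q_m, tau_now))))
          add_event("WALL_CONTACT", t_cur, qd)
          q <- q_m
          snap_sample(q_m, qd)
          qd <- if (boundary$wall == "sticky") 0 else -qd
        } else {
          q <- min(q, q_m) # tangential touch; keep going
        }
      }
    }
  }

  m <- do.call(rbind, sample_list)
  samples <- tibble::tibble(
    t = m[, 1], q = pmin(pmax(m[, 2], 0), q_m), qdot = m[, 3]
  )
  samples <- samples[!duplicated(samples$t), ]
  samples$tau <- tau_fun(samples$t)
  samples$u <- unfolding_degree(samples$q, params)

  # separatrix crossings: first sample of each below-separatrix stretch
  sep <- separatrix_test(samples$q, samples$qdot, params)
  cross <- which(sep & !c(FALSE, sep[-length(sep)]))
  for (i in cross) {
    ev_kind <- c(ev_kind, "SEPARATRIX_CROSS")
    ev_t <- c(ev_t, samples$t[i])
    ev_qd <- c(ev_qd, samples$qdot[i])
  }
  events <- tibble::tibble(kind = ev_kind, t = ev_t, qdot = ev_qd)
  events <- events[order(events$t), ]

  structure(
    list(
      samples = samples, events = events, fully_unfolded = fully_unfolded,
      params = params, boundary = boundary, profile_kind = profile$kind,
      t_end = t_end, rtol = rtol, atol = atol, method = method
    ),
    class = "vwf_trajectory"
  )
}

# Fixed-step velocity Verlet integrator (diagnostic mode): symplectic, so its
# energy drift bounds what the adaptive solver should beat.  Boundary contacts
# are located by linear interpolation within a step.
simulate_verlet <- function(profile, params, ini, boundary, t_end, dt, n_out) {
  q_m <- params$q_m
  tau_fun <- profile$fun
  t0 <- ini$t
  if (is.null(dt)) dt <- (t_end - t0) / 20000
  check_pos(dt, "dt")
  n_steps <- ceiling((t_end - t0) / dt)
  keep <- max(1L, floor(n_steps / n_out))
  acc <- function(q, t) {
    q <- max(q, 0)
    -tau_fun(t) * q^(3 / 7) + q^(1 / 7) - 1
  }
  q <- min(ini$q, q_m)
  qd <- ini$qdot
  t <- t0
  a <- acc(q, t)
  ts <- numeric(0)
  qs <- numeric(0)
  qds <- numeric(0)
  ev_kind <- character(0)
  ev_t <- numeric(0)
  ev_qd <- numeric(0)
  fully_unfolded <- FALSE
  record <- function(i) {
    ts <<- c(ts, t)
    qs <<- c(qs, q)
    qds <<- c(qds, qd)
  }
  record(0L)
  for (i in seq_len(n_steps)) {
    h <- min(dt, t_end - t)
    if (h <= 0) break
    if (q >= q_m * (1 - 1e-14) && qd <= 0 && boundary$wall == "sticky" &&
      acc(q_m, t) >= 0) {
      q <- q_m
      qd <- 0
      t <- t + h
      a <- acc(q, t)
      if (i %% keep == 0L) record(i)
      next
    }
    q_new <- q + qd * h + 0.5 * a * h^2
    a_new <- acc(q_new, t + h)
    qd_new <- qd + 0.5 * (a + a_new) * h
    if (q_new <= 0) {
      frac <- if (q_new < q) q / (q - q_new) else 0
      t <- t + frac * h
      q <- 0
      qd <- qd + a * frac * h
      ev_kind <- c(ev_kind, "ORIGIN_CONTACT")
      ev_t <- c(ev_t, t)
      ev_qd <- c(ev_qd, qd)
      fully_unfolded <- TRUE
      if (boundary$restitution == 0) {
        record(i)
        break
      }
      qd <- -boundary$restitution * qd
      a <- acc(q, t)
    } else if (q_new >= q_m && qd_new > 0) {
      t <- t + h
      q <- q_m
      ev_kind <- c(ev_kind, "WALL_CONTACT")
      ev_t <- c(ev_t, t)
      ev_qd <- c(ev_qd, qd_new)
      qd <- if (boundary$wall == "sticky") 0 else -qd_new
      a <- acc(q, t)
    } else {
      q <- q_new
      qd <- qd_new
      a <- a_new
      t <- t + h
    }
    if (i %% keep == 0L || t >= t_end) record(i)
  }
  samples <- tibble::tibble(t = ts, q = pmin(pmax(qs, 0), q_m), qdot = qds)
  samples <- samples[!duplicated(samples$t), ]
  samples$tau <- tau_fun(samples$t)
  samples$u <- unfolding_degree(samples$q, params)
  structure(
    list(
      samples = samples,
      events = tibble::tibble(kind = ev_kind, t = ev_t, qdot = ev_qd),
      fully_unfolded = fully_unfolded, params = params, boundary = boundary,
      profile_kind = profile$kind, t_end = t_end, rtol = NA_real_,
      atol = NA_real_, method = "verlet"
    ),
    class = "vwf_trajectory"
  )
}

#' @export
print.vwf_trajectory <- function(x, ...) {
  fin <- x$samples[nrow(x$samples), ]
  cat(sprintf(
    "<vwf_trajectory> N = %d, %s profile, %d samples, %d events\n",
    x$params$N, x$profile_kind, nrow(x$samples), nrow(x$events)
  ))
  cat(sprintf(
    "  final state: t = %.6g, q = %.6g, qdot = %.6g, u = %.4f\n",
    fin$t, fin$q, fin$qdot, fin$u
  ))
  cat(sprintf("  fully unfolded (reached q = 0): %s\n", x$fully_unfolded))
  invisible(x)
}
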