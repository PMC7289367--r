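#' Dimensionless potential energy of the VWF conformational coordinate
#'
#' The equation of motion of the conformational coordinate `q` under constant
#' dimensionless shear \eqn{\tilde\tau} is conservative, with potential
#' \deqn{\tilde U_{\tilde\tau}(q) = \frac{7}{10}\tilde\tau\, q^{10/7}
#'   - \frac{7}{8} q^{8/7} + q.}
#' The shear term tilts the landscape toward unfolding (small `q`); the other
#' two terms encode the surface-tension-driven refolding force.  At zero shear
#' the landscape has a saddle at exactly `q = 1` with
#' \eqn{\tilde U_0(1) = 1/8}.
#'
#' @param q Dimensionless conformational coordinate, `q >= 0`.  Vectorized.
#' @param tau Dimensionless shear stress, `tau >= 0`.  Vectorized (recycled
#'   against `q`).
#' @return Dimensionless potential energy, same length as the recycled inputs.
#' @seealso [acceleration()] for the corresponding force, [landscape_at()] for
#'   the critical-point analysis at fixed shear.
#' @examples
#' potential_energy(1, 0) # 1/8, the saddle energy
#' @export
potential_energy <- function(q, tau) {
  check_nonneg(q, "q")
  check_nonneg(tau, "tau")
  0.7 * tau * q^(10 / 7) - 0.875 * q^(8 / 7) + q
}

#' Dimensionless acceleration of the conformational coordinate
#'
#' Right-hand side of the equation of motion
#' \deqn{\ddot q = -\tilde\tau\, q^{3/7} + q^{1/7} - 1,}
#' equal to \eqn{-\partial \tilde U_{\tilde\tau}/\partial q} at the same
#' `(q, tau)`.  Negative acceleration drives the molecule toward the unfolded
#' state `q = 0`.
#'
#' @inheritParams potential_energy
#' @return Dimensionless acceleration \eqn{\ddot q}.
#' @examples
#' acceleration(1, 0) # 0: the zero-shear saddle is an equilibrium
#' acceleration(0, 5) # -1: only the constant restoring term survives at q = 0
#' @export
acceleration <- function(q, tau) {
  check_nonneg(q, "q")
  check_nonneg(tau, "tau")
  -tau * q^(3 / 7) + q^(1 / 7) - 1
}

#' Degree of unfolding
#'
#' Maps the conformational coordinate to the order parameter
#' \eqn{u = 1 - (q/q_m)^{3/7}}, the ratio of the unfolded tail length to the
#' contour length.  `u = 0` is the fully folded state (`q = q_m`), `u = 1` the
#' totally unfolded state (`q = 0`); `u` is strictly decreasing in `q`.
#'
#' @param q Dimensionless coordinate in `[0, q_m]`.  Vectorized.
#' @param params A [vwf_multimer()] (or subunit count).
#' @return Unfolding degree in `[0, 1]`.
#' @export
unfolding_degree <- function(q, params) {
  params <- as_vwf_multimer(params)
  check_nonneg(q, "q")
  if (any(q > params$q_m)) {
    abort("`q` must not exceed the folded-state coordinate q_m.",
      class = "vwfdyn_domain_error"
    )
  }
  1 - (q / params$q_m)^(3 / 7)
}

#' Inverse of the unfolding degree
#'
#' Recovers the conformational coordinate from the order parameter:
#' \eqn{q = q_m (1 - u)^{7/3}}.
#'
#' @param u Unfolding degree in `[0, 1]`.  Vectorized.
#' @inheritParams unfolding_degree
#' @return Dimensionless coordinate in `[0, q_m]`.
#' @export
degree_to_coordinate <- function(u, params) {
  params <- as_vwf_multimer(params)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    abort("`u` must lie in [0, 1].", class = "vwfdyn_domain_error")
  }
  params$q_m * (1 - u)^(7 / 3)
}

#' Shear at which the partially unfolded state detaches from the folded state
#'
#' Stationarity of the potential evaluated at `q = q_m` gives the bifurcation
#' shear \deqn{\tilde\tau_* = \frac{(3N/2)^{1/3} - 1}{3N/2}.}
#' Below it the landscape minima are the folded state `q_m` and the unfolded
#' state `0`; above it an interior (partially unfolded) minimum exists.
#' Decreasing in `N`: larger multimers start to unfold at lower shear.
#'
#' @inheritParams unfolding_degree
#' @return Dimensionless shear \eqn{\tilde\tau_*}.
#' @export
tau_star <- function(params) {
  params <- as_vwf_multimer(params)
  a <- 1.5 * params$N
  (a^(1 / 3) - 1) / a
}

#' Fold-catastrophe shear
#'
#' The shear at which the partially unfolded minimum and the barrier merge and
#' disappear.  Writing stationarity of the potential as the cubic
#' \eqn{\tilde\tau s^3 - s + 1 = 0} in \eqn{s = q^{1/7}}, the double-root
#' condition gives \eqn{\tilde\tau_c = 4/27} at \eqn{s = 3/2}, independent of
#' the multimer size (the fold sits at \eqn{q = (3/2)^7}, inside the physical
#' domain whenever `N >= 3`).  Above \eqn{\tilde\tau_c} the only minimum is the
#' totally unfolded state.
#'
#' @inheritParams unfolding_degree
#' @return Dimensionless shear `4/27`.
#' @export
tau_c <- function(params) {
  as_vwf_multimer(params) # N >= 3 guard
  4 / 27
}

#' Separatrix momentum at the unfolded boundary
#'
#' The magnitude of momentum with which the zero-shear separatrix — the orbit
#' through the saddle `q = 1` — meets the folded state `q = q_m`:
#' \deqn{|\dot q_A| = \sqrt{2(\tilde U_0(1) - \tilde U_0(q_m))}.}
#' A molecule at the folded state needs at least this (inward) momentum to be
#' carried over the saddle to complete unfolding under zero shear.  Strictly
#' increasing in `N`, and equal to \eqn{CSS_0(N)\, q_m^{3/7}}.
#'
#' @inheritParams unfolding_degree
#' @return Dimensionless momentum magnitude.
#' @export
saddle_momentum <- function(params) {
  params <- as_vwf_multimer(params)
  sqrt(2 * (0.125 - potential_energy(params$q_m, 0)))
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and non-negative.", name),
      class = "vwfdyn_domain_error"
    )
  }
  invisible(x)
}

# Positive stationary points of the potential at shear tau, as roots of the
# cubic tau*s^3 - s + 1 = 0 in s = q^(1/7).  Returns a sorted numeric vector
# (length 0, 1 or 2); the smaller root is the barrier, the larger the interior
# minimum.  polyroot() followed by a Newton polish (skipped near the fold,
# where the derivative degenerates).
stationary_s <- function(tau) {
  if (tau == 0) {
    return(1)
  }
  if (tau >= 4 / 27) {
    return(numeric(0))
  }
  z <- polyroot(c(1, -1, 0, tau))
  s <- Re(z)[abs(Im(z)) < 1e-8 * pmax(1, Mod(z))]
  s <- sort(s[s > 0])
  for (i in seq_len(3)) {
    dd <- 3 * tau * s^2 - 1
    ok <- abs(dd) > 1e-6
    s[ok] <- s[ok] - (tau * s[ok]^3 - s[ok] + 1)[ok] / dd[ok]
  }
  s
}

#' Potential landscape at fixed shear
#'
#' Locates the critical points of the potential
#' \eqn{\tilde U_{\tilde\tau}(q)} on the physical domain `[0, q_m]` and
#' classifies the regime:
#' \describe{
#'   \item{`folded_bistable`}{(\eqn{\tilde\tau < \tilde\tau_*}) minima at
#'     `q = 0` and `q = q_m`, barrier between them (`q_barrier = 1` exactly at
#'     zero shear).}
#'   \item{`partial_bistable`}{(\eqn{\tilde\tau_* < \tilde\tau <
#'     \tilde\tau_c}) minima at `q = 0` and at the interior partially unfolded
#'     state `q_partial`, barrier `q_barrier` between them.}
#'   \item{`monostable_unfolded`}{(\eqn{\tilde\tau \ge \tilde\tau_c}) the only
#'     minimum is the totally unfolded state; no interior critical points.}
#' }
#' Stationarity is solved as the cubic \eqn{\tilde\tau s^3 - s + 1 = 0} in
#' \eqn{s = q^{1/7}}, which has a closed-form discriminant and avoids
#' fractional-power bracketing failures near the fold.  An interior root at or
#' beyond `q_m` is clipped (the minimum is then the folded state itself).
#'
#' @param tau Dimensionless shear, `tau >= 0` (scalar).
#' @inheritParams unfolding_degree
#' @return An object of class `vwf_landscape`: a list with `tau`, `regime`,
#'   `q_barrier` (`NA` above the fold), `q_partial` (`NA` outside the
#'   partial-bistable regime), the potential energies `U_barrier` and `U_qm`,
#'   and the `params` used.
#' @examples
#' landscape_at(0.1, vwf_multimer(36))
#' @export
landscape_at <- function(tau, params) {
  params <- as_vwf_multimer(params)
  if (length(tau) != 1L) {
    abort("`tau` must be a scalar; map over a grid for tables.",
      class = "vwfdyn_domain_error"
    )
  }
  check_nonneg(tau, "tau")
  q_m <- params$q_m
  s <- stationary_s(tau)
  if (length(s) == 0L) {
    regime <- "monostable_unfolded"
    q_barrier <- NA_real_
    q_partial <- NA_real_
  } else if (length(s) == 1L) {
    # zero shear: degenerate cubic, barrier pinned at the saddle q_s = 1
    regime <- "folded_bistable"
    q_barrier <- s^7
    q_partial <- NA_real_
  } else {
    q_barrier <- s[1]^7
    q_partial <- s[2]^7
    if (q_partial >= q_m) {
      regime <- "folded_bistable"
      q_partial <- NA_real_
    } else {
      regime <- "partial_bistable"
    }
  }
  structure(
    list(
      tau = tau,
      regime = regime,
      q_barrier = q_barrier,
      q_partial = q_partial,
      U_barrier = if (is.na(q_barrier)) NA_real_ else potential_energy(q_barrier, tau),
      U_qm = potential_energy(q_m, tau),
      params = params
    ),
    class = "vwf_landscape"
  )
}

#' @export
print.vwf_landscape <- function(x, ...) {
  cat(sprintf(
    "<vwf_landscape> N = %d, tau = %.6g, regime = %s\n",
    x$params$N, x$tau, x$regime
  ))
  if (!is.na(x$q_barrier)) {
    cat(sprintf("  barrier: q = %.6g, U = %.6g\n", x$q_barrier, x$U_barrier))
  }
  if (!is.na(x$q_partial)) {
    cat(sprintf("  partial minimum: q = %.6g\n", x$q_partial))
  }
  cat(sprintf("  folded state: q_m = %.6g, U = %.6g\n", x$params$q_m, x$U_qm))
  invisible(x)
}

#' Bifurcation diagram of conformational equilibria
#'
#' Tabulates, for each shear value on a grid, the equilibrium branches of the
#' unfolding degree `u`: the totally unfolded branch (`u = 1`, stable at every
#' shear), the folded branch (`u = 0`, present below the detachment shear
#' \eqn{\tilde\tau_*}), the partially unfolded stable branch (between
#' \eqn{\tilde\tau_*} and the fold \eqn{\tilde\tau_c}) and the unstable barrier
#' branch (below \eqn{\tilde\tau_c}).
#'
#' @inheritParams unfolding_degree
#' @param tau_grid Non-negative, sorted vector of dimensionless shear values.
#' @return A tibble of class `vwf_bifurcation` with columns `tau`, `branch`
#'   (`"unfolded"`, `"folded"`, `"partial"`, `"unstable"`), `q`, `u` and
#'   `stable`; the multimer is attached as attribute `params`.
#' @examples
#' bifurcation_diagram(vwf_multimer(36), seq(0, 0.2, by = 0.05))
#' @export
bifurcation_diagram <- function(params, tau_grid) {
  params <- as_vwf_multimer(params)
  check_nonneg(tau_grid, "tau_grid")
  if (is.unsorted(tau_grid)) {
    abort("`tau_grid` must be sorted increasingly.", class = "vwfdyn_domain_error")
  }
  rows <- purrr::map(tau_grid, function(tt) {
    ls <- landscape_at(tt, params)
    branch <- "unfolded"
    q <- 0
    stable <- TRUE
    if (identical(ls$regime, "folded_bistable")) {
      branch <- c(branch, "folded")
      q <- c(q, params$q_m)
      stable <- c(stable, TRUE)
    }
    if (!is.na(ls$q_partial)) {
      branch <- c(branch, "partial")
      q <- c(q, ls$q_partial)
      stable <- c(stable, TRUE)
    }
    if (!is.na(ls$q_barrier)) {
      branch <- c(branch, "unstable")
      q <- c(q, ls$q_barrier)
      stable <- c(stable, FALSE)
    }
    tibble::tibble(tau = tt, branch = branch, q = q, stable = stable)
  })
  out <- dplyr::bind_rows(rows)
  out$u <- unfolding_degree(pmin(out$q, params$q_m), params)
  out <- out[, c("tau", "branch", "q", "u", "stable")]
  attr(out, "params") <- params
  class(out) <- c("vwf_bifurcation", class(out))
  out
}
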