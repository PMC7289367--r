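#' Shear-stress waveforms
#'
#' A shear profile is a non-negative function of dimensionless time with finite
#' support: the shear history a platelet experiences along its trajectory, e.g.
#' while transiting a stenosis.  Analytic constructors carry closed-form
#' integrals, so [cumulative_shear()] is exact; sampled profiles (typically CSV
#' exports from CFD) are interpolated piecewise-linearly, for which the
#' trapezoidal integral is also exact.  Every profile evaluates to exactly 0
#' outside its support — a clean switch-off is what makes the separatrix test
#' at the exit time exact.
#'
#' @name shear_profiles
#' @return An object of class `vwf_shear_profile`: a list with elements
#'   `kind`, `fun` (vectorized evaluator), `support` (`c(t_start, t_end)`),
#'   `breaks` (times where the waveform is non-smooth, used to split ODE
#'   integration), `integral` (`function(a, b)` exact integral) and `params`.
NULL

new_shear_profile <- function(kind, fun, support, breaks, integral, params) {
  structure(
    list(
      kind = kind, fun = fun, support = support,
      breaks = sort(unique(breaks)), integral = integral, params = params
    ),
    class = "vwf_shear_profile"
  )
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite scalar.", name),
      class = "vwfdyn_domain_error"
    )
  }
  invisible(x)
}

#' @export
print.vwf_shear_profile <- function(x, ...) {
  cat(sprintf(
    "<vwf_shear_profile> %s on [%.6g, %.6g], integral = %.6g\n",
    x$kind, x$support[1], x$support[2], x$integral(x$support[1], x$support[2])
  ))
  invisible(x)
}

#' Evaluate a shear profile
#'
#' @param profile A `vwf_shear_profile`.
#' @param t Dimensionless times (vectorized).
#' @return Dimensionless shear values; exactly 0 outside the support.
#' @export
shear_at <- function(profile, t) {
  stopifnot(inherits(profile, "vwf_shear_profile"))
  profile$fun(t)
}

#' @describeIn shear_profiles Rectangular impulse of amplitude `tau_m` on
#'   `[t_start, t_start + duration]`.
#' @param tau_m Dimensionless amplitude, `> 0`.
#' @param duration Impulse duration, `> 0`.
#' @param t_start Support start (default 0).
#' @export
shear_rectangular <- function(tau_m, duration, t_start = 0) {
  check_pos(tau_m, "tau_m")
  check_pos(duration, "duration")
  te <- t_start + duration
  new_shear_profile(
    kind = "rectangular",
    fun = function(t) ifelse(t >= t_start & t <= te, tau_m, 0),
    support = c(t_start, te),
    breaks = c(t_start, te),
    integral = function(a, b) tau_m * max(0, min(b, te) - max(a, t_start)),
    params = list(tau_m = tau_m, duration = duration)
  )
}

#' @describeIn shear_profiles Trapezoidal waveform: linear rise over `rise`,
#'   plateau at `tau_m` over `plateau`, linear fall over `fall`.  Degenerate
#'   ramps (`rise = 0` and/or `fall = 0`) reduce it to a rectangle.
#' @param rise,plateau,fall Non-negative phase durations (total `> 0`).
#' @export
shear_trapezoid <- function(tau_m, rise, plateau, fall, t_start = 0) {
  check_pos(tau_m, "tau_m")
  for (nm in c("rise", "plateau", "fall")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(sprintf("`%s` must be a non-negative scalar.", nm),
        class = "vwfdyn_domain_error"
      )
    }
  }
  total <- rise + plateau + fall
  if (total <= 0) {
    abort("trapezoid must have positive total duration.",
      class = "vwfdyn_domain_error"
    )
  }
  # cumulative integral of the unit-height shape from the support start
  cumint <- function(s) {
    s <- pmin(pmax(s, 0), total)
    r <- pmin(s, rise)
    p <- pmin(pmax(s - rise, 0), plateau)
    f <- pmax(s - rise - plateau, 0)
    up <- if (rise > 0) r^2 / (2 * rise) else 0
    dn <- if (fall > 0) f - f^2 / (2 * fall) else 0
    tau_m * (up + p + dn)
  }
  fun <- function(t) {
    s <- t - t_start
    up <- if (rise > 0) pmin(1, pmax(0, s / rise)) else as.numeric(s >= 0)
    dn <- if (fall > 0) pmin(1, pmax(0, (total - s) / fall)) else as.numeric(s <= total)
    tau_m * pmin(up, dn) * (s >= 0 & s <= total)
  }
  new_shear_profile(
    kind = "trapezoid",
    fun = fun,
    support = c(t_start, t_start + total),
    breaks = t_start + c(0, rise, rise + plateau, total),
    integral = function(a, b) max(0, cumint(b - t_start) - cumint(a - t_start)),
    params = list(tau_m = tau_m, rise = rise, plateau = plateau, fall = fall)
  )
}

#' @describeIn shear_profiles Gaussian pulse of peak `tau_m`, centre `centre`
#'   and width (standard deviation) `width`, truncated at four widths either
#'   side; the integral uses the error-function area of the clipped span.
#' @param centre Pulse centre time.
#' @param width Pulse width (standard deviation), `> 0`.
#' @export
shear_gaussian_pulse <- function(tau_m, centre, width) {
  check_pos(tau_m, "tau_m")
  check_pos(width, "width")
  if (!is.numeric(centre) || length(centre) != 1L || !is.finite(centre)) {
    abort("`centre` must be a finite scalar.", class = "vwfdyn_domain_error")
  }
  lo <- centre - 4 * width
  hi <- centre + 4 * width
  new_shear_profile(
    kind = "gaussian_pulse",
    fun = function(t) {
      ifelse(t >= lo & t <= hi, tau_m * exp(-(t - centre)^2 / (2 * width^2)), 0)
    },
    support = c(lo, hi),
    breaks = c(lo, hi),
    integral = function(a, b) {
      a <- max(a, lo)
      b <- min(b, hi)
      if (b <= a) {
        return(0)
      }
      tau_m * width * sqrt(2 * pi) *
        (pnorm((b - centre) / width) - pnorm((a - centre) / width))
    },
    params = list(tau_m = tau_m, centre = centre, width = width)
  )
}

#' @describeIn shear_profiles Half-sine arch `tau_m * sin(pi t / duration)` on
#'   `[t_start, t_start + duration]`; total area `2 tau_m duration / pi`.
#' @export
shear_half_sine <- function(tau_m, duration, t_start = 0) {
  check_pos(tau_m, "tau_m")
  check_pos(duration, "duration")
  te <- t_start + duration
  cumint <- function(s) {
    s <- pmin(pmax(s, 0), duration)
    tau_m * duration / pi * (1 - cos(pi * s / duration))
  }
  new_shear_profile(
    kind = "half_sine",
    fun = function(t) {
      s <- t - t_start
      # sin can round a hair below zero at the endpoints; the waveform
      # contract is tau >= 0 everywhere
      pmax(0, ifelse(s >= 0 & s <= duration, tau_m * sin(pi * s / duration), 0))
    },
    support = c(t_start, te),
    breaks = c(t_start, te),
    integral = function(a, b) max(0, cumint(b - t_start) - cumint(a - t_start)),
    params = list(tau_m = tau_m, duration = duration)
  )
}

#' @describeIn shear_profiles Sampled waveform: piecewise-linear interpolation
#'   between strictly increasing sample times; zero outside the sampled span.
#' @param time Strictly increasing sample times (length `>= 2`).
#' @param stress Non-negative shear values at `time`.
#' @export
shear_sampled <- function(time, stress) {
  if (length(time) < 2L || length(stress) != length(time)) {
    abort("a sampled profile needs >= 2 (time, stress) pairs of equal length.",
      class = "vwfdyn_csv_rows"
    )
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    abort("sample times must be finite and strictly increasing.",
      class = "vwfdyn_csv_monotonic"
    )
  }
  if (any(!is.finite(stress)) || any(stress < 0)) {
    abort("shear stress samples must be finite and non-negative.",
      class = "vwfdyn_csv_negative"
    )
  }
  lo <- time[1]
  hi <- time[length(time)]
  new_shear_profile(
    kind = "sampled",
    fun = function(t) {
      v <- approx(time, stress, xout = t, rule = 1)$y
      v[is.na(v)] <- 0
      v
    },
    support = c(lo, hi),
    breaks = c(lo, hi),
    integral = function(a, b) pwl_integral(time, stress, a, b),
    params = list(time = time, stress = stress)
  )
}

# Exact integral of a piecewise-linear curve over [a, b] (clipped to the knot
# span) — trapezoids between knots, with interpolated endpoints.
pwl_integral <- function(tk, vk, a, b) {
  a <- max(a, tk[1])
  b <- min(b, tk[length(tk)])
  if (b <= a) {
    return(0)
  }
  idx <- which(tk > a & tk < b)
  ts <- c(a, tk[idx], b)
  vs <- approx(tk, vk, xout = ts)$y
  sum(diff(ts) * (head(vs, -1) + tail(vs, -1)) / 2)
}

#' Read a shear-stress time series from CSV
#'
#' Expects exactly two named columns, `time` and `shear_stress`
#' (comma-separated, header required, decimal point, at least two rows,
#' strictly increasing times, non-negative stress).  In `"physical"` units
#' mode the stress column is divided by the stress scale of the supplied
#' [physical_scale()] (and the time column by its time scale, when the scale
#' carries one — a [calibrate_stress_scale()] fragment does not).
#'
#' @param path Path to the CSV file.
#' @param units_mode `"dimensionless"` (default) or `"physical"`.
#' @param scale A [physical_scale()]; required in physical mode.
#' @return A sampled `vwf_shear_profile`.
#' @export
read_profile_csv <- function(path, units_mode = c("dimensionless", "physical"),
                             scale = NULL) {
  units_mode <- match.arg(units_mode)
  if (!file.exists(path)) {
    abort(sprintf("profile file not found: %s", path), class = "vwfdyn_csv_missing")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!setequal(names(df), c("time", "shear_stress")) || ncol(df) != 2L) {
    abort(
      "profile CSV must have exactly the two columns `time` and `shear_stress`.",
      class = "vwfdyn_csv_columns"
    )
  }
  if (nrow(df) < 2L) {
    abort("profile CSV needs at least two rows.", class = "vwfdyn_csv_rows")
  }
  tt <- as.numeric(df$time)
  ss <- as.numeric(df$shear_stress)
  if (any(!is.finite(tt)) || any(diff(tt) <= 0)) {
    abort("`time` must be strictly increasing (duplicates are rejected).",
      class = "vwfdyn_csv_monotonic"
    )
  }
  if (any(!is.finite(ss)) || any(ss < 0)) {
    abort("`shear_stress` must be non-negative.", class = "vwfdyn_csv_negative")
  }
  if (units_mode == "physical") {
    if (is.null(scale) || !inherits(scale, "vwf_physical_scale")) {
      abort("physical units mode requires a `physical_scale()` object.",
        class = "vwfdyn_csv_scale"
      )
    }
    ss <- stress_to_dimensionless(ss, scale)
    if (is.finite(scale$time_scale)) {
      tt <- time_to_dimensionless(tt, scale)
    }
  }
  shear_sampled(tt, ss)
}

#' Write a shear profile to CSV
#'
#' Samples the profile on a regular grid of step `sampling_step` across its
#' support (support edges always included) and writes the
#' `time,shear_stress` schema read back by [read_profile_csv()].  Reading the
#' file back reproduces the written values exactly at the sample times.
#'
#' @param profile A `vwf_shear_profile`.
#' @param path Output path.
#' @param sampling_step Positive sampling step.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path, sampling_step) {
  stopifnot(inherits(profile, "vwf_shear_profile"))
  check_pos(sampling_step, "sampling_step")
  a <- profile$support[1]
  b <- profile$support[2]
  if (!(b > a)) {
    abort("profile support is empty; nothing to write.",
      class = "vwfdyn_domain_error"
    )
  }
  tt <- sort(unique(c(seq(a, b, by = sampling_step), b)))
  readr::write_csv(
    tibble::tibble(time = tt, shear_stress = profile$fun(tt)),
    path, progress = FALSE
  )
  invisible(path)
}
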