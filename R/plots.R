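#' Plot a simulated trajectory
#'
#' `type = "time"` shows the unfolding degree against time with the driving
#' shear overlaid (rescaled); `type = "phase"` shows the `(q, qdot)` phase
#' portrait with the zero-shear separatrix.
#'
#' @param object A `vwf_trajectory`.
#' @param type `"time"` or `"phase"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vwf_trajectory
#' @export
autoplot.vwf_trajectory <- function(object, type = c("time", "phase"), ...) {
  type <- match.arg(type)
  s <- object$samples
  if (type == "time") {
    sc <- max(s$tau, 1e-12)
    ggplot2::ggplot(s, ggplot2::aes(x = .data$t)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$u, colour = "unfolding degree u")) +
      ggplot2::geom_line(ggplot2::aes(y = .data$tau / sc, colour = "shear (rescaled)"),
        linetype = "dashed"
      ) +
      ggplot2::scale_colour_manual(values = c(
        "unfolding degree u" = "black",
        "shear (rescaled)" = "red"
      )) +
      ggplot2::labs(
        x = "dimensionless time", y = "unfolding degree u", colour = NULL,
        title = sprintf("VWF unfolding trajectory (N = %d)", object$params$N)
      ) +
      ggplot2::theme_minimal()
  } else {
    p <- object$params
    qg <- seq(1e-6, p$q_m, length.out = 400)
    e_sep <- 0.125
    sep <- tibble::tibble(
      q = rep(qg, 2),
      qdot = c(
        -sqrt(pmax(0, 2 * (e_sep - potential_energy(qg, 0)))),
        sqrt(pmax(0, 2 * (e_sep - potential_energy(qg, 0))))
      )
    )
    ggplot2::ggplot(s, ggplot2::aes(x = .data$q, y = .data$qdot)) +
      ggplot2::geom_path(colour = "red") +
      ggplot2::geom_path(
        data = sep, ggplot2::aes(x = .data$q, y = .data$qdot),
        inherit.aes = FALSE, linewidth = 0.3
      ) +
      ggplot2::labs(
        x = "q", y = "qdot",
        title = sprintf("Phase portrait (N = %d); thin line: zero-shear separatrix", p$N)
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot a potential landscape
#'
#' Potential energy profile at the landscape's shear, with critical points
#' marked.
#'
#' @param object A `vwf_landscape`.
#' @param n Grid resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vwf_landscape
#' @export
autoplot.vwf_landscape <- function(object, n = 400, ...) {
  p <- object$params
  qg <- seq(0, p$q_m, length.out = n)
  df <- tibble::tibble(q = qg, U = potential_energy(qg, object$tau))
  pts <- tidy.vwf_landscape(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$U)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$q, y = .data$energy, shape = .data$stable),
      size = 2
    ) +
    ggplot2::labs(
      x = "q", y = "potential energy",
      title = sprintf(
        "Potential landscape at tau = %.4g (%s)",
        object$tau, object$regime
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation diagram
#'
#' Equilibrium unfolding degree against shear, stable branches solid and the
#' unstable barrier branch dashed.
#'
#' @param object A `vwf_bifurcation` tibble from [bifurcation_diagram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vwf_bifurcation
#' @export
autoplot.vwf_bifurcation <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$tau, y = .data$u, group = .data$branch,
      linetype = .data$stable
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"),
      labels = c(`TRUE` = "stable", `FALSE` = "unstable"), name = NULL
    ) +
    ggplot2::labs(
      x = "dimensionless shear", y = "unfolding degree u",
      title = "Conformational equilibria of the grafted VWF multimer"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a critical-duration curve
#'
#' Log-log critical impulse duration against amplitude, with the cumulative
#' shear stress hyperbola `t_F = CSS0 / tau_m` (dashed) and the amplitude
#' asymptote (dotted vertical).
#'
#' @param object A `vwf_critical_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vwf_critical_curve
#' @export
autoplot.vwf_critical_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[is.finite(df$t_F), ]
  c0 <- attr(object, "css0")
  th <- attr(object, "tau_hash")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau_m, y = .data$t_F)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_function(fun = function(x) c0 / x, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = th, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "impulse amplitude tau_m", y = "critical duration t_F",
      title = sprintf(
        "Critical impulse duration (N = %d); dashed: tau_m * t_F = CSS0",
        attr(object, "params")$N
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
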