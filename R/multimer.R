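#' Multimer parameters for a surface-grafted VWF molecule
#'
#' A von Willebrand factor multimer is modelled as a chain of `N` identical
#' subunits whose conformation is tracked by the single dimensionless
#' coordinate \eqn{q = (2r/d)^7}, where `r` is the radius of the still-globular
#' part and `d` the subunit size.  The fully folded state sits at
#' \eqn{q_m = (3N/2)^{7/3}}, the totally unfolded state at \eqn{q = 0}.
#'
#' Multimers with fewer than three subunits are rejected: below that size the
#' fold point of the potential can leave the physical domain \eqn{(0, q_m)} and
#' the three-regime structure of the landscape (folded-bistable,
#' partial-bistable, monostable-unfolded) degenerates.
#'
#' @param N Integer subunit count, `N >= 3`.
#'
#' @return An object of class `vwf_multimer`: a list with elements `N` and the
#'   derived folded-state coordinate `q_m`.
#' @examples
#' p <- vwf_multimer(36)
#' p$q_m # (3 * 36 / 2)^(7/3) ~ 1.10e4
#' @export
vwf_multimer <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N != round(N)) {
    abort("`N` must be a single finite integer subunit count.",
      class = "vwfdyn_domain_error"
    )
  }
  if (N < 3) {
    abort(
      "`N` must be at least 3: smaller multimers collapse the three-regime potential structure.",
      class = "vwfdyn_domain_error"
    )
  }
  structure(
    list(N = as.integer(N), q_m = (1.5 * N)^(7 / 3)),
    class = "vwf_multimer"
  )
}

#' @export
print.vwf_multimer <- function(x, ...) {
  cat(sprintf(
    "<vwf_multimer> N = %d subunits, q_m = %.6g\n", x$N, x$q_m
  ))
  invisible(x)
}

# Accept either a vwf_multimer or a bare subunit count.
as_vwf_multimer <- function(x) {
  if (inherits(x, "vwf_multimer")) {
    return(x)
  }
  if (is.numeric(x) && length(x) == 1L) {
    return(vwf_multimer(x))
  }
  abort("`params` must be a vwf_multimer object or a single subunit count.",
    class = "vwfdyn_domain_error"
  )
}

#' Contour length of the multimer
#'
#' The fully extended length `L = N * d` in units of the subunit size `d`.
#'
#' @param params A [vwf_multimer()] object (or a subunit count).
#' @param d Subunit size; defaults to 1 so the result is in subunit units.
#' @return Numeric contour length.
#' @export
contour_length <- function(params, d = 1) {
  params <- as_vwf_multimer(params)
  if (!is.numeric(d) || length(d) != 1L || d <= 0) {
    abort("`d` must be a positive scalar.", class = "vwfdyn_domain_error")
  }
  params$N * d
}
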