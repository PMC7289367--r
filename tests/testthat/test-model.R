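test_that("multimer parameters derive the folded-state coordinate and guard small N", {
  p <- vwf_multimer(36)
  expect_identical(p$N, 36L)
  expect_equal(p$q_m, 54^(7 / 3))
  expect_equal(contour_length(p, d = 2), 72)
  expect_error(vwf_multimer(2), class = "vwfdyn_domain_error")
  expect_error(vwf_multimer(3.5), class = "vwfdyn_domain_error")
})

test_that("potential energy matches the closed form at landmark points", {
  expect_identical(potential_energy(0, 0.3), 0)
  expect_equal(potential_energy(1, 0), 0.125)
  # folded state of N = 36 at zero shear, evaluated from the raw powers
  expect_equal(
    potential_energy(p36$q_m, 0),
    -(7 / 8) * 54^(8 / 3) + 54^(7 / 3)
  )
  expect_lt(abs(potential_energy(p36$q_m, 0) / -2.5431e4 - 1), 1e-4)
  expect_error(potential_energy(-1, 0), class = "vwfdyn_domain_error")
  expect_error(potential_energy(1, -0.1), class = "vwfdyn_domain_error")
})

test_that("acceleration is minus the potential gradient", {
  expect_identical(acceleration(1, 0), 0)
  expect_identical(acceleration(0, 7), -1)
  # q_m^(3/7) = 3N/2, so the shear term is exactly -tau * 54
  expect_equal(acceleration(p36$q_m, 0.2), -0.2 * 54 + 54^(1 / 3) - 1)
  set.seed(42)
  q <- exp(runif(100, log(1e-2), log(p36$q_m)))
  tau <- runif(100, 0, 0.3)
  h <- pmax(1e-6, 1e-7 * q)
  grad <- (potential_energy(q + h, tau) - potential_energy(q - h, tau)) / (2 * h)
  expect_equal(acceleration(q, tau), -grad, tolerance = 1e-6)
})

test_that("unfolding degree is a bijection between [0, q_m] and [0, 1]", {
  for (N in c(3, 36, 100)) {
    p <- vwf_multimer(N)
    expect_identical(unfolding_degree(p$q_m, p), 0)
    expect_identical(unfolding_degree(0, p), 1)
    q <- seq(0, p$q_m, length.out = 101)
    u <- unfolding_degree(q, p)
    expect_true(all(diff(u) < 0))
    expect_equal(degree_to_coordinate(u, p), q, tolerance = 1e-10)
  }
  # (2^-7)^(3/7) = 1/8 exactly
  expect_equal(unfolding_degree(p36$q_m * 2^-7, p36), 0.875)
  expect_error(unfolding_degree(p36$q_m * 1.01, p36), class = "vwfdyn_domain_error")
})

test_that("landscape regimes and critical points follow the stationarity cubic", {
  l0 <- landscape_at(0, p36)
  expect_identical(l0$regime, "folded_bistable")
  expect_identical(l0$q_barrier, 1)
  expect_true(is.na(l0$q_partial))

  l1 <- landscape_at(0.1, p36)
  expect_identical(l1$regime, "partial_bistable")
  expect_lt(abs(l1$q_barrier / 2.72 - 1), 0.01)
  expect_lt(abs(l1$q_partial / 486 - 1), 0.02)
  expect_true(0 < l1$q_barrier && l1$q_barrier < l1$q_partial &&
    l1$q_partial < p36$q_m)

  l2 <- landscape_at(0.2, p36)
  expect_identical(l2$regime, "monostable_unfolded")
  expect_true(is.na(l2$q_barrier) && is.na(l2$q_partial))

  # stationary points really are stationary
  for (tt in c(0.02, 0.06, 0.1, 0.14)) {
    l <- landscape_at(tt, p36)
    expect_lt(abs(acceleration(l$q_barrier, tt)), 1e-9)
    if (!is.na(l$q_partial)) expect_lt(abs(acceleration(l$q_partial, tt)), 1e-9)
  }
})

test_that("regime boundaries agree with tau_star and tau_c closed forms", {
  for (N in c(3, 7, 36, 100)) {
    p <- vwf_multimer(N)
    ts <- tau_star(p)
    expect_equal(ts, ((1.5 * N)^(1 / 3) - 1) / (1.5 * N))
    expect_identical(tau_c(p), 4 / 27)
    expect_lt(ts, tau_c(p))
    eps <- 1e-4
    expect_identical(landscape_at(ts * (1 + eps), p)$regime, "partial_bistable")
    expect_identical(landscape_at(ts * (1 - eps), p)$regime, "folded_bistable")
    expect_identical(landscape_at(4 / 27 + 1e-6, p)$regime, "monostable_unfolded")
    expect_identical(landscape_at(4 / 27 - 1e-6, p)$regime, "partial_bistable")
    # brute-force stationary-point count flips 2 -> 0 across the fold
    expect_identical(count_stationary_points(4 / 27 - 1e-6, N), 2L)
    expect_identical(count_stationary_points(4 / 27 + 1e-6, N), 0L)
  }
  # tau_star decreases with multimer size
  tsv <- vapply(3:100, function(N) tau_star(vwf_multimer(N)), numeric(1))
  expect_true(all(diff(tsv) < 0))
})

test_that("saddle momentum matches the energy drop and the css0 identity", {
  expect_lt(abs(saddle_momentum(p36) / 225.52 - 1), 1e-4)
  expect_lt(saddle_momentum(vwf_multimer(3)), saddle_momentum(p36))
  for (N in c(3, 12, 36, 250)) {
    p <- vwf_multimer(N)
    expect_equal(saddle_momentum(p), css0(p) * p$q_m^(3 / 7), tolerance = 1e-12)
  }
})

test_that("bifurcation diagram tabulates the branches of each regime", {
  bd <- bifurcation_diagram(p36, c(0, 0.1, 0.2))
  r0 <- bd[bd$tau == 0, ]
  expect_setequal(r0$branch, c("unfolded", "folded", "unstable"))
  expect_setequal(r0$u[r0$stable], c(0, 1))
  expect_equal(r0$q[r0$branch == "unstable"], 1)

  r1 <- bd[bd$tau == 0.1, ]
  expect_setequal(r1$branch, c("unfolded", "partial", "unstable"))
  u_part <- r1$u[r1$branch == "partial"]
  expect_lt(abs(u_part / 0.7357 - 1), 0.01)

  r2 <- bd[bd$tau == 0.2, ]
  expect_identical(r2$branch, "unfolded")
  expect_identical(r2$u, 1)
  expect_error(bifurcation_diagram(p36, c(0.2, 0.1)), class = "vwfdyn_domain_error")
})
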