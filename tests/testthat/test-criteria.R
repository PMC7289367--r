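test_that("cumulative shear stress integrates waveforms exactly", {
  expect_identical(cumulative_shear(shear_rectangular(2, 3)), 6)
  expect_equal(cumulative_shear(shear_trapezoid(4, 0.5, 1, 0.5)), 6)
  expect_identical(cumulative_shear(shear_sampled(c(0, 1), c(0, 0))), 0)
  # sub-span and beyond-support behaviour
  pr <- shear_rectangular(2, 3)
  expect_identical(cumulative_shear(pr, 1, 2), 2)
  expect_identical(cumulative_shear(pr, -10, 100), 6)
  expect_error(cumulative_shear(pr, 2, 2), class = "vwfdyn_domain_error")
})

test_that("the css0 closed form matches the separatrix-energy definition", {
  expect_lt(abs(css0(p36) / 4.176 - 1), 1e-3)
  # independent route: sqrt(2 (U0(1) - U0(q_m))) / q_m^(3/7)
  for (N in c(3, 5, 36, 200, 1000)) {
    p <- vwf_multimer(N)
    oracle <- sqrt(2 * (potential_energy(1, 0) - potential_energy(p$q_m, 0))) /
      p$q_m^(3 / 7)
    expect_equal(css0(p), oracle, tolerance = 1e-13)
  }
  expect_equal(css0(vwf_multimer(3)), 1.2167, tolerance = 1e-4)
  v <- vapply(3:100, function(N) css0(vwf_multimer(N)), numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("the necessary condition compares CSS against the threshold", {
  expect_false(necessary_condition(shear_rectangular(10, 0.3), p36)) # CSS 3.0
  expect_true(necessary_condition(shear_rectangular(10, 0.5), p36)) # CSS 5.0
  expect_false(necessary_condition(shear_sampled(c(0, 1), c(0, 0)), p36))
})

test_that("the momentum sufficient condition requires inward super-saddle momentum", {
  expect_true(momentum_sufficient_condition(-300, p36))
  expect_false(momentum_sufficient_condition(0, p36))
  expect_false(momentum_sufficient_condition(300, p36))
  expect_false(momentum_sufficient_condition(-225, p36)) # just below |qdot_A|
})

test_that("the amplitude asymptote sits between detachment and the fold", {
  th <- tau_threshold(p36)
  expect_lt(abs(th / 0.0610 - 1), 0.01)
  for (N in c(3, 4, 10, 36, 70, 100)) {
    p <- vwf_multimer(N)
    t_h <- tau_threshold(p)
    expect_lt(tau_star(p), t_h)
    expect_lt(t_h, tau_c(p))
    # at the root, barrier energy equals the from-rest energy
    l <- landscape_at(t_h, p)
    expect_lt(abs(l$U_qm - l$U_barrier) / abs(l$U_qm), 1e-8)
  }
})

test_that("critical impulse durations shadow the CSS hyperbola at high amplitude", {
  t10 <- critical_duration(10, p36)
  expect_lt(abs(t10 * 10 / css0(p36) - 1), 0.01)
  expect_gt(critical_duration(5, p36), t10)
  expect_identical(critical_duration(0.05, p36), Inf)
  expect_identical(critical_duration(tau_threshold(p36) * 0.999, p36), Inf)
})

test_that("the critical curve is monotone, bounded by the hyperbola, and diverges at the asymptote", {
  th <- tau_threshold(p36)
  grid <- sort(c(1.05 * th, 0.08, 0.12, 2 * 4 / 27, 1, 5, 0.03))
  cc <- critical_curve(p36, grid)
  expect_identical(cc$never, !is.finite(cc$t_F))
  expect_true(cc$never[cc$tau_m == 0.03])
  fin <- cc[!cc$never, ]
  expect_true(all(diff(fin$t_F) < 0))
  expect_true(all(fin$tau_m * fin$t_F >= css0(p36)))
  expect_gt(
    fin$t_F[fin$tau_m == 1.05 * th],
    10 * fin$t_F[abs(fin$tau_m - 2 * 4 / 27) < 1e-12]
  )
  g <- glance(cc)
  expect_equal(g$tau_hash, th)
  expect_equal(g$css0, css0(p36))
})

test_that("classification reproduces the rectangular-impulse case studies", {
  r1 <- classify_profile(shear_rectangular(10, 1), p36)
  expect_true(r1$activated && r1$necessary_met)
  expect_true(r1$momentum_sufficient_met || r1$fully_unfolded)

  r2 <- classify_profile(shear_rectangular(10, 0.3), p36)
  expect_false(r2$activated)
  expect_false(r2$necessary_met)

  # parametric regime: sustained stress between the asymptote and the fold
  r3 <- classify_profile(shear_rectangular(0.13, 5000), p36)
  expect_true(r3$activated)
  expect_gt(r3$residual_momentum, 0)
})

test_that("activation verdicts respect the criteria implication chain", {
  set.seed(11)
  n_checked <- 0L
  for (i in 1:60) {
    pr <- random_profile()
    rep <- classify_profile(pr, p36)
    if (rep$momentum_sufficient_met) expect_true(rep$fully_unfolded)
    if (rep$fully_unfolded) expect_true(rep$necessary_met)
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 60L)
})

test_that("tidy and glance methods expose the report as tibbles", {
  rep <- classify_profile(shear_rectangular(10, 1), p36)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 3L)
  g <- glance(rep)
  expect_identical(nrow(g), 1L)
  expect_true(g$activated)
  tj <- tidy(rep$trajectory)
  expect_true(all(c("t", "q", "qdot", "tau", "u") %in% names(tj)))
  expect_identical(glance(rep$trajectory)$N, 36L)
})
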