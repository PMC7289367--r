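test_that("total energy and the separatrix test follow the zero-shear landscape", {
  expect_equal(total_energy(1, 0, 0), 0.125)
  expect_identical(total_energy(0, -3, 0.7), 4.5)
  # folded state at rest sits above the separatrix; super-saddle inward
  # momentum and sub-saddle positions dip below it
  expect_false(separatrix_test(p36$q_m, 0, p36))
  expect_true(separatrix_test(p36$q_m, -226, p36))
  expect_false(separatrix_test(p36$q_m, -225, p36))
  expect_true(separatrix_test(0.5, -1e-3, p36))
  # resting below the saddle still rolls down to the origin
  expect_true(separatrix_test(0.5, 0, p36))
  # outward motion with enough energy to clear the saddle escapes to folding
  expect_false(separatrix_test(0.5, 0.5, p36))
  expect_false(separatrix_test(1, 0, p36))
})

test_that("a folded molecule below the detachment shear stays pinned at the wall", {
  tr <- simulate_unfolding(shear_rectangular(0.04, 5), p36, t_end = 5)
  expect_true(all(abs(tr$samples$q - p36$q_m) < 1e-9 * p36$q_m))
  expect_false(tr$fully_unfolded)
  expect_identical(nrow(tr$events), 0L)
})

test_that("shear above the fold catastrophe unfolds a resting molecule completely", {
  tr <- simulate_unfolding(shear_rectangular(0.2, 100), p36, t_end = 100)
  expect_true(tr$fully_unfolded)
  expect_identical(tail(tr$samples$u, 1), 1)
  expect_identical(tail(tr$samples$q, 1), 0) # absorbing state at e = 0
  expect_true(any(tr$events$kind == "ORIGIN_CONTACT"))
})

test_that("shear between detachment and the asymptote oscillates without unfolding", {
  tr <- simulate_unfolding(shear_rectangular(0.055, 2000), p36, t_end = 900)
  expect_false(tr$fully_unfolded)
  expect_gt(min(tr$samples$q), 1000) # never near the unfolded state
  expect_true(all(tr$samples$q <= p36$q_m * (1 + 1e-9)))
})

test_that("energy is conserved on constant-shear spans at default tolerances", {
  tr <- simulate_unfolding(shear_rectangular(0.1, 12), p36,
    initial = vwf_state(486, -10, 0), t_end = 10
  )
  e <- total_energy(tr$samples$q, tr$samples$qdot, 0.1)
  expect_lt(max(abs(e - e[1])) / max(1, abs(e[1])), 1e-8)
  # reported samples never exit the physical domain
  expect_true(all(tr$samples$q >= 0 & tr$samples$q <= p36$q_m * (1 + 1e-12)))
})

test_that("an elastic origin bounce conserves energy across the contact", {
  tr <- simulate_unfolding(zero_shear(), p36,
    initial = vwf_state(0.5, -1, 0),
    boundary = boundary_spec(restitution = 1), t_end = 6,
    rtol = 1e-11, atol = 1e-11
  )
  expect_true(any(tr$events$kind == "ORIGIN_CONTACT"))
  i <- which(tr$samples$q == 0)[1]
  e <- total_energy(tr$samples$q, tr$samples$qdot, 0)
  expect_lt(abs(e[i + 1] - e[i - 1]) / max(1, abs(e[i - 1])), 1e-8)
  expect_lt(max(abs(e - e[1])) / max(1, abs(e[1])), 1e-7)
})

test_that("an inelastic contact terminates exactly in the unfolded absorbing state", {
  tr <- simulate_unfolding(zero_shear(), p36,
    initial = vwf_state(0.5, -1, 0),
    boundary = boundary_spec(restitution = 0), t_end = 6
  )
  expect_true(tr$fully_unfolded)
  expect_identical(tail(tr$samples$q, 1), 0)
  expect_lt(tail(tr$samples$t, 1), 6) # stopped at contact, not at t_end
})

test_that("forward-then-backward integration recovers the initial state", {
  pr <- shear_rectangular(0.1, 12)
  fw <- simulate_unfolding(pr, p36, initial = vwf_state(486, -10, 0), t_end = 5)
  fin <- tail(fw$samples, 1)
  bw <- simulate_unfolding(pr, p36,
    initial = vwf_state(fin$q, -fin$qdot, 0), t_end = 5
  )
  back <- tail(bw$samples, 1)
  expect_lt(abs(back$q - 486) / 486, 1e-6)
  expect_lt(abs(-back$qdot - (-10)) / 10, 1e-6)
})

test_that("the simulated verdict matches the separatrix test at impulse switch-off", {
  set.seed(7)
  for (i in 1:50) {
    tau_m <- exp(runif(1, log(0.3), log(10)))
    dur <- exp(runif(1, log(0.05), log(3)))
    pr <- shear_rectangular(tau_m, dur)
    tr <- simulate_unfolding(pr, p36, t_end = dur + 300)
    contact_during <- any(tr$events$kind == "ORIGIN_CONTACT" &
      tr$events$t <= dur + 1e-9)
    if (contact_during) {
      expect_true(tr$fully_unfolded)
    } else {
      sw <- tr$samples[which.min(abs(tr$samples$t - dur)), ]
      expect_identical(
        tr$fully_unfolded,
        separatrix_test(sw$q, sw$qdot, p36)
      )
    }
  }
})

test_that("the fixed-step Verlet audit mode tracks the adaptive solver", {
  tr <- simulate_unfolding(shear_rectangular(0.1, 12), p36,
    initial = vwf_state(486, -10, 0), t_end = 10,
    method = "verlet", dt = 1e-3
  )
  e <- total_energy(tr$samples$q, tr$samples$qdot, 0.1)
  expect_lt(max(abs(e - e[1])) / max(1, abs(e[1])), 1e-8)
  ad <- simulate_unfolding(shear_rectangular(0.1, 12), p36,
    initial = vwf_state(486, -10, 0), t_end = 10
  )
  expect_lt(abs(tail(tr$samples$q, 1) - tail(ad$samples$q, 1)) / 486, 1e-3)
})

test_that("degenerate inputs are rejected loudly", {
  expect_error(
    simulate_unfolding(shear_rectangular(1, 1), p36,
      initial = vwf_state(-1, 0, 0), t_end = 1
    ),
    class = "vwfdyn_domain_error"
  )
  expect_error(
    simulate_unfolding(shear_rectangular(1, 1), p36, t_end = -1),
    class = "vwfdyn_domain_error"
  )
  expect_error(boundary_spec(restitution = 1.5), class = "vwfdyn_domain_error")
})
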