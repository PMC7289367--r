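# Shared fixtures: everything is generated in code at test time.

p36 <- vwf_multimer(36)

# A profile that is zero over any span of interest (support far in the past),
# used to probe free motion at zero shear.
zero_shear <- function() shear_rectangular(1e-9, 1e-9, t_start = -100)

# Random finite-support waveform, for property-style tests.
random_profile <- function(tau_range = c(0.02, 8), dur_range = c(0.05, 100)) {
  tau_m <- exp(stats::runif(1, log(tau_range[1]), log(tau_range[2])))
  dur <- exp(stats::runif(1, log(dur_range[1]), log(dur_range[2])))
  kind <- sample(c("rectangular", "trapezoid", "half_sine", "gaussian"), 1)
  switch(kind,
    rectangular = shear_rectangular(tau_m, dur),
    trapezoid = shear_trapezoid(tau_m, dur / 4, dur / 2, dur / 4),
    half_sine = shear_half_sine(tau_m, dur),
    gaussian = shear_gaussian_pulse(tau_m, centre = dur, width = dur / 8)
  )
}

# Independent oracle: count stationary points of the potential on (0, q_m) by
# sign changes of the acceleration over a dense grid in s = q^(1/7), with
# extra resolution around the fold point s = 3/2.
count_stationary_points <- function(tau, N) {
  s_m <- (1.5 * N)^(1 / 3)
  s <- sort(unique(c(
    seq(1e-4, s_m, length.out = 1200),
    seq(max(1e-4, 1.5 - 0.05), min(s_m, 1.5 + 0.05), length.out = 4000)
  )))
  a <- -tau * s^3 + s - 1 # acceleration written in s
  sum(diff(sign(a)) != 0)
}
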