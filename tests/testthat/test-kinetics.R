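test_that("shipped presets load with the published conductances", {
  am <- load_scheme("AMPAR")
  expect_equal(am$conductance_pS, 12.5)
  expect_equal(length(am$states), 7)
  expect_equal(am$open_states, "O")

  nm <- load_scheme("NMDAR")
  expect_equal(nm$conductance_pS, 25)
  expect_equal(length(nm$states), 5)

  # uniform temperature factor applied to every rate
  expect_equal(am$temp_factor, am$q10^((am$temp_target - am$temp_ref) / 10))
  expect_true(all(am$q0 >= 0) && all(am$q1 >= 0))
})

test_that("scheme files are validated with informative errors", {
  path <- withr::local_tempfile(fileext = ".yml")
  base <- list(name = "bad", states = list("C", "O"), initial_state = "C",
               open_states = list("O"), conductance_pS = 10,
               transitions = list(
                 list(from = "C", to = "O", rate = 1e6, unit = "per_M_per_s"),
                 list(from = "O", to = "C", rate = 500, unit = "per_s")))

  bad <- base; bad$transitions[[1]]$rate <- -1
  yaml::write_yaml(bad, path)
  expect_error(load_scheme(path), "C -> O")

  bad <- base; bad$conductance_pS <- NULL
  yaml::write_yaml(bad, path)
  expect_error(load_scheme(path), "conductance")

  bad <- base; bad$transitions <- bad$transitions[2]
  yaml::write_yaml(bad, path)
  expect_error(load_scheme(path), "unreachable")

  bad <- base; bad$transitions[[1]]$unit <- "per_fortnight"
  yaml::write_yaml(bad, path)
  expect_error(load_scheme(path), "unit")

  expect_error(load_scheme("/nonexistent/scheme.yml"), "not found")

  yaml::write_yaml(base, path)
  sc <- load_scheme(path)
  expect_equal(length(sc$open_states), 1)

  # round trip through write_scheme
  path2 <- withr::local_tempfile(fileext = ".yml")
  write_scheme(sc, path2)
  sc2 <- load_scheme(path2)
  expect_equal(sc2$q0, sc$q0)
  expect_equal(sc2$q1, sc$q1)
})

test_that("hybrid propagation matches the closed-form two-state solution", {
  sc <- two_state_scheme(k_on = 1e7, k_off = 5e3)
  conc <- 1
  kon <- 1e7 * 1e-9 * conc; koff <- 5e3 * 1e-6  # per us
  p <- c(C = 1, O = 0)
  for (i in 1:2000) {
    p <- propagate_hybrid(p, sc, conc, dt = 0.1)
    if (i %% 200 == 0) {
      t <- i * 0.1
      exact <- kon / (kon + koff) * (1 - exp(-(kon + koff) * t))
      expect_equal(unname(p[["O"]]), exact, tolerance = 1e-3)
    }
  }
  # and on towards equilibrium with large sub-stepped steps
  for (i in 1:3000) p <- propagate_hybrid(p, sc, conc, 10)
  expect_equal(unname(p[["O"]]), kon / (kon + koff), tolerance = 1e-3)
})

test_that("hybrid propagation conserves probability and positivity", {
  sc <- load_scheme("AMPAR")
  p <- setNames(c(1, rep(0, 6)), sc$states)
  # zero ligand, all unbound: absorbing
  expect_equal(propagate_hybrid(p, sc, 0, 0.1), p)

  withr::with_seed(10, {
    for (rep in 1:20) {
      p <- stats::runif(7); p <- p / sum(p)
      conc <- stats::runif(1, 0, 50)  # includes stiff post-release spikes
      for (i in 1:50) p <- propagate_hybrid(p, sc, conc, 0.1)
      expect_true(all(p >= 0))
      expect_lt(abs(sum(p) - 1), 1e-9)
    }
  })
  expect_error(propagate_hybrid(c(0.5, 0.4, 0, 0, 0, 0, 0), sc, 1, 0.1),
               "sum")
})

test_that("long-run propagation reaches the generator's steady state", {
  sc <- load_scheme("AMPAR")
  conc <- 0.5
  ss <- steady_state(sc, conc)
  p <- setNames(c(1, rep(0, 6)), sc$states)
  # the desensitised branch recovers on the ~second scale; propagate far
  # beyond it with large (sub-stepped) steps
  for (i in 1:5000) p <- propagate_hybrid(p, sc, conc, 1000)
  expect_equal(unname(p), unname(ss), tolerance = 1e-4)
})

test_that("halving dt leaves the hybrid peak open fraction unchanged", {
  # prescribed concentration pulse, peak open fraction at two resolutions
  sc <- load_scheme("AMPAR")
  pulse <- function(t) 5 * exp(-t / 50)   # mM, t in us
  run <- function(dt) {
    p <- setNames(c(1, rep(0, 6)), sc$states)
    peak <- 0
    for (i in seq_len(round(1000 / dt)))
      { p <- propagate_hybrid(p, sc, pulse(i * dt), dt)
        peak <- max(peak, open_fraction(p, sc)) }
    peak
  }
  expect_equal(run(0.05), run(0.1), tolerance = 1e-3)
})

test_that("stochastic stepping is exact for waiting times and ergodic", {
  sc <- two_state_scheme(k_on = 1e7, k_off = 5e3)
  # all rates zero at zero ligand for the unbound state
  expect_equal(unname(propagate_stochastic(1L, sc, 0, 10)), 1L)

  conc <- 1
  kon <- 1e7 * 1e-9 * conc; koff <- 5e3 * 1e-6
  dt <- 5
  frac <- withr::with_seed(12, {
    s <- 1L; open_time <- 0
    for (i in 1:20000) {
      s <- propagate_stochastic(s, sc, conc, dt)
      open_time <- open_time + (s == 2L)
    }
    open_time / 20000
  })
  expect_equal(unname(frac), kon / (kon + koff), tolerance = 0.05)
})

test_that("open_fraction handles occupancy vectors and discrete states", {
  sc <- load_scheme("AMPAR")
  expect_equal(open_fraction(setNames(c(1, rep(0, 6)), sc$states), sc), 0)
  expect_equal(open_fraction("O", sc), 1)
  expect_equal(open_fraction(rep(1 / 7, 7), sc), 1 / 7)
  expect_equal(open_fraction(c("C0", "O", "C2", "O"), sc), 0.5)
})
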