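# Sweep machinery tests run on shortened traces (400-1500 us) with small
# ensembles: they exercise the bookkeeping, monotonicity and reproducibility,
# not the headline numbers (those live in test-acceptance.R).

short_base <- function(duration = 1200, n = 50, seed = 21)
  quick_config(n = n, duration = duration, seed = seed)

test_that("degenerate single-cell sweeps reproduce the baseline", {
  cfg <- short_base()
  sw <- sweep_density_constant(cfg, psd_radii = 110, n_trials = 3,
                               base_seed = 5)
  expect_equal(nrow(sw$cells), 1)
  expect_equal(sw$cells$n_receptors, 50)
  ens <- run_cell(cfg, "AMPAR", 200, 110, 50, 3, 5)$ensemble
  g <- glance(ens)
  expect_equal(sw$cells$mean_peak_pA,
               g$mean_peak_pA[g$kind == "AMPAR"])  # identical streams

  sw2 <- sweep_fixed_n(cfg, psd_radii = 110, n_trials = 3, base_seed = 5)
  expect_equal(sw2$cells$mean_peak_pA, sw$cells$mean_peak_pA)
})

test_that("peak current grows with receptor number at constant density", {
  sw <- sweep_density_constant(short_base(), psd_radii = c(80, 110, 150, 190),
                               n_trials = 6, base_seed = 6)
  cells <- dplyr::arrange(sw$cells, n_receptors)
  expect_equal(cells$n_receptors, round(50 * (cells$psd_radius / 110)^2))
  # monotone within ensemble error
  for (i in seq_len(nrow(cells) - 1)) {
    se <- sqrt(cells$sd_peak_pA[i]^2 / cells$n_trials[i] +
               cells$sd_peak_pA[i + 1]^2 / cells$n_trials[i + 1])
    expect_gt(cells$mean_peak_pA[i + 1] - cells$mean_peak_pA[i], -2 * se)
  }
  expect_gt(cells$mean_peak_pA[4], cells$mean_peak_pA[1])
  # disproportionality: % current gain < % receptor gain along the grid
  base <- cells[cells$psd_radius == 110, ]
  top <- cells[cells$psd_radius == 190, ]
  gain_i <- 100 * (top$mean_peak_pA / base$mean_peak_pA - 1)
  gain_n <- 100 * (top$n_receptors / base$n_receptors - 1)
  expect_lt(gain_i, gain_n)
  # linear fit table is produced
  expect_true("estimate" %in% names(sw$fits))
})

test_that("crowding a fixed pool boosts the peak; dispersal weakens it", {
  sw <- sweep_fixed_n(short_base(), psd_radii = c(70, 110, 160),
                      n_trials = 6, base_seed = 7)
  cells <- dplyr::arrange(sw$cells, psd_radius)
  expect_true(all(cells$n_receptors == 50))
  expect_true(all(diff(cells$mean_nn) > 0))  # NN grows with the disc
  expect_gt(cells$mean_peak_pA[1], cells$mean_peak_pA[2])
  expect_gt(cells$mean_peak_pA[2], cells$mean_peak_pA[3])
})

test_that("a wider cleft boosts the current, more so at high density", {
  cfg <- short_base()
  sw <- sweep_cleft_size(cfg, cleft_radii = c(180, 240),
                         n_receptors = c(25, 100), n_trials = 6,
                         base_seed = 8)
  cells <- sw$cells
  get <- function(R, n)
    cells$mean_peak_pA[cells$cleft_radius == R & cells$n_receptors == n]
  expect_gt(get(240, 25), get(180, 25))
  expect_gt(get(240, 100), get(180, 100))
  # interaction: absolute gain grows with receptor density
  expect_gt(get(240, 100) - get(180, 100), get(240, 25) - get(180, 25))
  # r_a > R cells are skipped with a warning
  expect_warning(sweep_cleft_size(cfg, cleft_radii = 100, n_trials = 1,
                                  base_seed = 8), "skipping")
})

test_that("parametric map gradients recover analytic surfaces", {
  cfg <- short_base()
  inj <- parametric_map(cfg, densities = 1:4, psd_radii = 1:4 * 10,
                        peak_fun = function(d, r) d + 2 * r)
  g <- inj$gradient
  expect_equal(nrow(g), 4)
  expect_true(all(abs(g$d_peak_d_density - 1) < 1e-9))
  expect_true(all(abs(g$d_peak_d_radius - 2) < 1e-9))
  nrm <- sqrt(1 + 4)
  expect_true(all(abs(g$dir_density - 1 / nrm) < 1e-9))

  flat <- parametric_map(cfg, densities = 1:3, psd_radii = 1:3 * 10,
                         peak_fun = function(d, r) 7)
  expect_true(all(flat$gradient$flat))
  expect_true(all(is.na(flat$gradient$dir_density)))

  expect_warning(parametric_map(cfg, densities = 1:2, psd_radii = 1:3 * 10,
                                peak_fun = function(d, r) d),
                 "3x3")
})

test_that("map cells agree exactly with 1-D sweeps sharing configurations", {
  cfg <- short_base(duration = 400)
  d0 <- 50 / (pi * 110^2)
  sw <- sweep_density_constant(cfg, psd_radii = c(90, 110, 130),
                               n_trials = 2, base_seed = 9)
  mp <- parametric_map(cfg, densities = d0 * c(0.9, 1, 1.1),
                       psd_radii = c(90, 110, 130), n_trials = 2,
                       base_seed = 9)
  # the (d0, 110) map cell has the same (kind, r_a, N, R) as the sweep's
  # baseline cell, hence the same streams and identical results
  map_cell <- mp$surface[mp$surface$density == d0 &
                           mp$surface$psd_radius == 110, ]
  sweep_cell <- sw$cells[sw$cells$psd_radius == 110, ]
  expect_equal(map_cell$n_receptors, sweep_cell$n_receptors)
  expect_equal(map_cell$mean_peak_pA, sweep_cell$mean_peak_pA)
})

test_that("polynomial fits recover known coefficients", {
  f <- fit_linear(1:6, 2 * (1:6) + 1)
  expect_equal(f$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(f$r_squared, 1)

  q <- fit_quadratic(-3:3, (-3:3)^2)
  expect_equal(q$coefficients$estimate[3], 1, tolerance = 1e-10)

  noisy <- withr::with_seed(13, {
    x <- seq(0, 1, length.out = 100)
    fit_linear(x, 3 * x + 1 + rnorm(100, sd = 0.1))
  })
  est <- noisy$coefficients
  expect_lt(abs(est$estimate[2] - 3), 3 * est$std_error[2])

  expect_error(fit_linear(1, 1), "at least")
  expect_error(fit_quadratic(c(1, 1, 1), c(1, 2, 3)), "rank")
})

test_that("potentiation percentages are invariant under gamma rescaling", {
  # doubled single-channel conductance must cancel exactly in the ratios
  shorten <- function(cfg) { cfg$duration <- 600; cfg }
  rep1 <- ltp_scenarios("AMPAR", n_trials = 2, base_seed = 14,
                        scenarios = "clust", config_tweaks = shorten)
  rep2 <- ltp_scenarios("AMPAR", n_trials = 2, base_seed = 14,
                        scenarios = "clust", config_tweaks = function(cfg) {
    cfg <- shorten(cfg)
    sc <- cfg$schemes[[1]]
    cfg$schemes[[1]] <- kinetic_scheme(
      sc$states, sc$transitions, sc$open_states,
      conductance_pS = 2 * sc$conductance_pS,
      q10 = sc$q10, temp_ref = sc$temp_ref, temp_target = sc$temp_target)
    cfg
  })
  expect_equal(rep2$test_mean_pA, 2 * rep1$test_mean_pA, tolerance = 1e-12)
  expect_equal(rep1$pct_change_peak, rep2$pct_change_peak, tolerance = 1e-10)
})
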