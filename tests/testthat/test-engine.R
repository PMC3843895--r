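test_that("current follows Ohm's law for a permanently open channel", {
  geom <- synapse_geometry()
  lay <- manual_layout(0, 0, psd_radius = 110)
  cfg <- trial_config(geom, lay, schemes = list(AMPAR = always_open_scheme()),
                      duration = 10, q = 1)
  tr <- tidy(run_trial(cfg, seed = 1))
  # 12.5 pS x 80 mV = 1.0 pA, inward
  expect_true(all(abs(tr$current_pA + 1.0) < 1e-12))
})

test_that("no release means no current; fixed seeds are bit-reproducible", {
  cfg <- quick_config(duration = 300, q = 0)
  tr <- tidy(run_trial(cfg, seed = 1))
  expect_true(all(tr$current_pA == 0))

  cfg2 <- quick_config(duration = 300)
  a <- tidy(run_trial(cfg2, seed = 5, stream = 2))
  b <- tidy(run_trial(cfg2, seed = 5, stream = 2))
  d <- tidy(run_trial(cfg2, seed = 5, stream = 3))
  expect_identical(a$current_pA, b$current_pA)
  expect_false(identical(a$current_pA, d$current_pA))
})

test_that("typical synapse: fast-rising sub-ms AMPAR current within bounds", {
  cfg <- quick_config(duration = 3000, seed = 2)
  tr <- run_trial(cfg, seed = 3)
  g <- glance(tr)
  peak <- g$peak_pA[g$kind == "AMPAR"]
  expect_gt(peak, 2)                   # a few to tens of pA
  expect_lt(peak, 50 * 12.5 * 80 / 1000)  # N gamma |Vm| hard bound
  expect_lt(g$peak_time_us[g$kind == "AMPAR"], 1000)
  expect_equal(tidy(tr)$current_pA[1], 0)  # zero current at t = 0
  expect_true(all(abs(tidy(tr)$current_pA) <= peak + 1e-12))
})

test_that("current is linear in conductance and driving force", {
  geom <- synapse_geometry()
  lay <- place_receptors(geom, 30, seed = 6)
  sc <- load_scheme("AMPAR")
  sc2 <- kinetic_scheme(sc$states, sc$transitions, sc$open_states,
                        conductance_pS = 2 * sc$conductance_pS,
                        q10 = sc$q10, temp_ref = sc$temp_ref,
                        temp_target = sc$temp_target)
  base <- trial_config(geom, lay, duration = 400)
  dbl <- trial_config(geom, lay, schemes = list(AMPAR = sc2), duration = 400)
  half_v <- trial_config(geom, lay, duration = 400, v_m = -40)
  a <- tidy(run_trial(base, seed = 7))$current_pA
  b <- tidy(run_trial(dbl, seed = 7))$current_pA
  v <- tidy(run_trial(half_v, seed = 7))$current_pA
  expect_equal(b, 2 * a, tolerance = 1e-12)
  expect_equal(v, a / 2, tolerance = 1e-12)
})

test_that("receptors far outside the glutamate footprint see ~no current", {
  geom <- synapse_geometry(cleft_radius = 2000, psd_radius = 1950,
                           outer_radius = 4000)
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  far <- manual_layout(1900 * cos(th), 1900 * sin(th), psd_radius = 1950)
  cfg <- trial_config(geom, far, duration = 1000)
  near_cfg <- quick_config(n = 20, duration = 1000)
  far_peak <- glance(run_trial(cfg, seed = 8))$peak_pA[1]
  near_peak <- glance(run_trial(near_cfg, seed = 8))$peak_pA[1]
  expect_lt(far_peak, 0.01 * near_peak)
})

test_that("ensembles: single-trial degenerate case and low hybrid variability", {
  cfg <- quick_config(duration = 1500)
  one <- run_ensemble(cfg, n_trials = 1, base_seed = 9)
  g1 <- glance(one)
  expect_equal(g1$sd_peak_pA, rep(0, nrow(g1)))
  expect_equal(g1$mean_peak_pA[g1$kind == "AMPAR"],
               tidy(one)$peak_pA[tidy(one)$kind == "AMPAR"])

  ens <- run_ensemble(cfg, n_trials = 10, base_seed = 9)
  g <- glance(ens)
  cv <- g$sd_peak_pA[g$kind == "AMPAR"] / g$mean_peak_pA[g$kind == "AMPAR"]
  expect_lt(cv, 0.05)  # centre-fixed hybrid mode: only diffusion noise
})

test_that("random release sites lower the mean peak and raise its spread", {
  centre <- quick_config(duration = 2000, seed = 10)
  random <- quick_config(duration = 2000, seed = 10,
                         release_mode = "random_active_zone")
  ec <- glance(run_ensemble(centre, n_trials = 20, base_seed = 11))
  er <- glance(run_ensemble(random, n_trials = 20, base_seed = 11))
  mc <- ec$mean_peak_pA[ec$kind == "AMPAR"]
  mr <- er$mean_peak_pA[er$kind == "AMPAR"]
  expect_lt(mr, mc)
  expect_gt(er$sd_peak_pA[er$kind == "AMPAR"],
            ec$sd_peak_pA[ec$kind == "AMPAR"])
})

test_that("stochastic per-receptor gating reproduces the hybrid mean", {
  cfg <- quick_config(duration = 1500, seed = 12)
  nh <- 8
  hyb <- Reduce(`+`, lapply(seq_len(nh), function(i)
    tidy(run_trial(cfg, seed = 13, stream = i))$open_count)) / nh
  peak_idx <- which.max(hyb)
  n_sto <- 40
  sto <- vapply(seq_len(n_sto), function(i)
    tidy(run_trial(cfg, seed = 13, stream = 100 + i,
                   engine = "stochastic"))$open_count[peak_idx],
    numeric(1))
  sem <- stats::sd(sto) / sqrt(n_sto)
  expect_lt(abs(mean(sto) - hyb[peak_idx]), 2 * sem)
})

test_that("molecule bookkeeping is conserved throughout a trial", {
  cfg <- quick_config(duration = 2000)
  tr <- run_trial(cfg, seed = 14, diagnostics = TRUE)
  mc <- attr(tr, "molecule_counts")
  expect_true(all(mc$n_cleft + mc$n_extracellular + mc$n_absorbed == cfg$q))
  expect_true(all(diff(mc$n_absorbed) >= 0))
  expect_gt(tail(mc$n_absorbed, 1), 0)
})

test_that("recorded state occupancies stay normalised", {
  cfg <- quick_config(n = 25, duration = 800)
  tr <- run_trial(cfg, seed = 15, record_states = TRUE)
  occ <- attr(tr, "occupancy")[[1]]
  expect_equal(ncol(occ), 7)
  expect_true(all(abs(rowSums(occ) - 1) < 1e-8))
})
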