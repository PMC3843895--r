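#' Run the model's internal property suite
#'
#' Executes the self-checks that establish the numerical validity of the
#' simulator without reference to any external data:
#'
#' * molecule conservation across regions at every recorded time point;
#' * free-diffusion law: planar mean squared displacement = 4 D t;
#' * two-state channel relaxation against the closed-form CTMC solution;
#' * mean nearest-neighbour distance of uniform layouts against the planar
#'   Poisson value \eqn{0.5/\sqrt\lambda};
#' * hybrid versus stochastic receptor activation: the ensemble-mean
#'   stochastic open count must agree with the hybrid trace at the peak;
#' * time-step robustness of the ensemble-mean peak current;
#' * sensitivity of the peak to the concentration-estimator resolution
#'   (ring width and sampling-cylinder radius), reported for information.
#'
#' @param seed Seed for all randomised checks.
#' @param n_stochastic Stochastic runs in the hybrid-vs-stochastic check.
#' @param n_trials Trials per ensemble in engine-level checks.
#' @param quick Use reduced problem sizes (smaller ensembles, shorter
#'   traces); the full sizes are used by the command-line `validate`.
#' @return A tibble with columns `check`, `pass`, `value`, `detail`.
#' @export
validate_model <- function(seed = 1, n_stochastic = 40, n_trials = 20,
                           quick = FALSE) {
  if (quick) { n_stochastic <- 12; n_trials <- 6 }
  rows <- list()
  add <- function(check, pass, value, detail)
    rows[[length(rows) + 1]] <<- tibble(check = check, pass = pass,
                                        value = value, detail = detail)

  geom <- synapse_geometry()
  lay <- place_receptors(geom, 50, "AMPAR", seed = seed)
  cfg <- trial_config(geom, lay, duration = if (quick) 1000 else 3000)

  # --- molecule conservation --------------------------------------------
  tr <- run_trial(cfg, seed = seed, diagnostics = TRUE)
  mc <- attr(tr, "molecule_counts")
  tot <- mc$n_cleft + mc$n_extracellular + mc$n_absorbed
  ok <- all(tot == cfg$q) && all(diff(mc$n_absorbed) >= 0)
  add("molecule conservation", ok, max(abs(tot - cfg$q)),
      "all region counts sum to q; absorbed count monotone")

  # --- free diffusion MSD -----------------------------------------------
  big <- synapse_geometry(cleft_radius = 1e6, psd_radius = 1e5,
                          cleft_height = 1e5, outer_radius = 1e7)
  mols <- release_molecules(big, q = 40000)
  mols$z <- rep(5e4, nrow(mols))  # far from both membranes
  nsteps <- 20
  msd <- withr::with_seed(seed, {
    m <- mols
    for (i in seq_len(nsteps)) m <- step_brownian(m, big, dt = 0.1)
    mean(m$x^2 + m$y^2)
  })
  expected <- 4 * 330 * nsteps * 0.1
  rel <- abs(msd / expected - 1)
  add("free-diffusion MSD = 4Dt", rel < 0.02, rel,
      sprintf("relative error %.4f over %d molecules", rel, nrow(mols)))

  # --- two-state channel vs closed form ---------------------------------
  two <- kinetic_scheme(
    states = c("C", "O"),
    transitions = tibble(from = c("C", "O"), to = c("O", "C"),
                         rate = c(1e7, 5e3), ligand = c(TRUE, FALSE)),
    open_states = "O", conductance_pS = 10
  )
  conc <- 1  # mM
  kon <- 1e7 * 1e-9 * conc; koff <- 5e3 * 1e-6  # per us
  p <- c(1, 0)
  worst <- 0
  for (i in 1:3000) {
    p <- propagate_hybrid(p, two, conc, 0.1)
    if (i %% 300 == 0) {
      t <- i * 0.1
      exact <- kon / (kon + koff) * (1 - exp(-(kon + koff) * t))
      worst <- max(worst, abs(p[["O"]] - exact) / exact)
    }
  }
  add("two-state channel vs closed form", worst < 1e-3, worst,
      sprintf("max relative error %.2e at 10 checkpoints", worst))

  # --- Poisson nearest-neighbour law ------------------------------------
  # border-corrected: averaging interior receptors only removes the upward
  # edge bias that a bounded disc adds to the unbounded Poisson expectation
  nlay <- if (quick) 100 else 500
  lambda <- 50 / (pi * geom$psd_radius^2)
  margin <- 1.5 * 0.5 / sqrt(lambda)
  nn <- withr::with_seed(seed, {
    mean(vapply(seq_len(nlay), function(i)
      mean_nn_distance(place_receptors(geom, 50, "AMPAR"),
                       interior_margin = margin), numeric(1)), na.rm = TRUE)
  })
  rel <- abs(nn / (0.5 / sqrt(lambda)) - 1)
  add("Poisson nearest-neighbour law", rel < 0.05, rel,
      sprintf("border-corrected ensemble mean %.2f nm vs 0.5/sqrt(lambda) = %.2f nm",
              nn, 0.5 / sqrt(lambda)))

  # --- hybrid vs stochastic ---------------------------------------------
  nh <- max(4, n_trials %/% 2)
  hyb_open <- Reduce(`+`, lapply(seq_len(nh), function(i)
    as_tibble(run_trial(cfg, seed = seed, stream = i))$open_count)) / nh
  peak_idx <- which.max(hyb_open)
  sto <- vapply(seq_len(n_stochastic), function(i) {
    t <- run_trial(cfg, seed = seed, stream = 1000 + i, engine = "stochastic")
    as_tibble(t)$open_count[peak_idx]
  }, numeric(1))
  sem <- stats::sd(sto) / sqrt(n_stochastic)
  dev <- abs(mean(sto) - hyb_open[peak_idx])
  add("hybrid vs stochastic ensemble mean", dev <= 2 * sem + 1e-9, dev,
      sprintf("deviation %.3f open channels vs 2 s.e.m. = %.3f over %d runs",
              dev, 2 * sem, n_stochastic))

  # --- time-step robustness ---------------------------------------------
  m1 <- mean(vapply(seq_len(n_trials), function(i)
    glance(run_trial(cfg, seed = seed, stream = i))$peak_pA[1], numeric(1)))
  cfg2 <- rebuild_config(cfg); cfg2$dt <- cfg$dt / 2
  m2 <- mean(vapply(seq_len(n_trials), function(i)
    glance(run_trial(cfg2, seed = seed, stream = i))$peak_pA[1], numeric(1)))
  rel <- abs(m2 - m1) / m1
  add("time-step robustness of mean peak", rel < 0.02, rel,
      sprintf("halving dt changed the mean peak by %.2f%% (n = %d)",
              100 * rel, n_trials))

  # --- estimator-resolution sensitivity (report only) -------------------
  p0 <- glance(run_trial(cfg, seed = seed))$peak_pA[1]
  cfg_dr <- rebuild_config(cfg); cfg_dr$dr <- cfg$dr / 2
  p_dr <- glance(run_trial(cfg_dr, seed = seed))$peak_pA[1]
  cfg_loc <- rebuild_config(cfg); cfg_loc$conc_estimator <- "local"
  p_loc <- glance(run_trial(cfg_loc, seed = seed))$peak_pA[1]
  add("estimator sensitivity (informational)", TRUE,
      max(abs(c(p_dr, p_loc) / p0 - 1)),
      sprintf("peak %.3g pA; dr/2 -> %.3g pA; local(rho=%g nm) -> %.3g pA",
              p0, p_dr, cfg$rho_local, p_loc))

  dplyr::bind_rows(rows)
}
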