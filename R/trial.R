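#' Assemble a simulation trial configuration
#'
#' Bundles geometry, receptor layout(s), kinetic schemes, release settings
#' and engine parameters for [run_trial()] / [run_ensemble()].
#'
#' Defaults follow the typical small excitatory synapse: quantal release of
#' 2700 glutamate molecules, a 0.1 us time step, and a postsynaptic membrane
#' potential of -80 mV (applied to both receptor kinds; the NMDAR scheme
#' carries no Mg2+ block, and potentiation percentages, being current ratios,
#' are insensitive to the driving force). Trace duration defaults to 3 ms for
#' AMPAR-only configurations and to a 50 ms cap with early stopping (current
#' decayed below 1% of its running peak) when an NMDAR pool is present,
#' enough to capture peak statistics.
#'
#' @param geometry A [synapse_geometry()].
#' @param layouts A `receptor_layout` or list of layouts (one per receptor
#'   pool; kinds may repeat).
#' @param schemes Optional named list mapping layout kinds to
#'   [kinetic_scheme()] objects; kinds `"AMPAR"`/`"NMDAR"` default to the
#'   shipped presets.
#' @param release_mode `"centre"` (release on the cleft axis) or
#'   `"random_active_zone"` (release point redrawn uniformly over the active
#'   zone each trial).
#' @param q Molecules per released vesicle.
#' @param dt Integration time step in us.
#' @param duration Trace duration in us (default as described above).
#' @param v_m Membrane potential in mV.
#' @param d_in,d_out Glutamate diffusion coefficients in um^2/ms.
#' @param dr Ring width of the radial concentration field, nm.
#' @param rho_local Radius of the per-receptor sampling cylinder, nm.
#' @param conc_estimator `"ring"` (radial field; valid under rotational
#'   symmetry) or `"local"` (per-receptor cylinder); defaults to `"ring"` for
#'   centre release and `"local"` for random release sites.
#' @param record_dt Trace recording interval in us.
#' @param early_stop Stop once the total current decays below 1% of its
#'   running peak; `NULL` = only for NMDAR-containing configurations.
#' @return A `trial_config` object.
#' @examples
#' geom <- synapse_geometry()
#' cfg <- trial_config(geom, place_receptors(geom, 50, "AMPAR", seed = 1))
#' @export
trial_config <- function(geometry, layouts, schemes = NULL,
                         release_mode = c("centre", "random_active_zone"),
                         q = 2700, dt = 0.1, duration = NULL, v_m = -80,
                         d_in = 0.33, d_out = 0.4,
                         dr = 10, rho_local = 20, conc_estimator = NULL,
                         record_dt = 1, early_stop = NULL) {
  stopifnot(is_synapse_geometry(geometry))
  release_mode <- match.arg(release_mode)
  if (inherits(layouts, "receptor_layout")) layouts <- list(layouts)
  if (!is.list(layouts) || length(layouts) == 0)
    abort("`layouts` must be one receptor_layout or a non-empty list of them")
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be positive (us)")
  if (!is.numeric(q) || q < 0 || q != round(q))
    abort("`q` must be a non-negative integer")
  kinds <- vapply(layouts, function(l) {
    if (nrow(l) > 0) as.character(l$kind[[1]]) else "AMPAR"
  }, character(1))
  schemes <- schemes %||% list()
  resolved <- lapply(kinds, function(k) {
    if (!is.null(schemes[[k]])) load_scheme(schemes[[k]])
    else if (k %in% c("AMPAR", "NMDAR")) load_scheme(k)
    else abort(sprintf("no kinetic scheme supplied for receptor kind '%s'", k))
  })
  for (l in layouts) {
    r <- sqrt(l$x^2 + l$y^2)
    if (any(r > geometry$cleft_radius + 1e-9))
      abort("receptor positions fall outside the cleft")
  }
  has_nmdar <- any(kinds == "NMDAR")
  duration <- duration %||% if (has_nmdar) 50000 else 3000
  if (duration <= 0) abort("`duration` must be positive (us)")
  early_stop <- early_stop %||% has_nmdar
  conc_estimator <- conc_estimator %||%
    if (release_mode == "centre") "ring" else "local"
  if (!conc_estimator %in% c("ring", "local"))
    abort("`conc_estimator` must be 'ring' or 'local'")
  structure(
    list(geometry = geometry, layouts = layouts, kinds = kinds,
         schemes = resolved, release_mode = release_mode, q = as.integer(q),
         dt = dt, duration = duration, v_m = v_m, d_in = d_in, d_out = d_out,
         dr = dr, rho_local = rho_local, conc_estimator = conc_estimator,
         record_dt = record_dt, early_stop = isTRUE(early_stop)),
    class = "trial_config"
  )
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>\n")
  cat(sprintf("  geometry: R=%g nm, r_a=%g nm, delta=%g nm\n",
              x$geometry$cleft_radius, x$geometry$psd_radius,
              x$geometry$cleft_height))
  for (i in seq_along(x$layouts))
    cat(sprintf("  pool %d: %d %s\n", i, nrow(x$layouts[[i]]), x$kinds[[i]]))
  cat(sprintf("  release: %d molecules, %s; dt=%g us; duration=%g us; Vm=%g mV\n",
              x$q, x$release_mode, x$dt, x$duration, x$v_m))
  invisible(x)
}

# Replace geometry/layouts of a config, keeping all engine settings.
rebuild_config <- function(config, geometry = NULL, layouts = NULL) {
  trial_config(
    geometry = geometry %||% config$geometry,
    layouts = layouts %||% config$layouts,
    schemes = setNames(config$schemes, config$kinds),
    release_mode = config$release_mode, q = config$q, dt = config$dt,
    duration = config$duration, v_m = config$v_m,
    d_in = config$d_in, d_out = config$d_out, dr = config$dr,
    rho_local = config$rho_local, conc_estimator = config$conc_estimator,
    record_dt = config$record_dt, early_stop = config$early_stop
  )
}

#' Run one simulated release trial
#'
#' Executes the full duty cycle at each time step: Brownian update of every
#' tracked molecule, estimation of the glutamate concentration at the
#' receptors (radial rings under rotational symmetry, per-receptor sampling
#' cylinders otherwise), propagation of all receptor pools, and accumulation
#' of the total synaptic current
#' \eqn{I(t) = \sum_{pools} N_{open} \gamma (V_m - E_{rev})}.
#'
#' In `"hybrid"` mode receptor occupancies are propagated deterministically
#' from the local concentration (fast; the default). In `"stochastic"` mode
#' each receptor walks its kinetic scheme as an individual continuous-time
#' Markov chain; ensemble averages of the two agree, which is the model's
#' internal validation.
#'
#' Trajectories are bit-reproducible for a fixed `(seed, stream)` pair.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed for the engine RNG.
#' @param stream Secondary seed component; [run_ensemble()] gives each trial
#'   its own stream.
#' @param engine `"hybrid"` or `"stochastic"`.
#' @param record_states Also record the mean occupancy of every kinetic state
#'   over time (one matrix per pool).
#' @param diagnostics Also record molecule counts per region over time.
#' @param coarse_far_field Let molecules far outside the cleft opening take
#'   coarser time steps (1.6 us) until they approach it again; exact per-axis
#'   Gaussian increments make this statistically equivalent away from
#'   boundaries and it does not affect in-cleft dynamics.
#' @return A `current_trace`: tibble with columns `time_us`, `kind`,
#'   `current_pA`, `open_count`, with peak statistics available via
#'   [glance()].
#' @examples
#' geom <- synapse_geometry()
#' cfg <- trial_config(geom, place_receptors(geom, 50, "AMPAR", seed = 1),
#'                     duration = 500)
#' tr <- run_trial(cfg, seed = 1)
#' glance(tr)
#' @export
run_trial <- function(config, seed = 1, stream = 0,
                      engine = c("hybrid", "stochastic"),
                      record_states = FALSE, diagnostics = FALSE,
                      coarse_far_field = TRUE) {
  stopifnot(inherits(config, "trial_config"))
  engine <- match.arg(engine)
  pools <- lapply(seq_along(config$layouts), function(i) {
    sc <- config$schemes[[i]]
    lay <- config$layouts[[i]]
    list(q0 = unname(sc$q0), q1 = unname(sc$q1),
         open = match(sc$open_states, sc$states),
         gamma = sc$conductance_pS, erev = sc$reversal_mV,
         init = match(sc$initial_state, sc$states),
         x = as.numeric(lay$x), y = as.numeric(lay$y),
         stochastic = identical(engine, "stochastic"))
  })
  res <- cpp_run_trial(
    R = config$geometry$cleft_radius, ra = config$geometry$psd_radius,
    delta = config$geometry$cleft_height, Rout = config$geometry$outer_radius,
    pools = pools, q = config$q,
    release_mode = if (config$release_mode == "centre") 0L else 1L,
    dt = config$dt, duration = config$duration, vm = config$v_m,
    conc_mode = if (config$conc_estimator == "ring") 0L else 1L,
    dr = config$dr, rho_local = config$rho_local,
    d_in = config$d_in * 1000, d_out = config$d_out * 1000,
    seed = as.integer(seed), stream = as.integer(stream),
    record_every = max(1L, as.integer(round(config$record_dt / config$dt))),
    early_stop = config$early_stop,
    coarse_far = coarse_far_field, far_buffer = 200, coarse_dt = 1.6,
    record_states = record_states, diagnostics = diagnostics
  )
  npool <- length(pools)
  trace <- purrr::map_dfr(seq_len(npool), function(i) {
    tibble(time_us = res$time, pool = i, kind = config$kinds[[i]],
           current_pA = res$current[, i], open_count = res$open[, i])
  })
  peaks <- tibble(
    pool = c(seq_len(npool), NA_integer_),
    kind = c(config$kinds, "total"),
    peak_pA = c(res$peak_pool, res$peak_total),
    peak_time_us = c(res$peak_pool_time, res$peak_total_time)
  )
  structure(trace,
            class = c("current_trace", class(trace)),
            peaks = peaks, seed = seed, stream = stream, engine = engine,
            config = config, stopped_early = res$stopped_early,
            molecule_counts = if (diagnostics)
              tibble(time_us = res$time, n_cleft = res$n_cleft,
                     n_extracellular = res$n_out, n_absorbed = res$n_absorbed)
            else NULL,
            occupancy = if (record_states) res$occupancy else NULL)
}

#' @export
print.current_trace <- function(x, ...) {
  p <- attr(x, "peaks")
  tot <- p[p$kind == "total", ]
  cat(sprintf("<current_trace> %s engine; peak |I| = %.3g pA at %.3g us\n",
              attr(x, "engine"), tot$peak_pA, tot$peak_time_us))
  NextMethod()
}

#' @rdname run_trial
#' @param x A `current_trace`.
#' @param ... Unused.
#' @export
tidy.current_trace <- function(x, ...) {
  as_tibble(x)[, c("time_us", "kind", "current_pA", "open_count")]
}

#' @rdname run_trial
#' @export
glance.current_trace <- function(x, ...) {
  p <- attr(x, "peaks")
  tibble(kind = p$kind, peak_pA = p$peak_pA, peak_time_us = p$peak_time_us,
         seed = attr(x, "seed"), stream = attr(x, "stream"),
         engine = attr(x, "engine"))
}
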