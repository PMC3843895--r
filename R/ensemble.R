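#' Run a seeded ensemble of release trials
#'
#' Repeats [run_trial()] `n_trials` times with per-trial RNG streams derived
#' deterministically from `base_seed`, collects per-trial peak currents, and
#' averages the traces pointwise. Peak statistics are the mean and standard
#' deviation of the per-trial peaks (matching how trial-to-trial variability
#' is usually summarised); the peak of the mean trace is also reported.
#'
#' @param config A [trial_config()].
#' @param n_trials Number of consecutive simulated release events
#'   (default 20).
#' @param base_seed Integer seed; trial `i` uses stream `stream_base + i - 1`.
#' @param stream_base Offset of the stream index, used by the sweep engine to
#'   give every configuration cell its own reproducible stream family.
#' @param engine `"hybrid"` or `"stochastic"`.
#' @param trace Keep the pointwise mean trace (set `FALSE` to save memory in
#'   large sweeps).
#' @param layout_fn Optional function `trial index -> list of receptor
#'   layouts` used to redraw the (random) receptor arrangement for every
#'   simulated release event, so that ensemble statistics describe the
#'   configuration class (given N, r_a, density) rather than one particular
#'   scatter; `NULL` keeps the config's fixed layouts for all trials.
#' @return A `synapse_ensemble` with per-trial peaks ([tidy()]), summary
#'   statistics ([glance()]) and the mean trace (`attr(, "mean_trace")`).
#' @examples
#' geom <- synapse_geometry()
#' cfg <- trial_config(geom, place_receptors(geom, 50, "AMPAR", seed = 1),
#'                     duration = 500)
#' ens <- run_ensemble(cfg, n_trials = 3, base_seed = 1)
#' glance(ens)
#' @export
run_ensemble <- function(config, n_trials = 20, base_seed = 1, stream_base = 0,
                         engine = c("hybrid", "stochastic"), trace = TRUE,
                         layout_fn = NULL) {
  stopifnot(inherits(config, "trial_config"))
  engine <- match.arg(engine)
  if (n_trials < 1) abort("`n_trials` must be >= 1")
  trials <- lapply(seq_len(n_trials), function(i) {
    cfg_i <- if (is.null(layout_fn)) config
             else rebuild_config(config, layouts = layout_fn(i))
    run_trial(cfg_i, seed = base_seed, stream = stream_base + i - 1,
              engine = engine)
  })
  peaks <- purrr::map_dfr(seq_len(n_trials), function(i) {
    g <- glance(trials[[i]])
    g$trial <- i
    g
  })
  mean_trace <- NULL
  if (trace) {
    # trials may stop early; average over the common part of the grid
    nmin <- min(vapply(trials, function(t) length(unique(t$time_us)),
                       integer(1)))
    mean_trace <- purrr::map_dfr(trials, function(t) {
      tt <- as_tibble(t)
      keep <- tt$time_us %in% sort(unique(tt$time_us))[seq_len(nmin)]
      tt[keep, c("time_us", "kind", "current_pA", "open_count")]
    }) |>
      dplyr::group_by(.data$time_us, .data$kind) |>
      dplyr::summarise(current_pA = mean(.data$current_pA),
                       open_count = mean(.data$open_count), .groups = "drop")
  }
  structure(
    list(peaks = peaks, mean_trace = mean_trace, config = config,
         n_trials = n_trials, base_seed = base_seed,
         stream_base = stream_base, engine = engine),
    class = "synapse_ensemble"
  )
}

#' @export
print.synapse_ensemble <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<synapse_ensemble> %d trials (%s engine)\n", x$n_trials,
              x$engine))
  print(g)
  invisible(x)
}

#' @rdname run_ensemble
#' @param x A `synapse_ensemble`.
#' @param ... Unused.
#' @export
tidy.synapse_ensemble <- function(x, ...) {
  x$peaks[, c("trial", "kind", "peak_pA", "peak_time_us", "seed", "stream")]
}

#' @rdname run_ensemble
#' @export
glance.synapse_ensemble <- function(x, ...) {
  out <- x$peaks |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(mean_peak_pA = mean(.data$peak_pA),
                     sd_peak_pA = stats::sd(.data$peak_pA),
                     mean_peak_time_us = mean(.data$peak_time_us),
                     n_trials = dplyr::n(), .groups = "drop")
  if (x$n_trials == 1) out$sd_peak_pA <- 0
  if (!is.null(x$mean_trace)) {
    pk <- x$mean_trace |>
      dplyr::group_by(.data$kind) |>
      dplyr::summarise(peak_of_mean_trace_pA = max(abs(.data$current_pA)),
                       .groups = "drop")
    out <- dplyr::left_join(out, pk, by = "kind")
  }
  out
}

# Convenience: ensemble-mean peak of one receptor kind (or "total").
ensemble_peak <- function(ensemble, kind = NULL) {
  g <- glance(ensemble)
  kind <- kind %||% setdiff(unique(g$kind), "total")[[1]]
  g$mean_peak_pA[g$kind == kind]
}
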