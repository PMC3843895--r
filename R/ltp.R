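# Long-term potentiation scenarios: receptor insertion at constant density
# versus receptor crowding at constant number, for AMPAR and NMDAR pools.

ltp_presets <- list(
  AMPAR = list(base = list(ra = 110, n = 50, R = 200),
               insert = list(ra = 180, n = 134, R = 200),
               clust = list(ra = 75, n = 50, R = 200)),
  NMDAR = list(base = list(ra = 110, n = 10, R = 200),
               insert = list(ra = 190, n = 30, R = 200),
               clust = list(ra = 80, n = 10, R = 200))
)

pct <- function(test, base) 100 * (test - base) / base

#' Compare potentiation scenarios: receptor insertion versus clustering
#'
#' Runs the reference synapse (`r_a` = 110 nm, `R` = 200 nm, 50 AMPARs or 10
#' NMDARs) against two potentiated configurations: `"insert"` adds receptors
#' to the periphery by expanding the PSD at unchanged surface density (AMPAR:
#' `r_a` = 180 nm, N = 134; NMDAR: `r_a` = 190 nm, N = 30), and `"clust"`
#' shrinks the PSD with no change in receptor number (AMPAR: `r_a` = 75 nm;
#' NMDAR: `r_a` = 80 nm). Both correspond to roughly half-again current
#' potentiation in this model. Scenarios run with the centre-fixed release
#' site, the trial-to-trial random release site, or both.
#'
#' @param kind `"AMPAR"` or `"NMDAR"`.
#' @param release_mode `"centre"`, `"random_active_zone"`, or `"both"`.
#' @param n_trials Trials per configuration (default 20).
#' @param base_seed Seed from which all trial streams derive.
#' @param n_insert_override Optional receptor count for the insert scenario,
#'   replacing the preset.
#' @param scenarios Subset of `c("insert", "clust")` to run.
#' @param config_tweaks Optional function applied to each [trial_config()]
#'   before running (e.g. to shorten `duration` in quick checks).
#' @return A `potentiation_report` tibble: one row per scenario and release
#'   mode, with baseline and test peak statistics, the percent change of the
#'   mean peak current, and the percent changes of receptor number and mean
#'   nearest-neighbour distance.
#' @examples
#' \donttest{
#' ltp_scenarios("AMPAR", n_trials = 3)
#' }
#' @export
ltp_scenarios <- function(kind = c("AMPAR", "NMDAR"),
                          release_mode = c("centre", "random_active_zone",
                                           "both"),
                          n_trials = 20, base_seed = 1,
                          n_insert_override = NULL,
                          scenarios = c("insert", "clust"),
                          config_tweaks = NULL) {
  kind <- match.arg(kind)
  release_mode <- match.arg(release_mode)
  modes <- if (release_mode == "both") c("centre", "random_active_zone")
           else release_mode
  preset <- ltp_presets[[kind]]
  scenarios <- match.arg(scenarios, several.ok = TRUE)

  # Each simulated release event redraws the random receptor scatter, so the
  # ensemble mean describes the configuration class. The clustering scenario
  # rescales the baseline scatter of the same trial onto the smaller disc
  # ("the same receptors, pulled together").
  run_config <- function(par, mode, shrink_from = NULL) {
    geom <- synapse_geometry(cleft_radius = par$R, psd_radius = par$ra)
    sb <- cell_stream_base(paste0(kind, mode), par$ra, par$n, par$R)
    make_layout <- if (is.null(shrink_from)) {
      lseed <- cell_layout_seed(base_seed, sb)
      function(i) place_receptors(geom, par$n, kind = kind, seed = lseed + i)
    } else {
      base_geom <- synapse_geometry(cleft_radius = par$R,
                                    psd_radius = shrink_from$ra)
      lseed <- cell_layout_seed(
        base_seed, cell_stream_base(paste0(kind, mode), shrink_from$ra,
                                    shrink_from$n, shrink_from$R))
      function(i) scale_layout(
        place_receptors(base_geom, shrink_from$n, kind = kind, seed = lseed + i),
        par$ra, mode = "fixed_n")
    }
    cfg <- trial_config(geom, make_layout(0), release_mode = mode)
    if (!is.null(config_tweaks)) cfg <- config_tweaks(cfg)
    ens <- run_ensemble(cfg, n_trials = n_trials, base_seed = base_seed,
                        stream_base = sb, trace = FALSE,
                        layout_fn = function(i) list(make_layout(i)))
    g <- glance(ens)
    g <- g[g$kind == kind, ]
    nn <- if (par$n >= 2)
      mean(vapply(seq_len(n_trials), function(i)
        mean_nn_distance(make_layout(i)), numeric(1)))
    else NA_real_
    list(mean = g$mean_peak_pA, sd = g$sd_peak_pA, n = par$n, nn = nn)
  }

  rows <- list()
  for (mode in modes) {
    base <- run_config(preset$base, mode)
    for (sc in scenarios) {
      par <- preset[[sc]]
      if (sc == "insert" && !is.null(n_insert_override))
        par$n <- as.integer(n_insert_override)
      test <- run_config(par, mode,
                         shrink_from = if (sc == "clust") preset$base)
      rows[[length(rows) + 1]] <- tibble(
        kind = kind, release_mode = mode, scenario = sc,
        base_mean_pA = base$mean, base_sd_pA = base$sd,
        test_mean_pA = test$mean, test_sd_pA = test$sd,
        pct_change_peak = pct(test$mean, base$mean),
        pct_change_n = pct(test$n, base$n),
        pct_change_nn = pct(test$nn, base$nn),
        n_trials = n_trials
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("potentiation_report", class(out)))
}

#' @export
print.potentiation_report <- function(x, ...) {
  cat("<potentiation_report>\n")
  NextMethod()
}
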