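# Parametric sweeps over synapse architecture: receptor number at constant
# density, fixed-N crowding, and cleft-size dependence. Every grid cell gets
# a reproducible RNG stream family derived from its configuration values, so
# identical cells in different sweeps (or in the parametric map) yield
# identical results for the same base seed.

# Deterministic small-integer hash of a cell configuration. Streams are
# h * 128 + trial, so up to 128 trials per cell never collide within a cell.
cell_stream_base <- function(kind, psd_radius, n, cleft_radius) {
  h <- 17
  for (v in c(sum(utf8ToInt(as.character(kind))), round(psd_radius * 10),
              round(n), round(cleft_radius * 10))) {
    h <- (h * 131 + v) %% 1048573
  }
  as.integer(h * 128)
}

cell_layout_seed <- function(base_seed, stream_base) {
  as.integer((base_seed * 7919 + stream_base) %% .Machine$integer.max)
}

# Shared cell runner for all sweep families. The receptor scatter is redrawn
# for every simulated release event, so cell statistics describe the
# configuration class (N, r_a, R) rather than one particular layout.
run_cell <- function(config, kind, cleft_radius, psd_radius, n, n_trials,
                     base_seed, engine = "hybrid") {
  geom <- synapse_geometry(
    cleft_radius = cleft_radius, psd_radius = psd_radius,
    cleft_height = config$geometry$cleft_height,
    outer_radius = config$geometry$outer_radius
  )
  sb <- cell_stream_base(kind, psd_radius, n, cleft_radius)
  lseed <- cell_layout_seed(base_seed, sb)
  make_layout <- function(i) place_receptors(geom, n, kind = kind,
                                             seed = lseed + i)
  cfg <- rebuild_config(config, geometry = geom, layouts = list(make_layout(0)))
  ens <- run_ensemble(cfg, n_trials = n_trials, base_seed = base_seed,
                      stream_base = sb, engine = engine, trace = FALSE,
                      layout_fn = function(i) list(make_layout(i)))
  nn <- if (n >= 2)
    mean(vapply(seq_len(n_trials), function(i)
      mean_nn_distance(make_layout(i)), numeric(1)))
  else NA_real_
  list(ensemble = ens, mean_nn = nn)
}

new_sweep_result <- function(trials, cells, fits, family) {
  structure(list(trials = trials, cells = cells, fits = fits, family = family),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> family '%s', %d cells\n", x$family,
              nrow(x$cells)))
  print(x$cells)
  invisible(x)
}

#' @export
tidy.sweep_result <- function(x, ...) x$cells

empty_trials_tbl <- function() {
  tibble(cleft_radius = numeric(), psd_radius = numeric(),
         n_receptors = integer(), density = numeric(), mean_nn = numeric(),
         trial = integer(), peak_pA = numeric(), peak_time_us = numeric(),
         stream = numeric())
}

summarise_cells <- function(trials) {
  if (nrow(trials) == 0) trials <- empty_trials_tbl()
  trials |>
    dplyr::group_by(.data$cleft_radius, .data$psd_radius, .data$n_receptors,
                    .data$density, .data$mean_nn) |>
    dplyr::summarise(mean_peak_pA = mean(.data$peak_pA),
                     sd_peak_pA = stats::sd(.data$peak_pA),
                     n_trials = dplyr::n(), .groups = "drop")
}

sweep_kind <- function(config) {
  if (length(config$kinds) != 1)
    abort("sweeps operate on single-pool configurations")
  config$kinds[[1]]
}

collect_cell_trials <- function(cell, cleft_radius, psd_radius, n) {
  td <- tidy(cell$ensemble)
  td <- td[td$kind != "total", ]
  tibble(cleft_radius = cleft_radius, psd_radius = psd_radius,
         n_receptors = n, density = n / (pi * psd_radius^2),
         mean_nn = cell$mean_nn, trial = td$trial, peak_pA = td$peak_pA,
         peak_time_us = td$peak_time_us, stream = td$stream)
}

#' Sweep receptor number at constant surface density
#'
#' Expands (or shrinks) the PSD over `psd_radii`, rescaling the receptor
#' count by the area ratio from the base configuration so that the surface
#' density stays constant, and tabulates ensemble peak currents; a straight
#' line is fitted to peak versus receptor number for each cleft radius.
#'
#' @param config Base [trial_config()] (single receptor pool); its layout
#'   defines the reference `(r_a, N)`.
#' @param psd_radii PSD radii (nm) to visit.
#' @param cleft_radii Cleft radii (nm); defaults to the base cleft radius.
#'   Cells with `r_a > R` are skipped with a warning.
#' @param n_trials Trials per cell.
#' @param base_seed Seed from which all cell streams derive.
#' @param n_override Optional integer vector (same length as `psd_radii`)
#'   overriding the area-ratio receptor counts, e.g. to run an alternative
#'   published count for a scenario; `NA` entries keep the rule.
#' @return A `sweep_result` with `$trials` (one row per cell and trial),
#'   `$cells` (per-cell mean +/- s.d. peak, density, mean nearest-neighbour
#'   distance) and `$fits` (per-R linear regression of mean peak on N).
#' @export
sweep_density_constant <- function(config, psd_radii, cleft_radii = NULL,
                                   n_trials = 20, base_seed = 1,
                                   n_override = NULL) {
  kind <- sweep_kind(config)
  ra0 <- config$geometry$psd_radius
  n0 <- nrow(config$layouts[[1]])
  cleft_radii <- cleft_radii %||% config$geometry$cleft_radius
  if (!is.null(n_override) && length(n_override) != length(psd_radii))
    abort("`n_override` must match `psd_radii` in length")
  trials <- list()
  for (R in cleft_radii) {
    for (j in seq_along(psd_radii)) {
      ra <- psd_radii[j]
      if (ra > R) {
        warn(sprintf("skipping cell r_a=%g > R=%g", ra, R))
        next
      }
      n <- as.integer(round(n0 * (ra / ra0)^2))
      if (!is.null(n_override) && !is.na(n_override[j]))
        n <- as.integer(n_override[j])
      cell <- run_cell(config, kind, R, ra, n, n_trials, base_seed)
      trials[[length(trials) + 1]] <- collect_cell_trials(cell, R, ra, n)
    }
  }
  trials <- dplyr::bind_rows(trials)
  if (nrow(trials) == 0) trials <- empty_trials_tbl()
  cells <- summarise_cells(trials)
  fits <- cells |>
    dplyr::group_by(.data$cleft_radius) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) return(tibble(term = character(), estimate = numeric()))
      f <- fit_linear(d$n_receptors, d$mean_peak_pA)
      out <- f$coefficients
      out$r_squared <- f$r_squared
      out
    }) |>
    dplyr::ungroup()
  new_sweep_result(trials, cells, fits, "density_constant")
}

#' Sweep PSD size at fixed receptor number (crowding / dispersal)
#'
#' Keeps the receptor count of the base configuration and redraws the pool on
#' discs of the given radii, tabulating peak current against the mean
#' inter-receptor nearest-neighbour distance; a quadratic is fitted per cleft
#' radius.
#'
#' @inheritParams sweep_density_constant
#' @return A `sweep_result`; `$fits` holds the per-R quadratic regression of
#'   mean peak on mean nearest-neighbour distance.
#' @export
sweep_fixed_n <- function(config, psd_radii, cleft_radii = NULL,
                          n_trials = 20, base_seed = 1) {
  kind <- sweep_kind(config)
  n0 <- nrow(config$layouts[[1]])
  cleft_radii <- cleft_radii %||% config$geometry$cleft_radius
  trials <- list()
  for (R in cleft_radii) {
    for (ra in psd_radii) {
      if (ra > R) {
        warn(sprintf("skipping cell r_a=%g > R=%g", ra, R))
        next
      }
      cell <- run_cell(config, kind, R, ra, n0, n_trials, base_seed)
      trials[[length(trials) + 1]] <- collect_cell_trials(cell, R, ra, n0)
    }
  }
  trials <- dplyr::bind_rows(trials)
  if (nrow(trials) == 0) trials <- empty_trials_tbl()
  cells <- summarise_cells(trials)
  fits <- cells |>
    dplyr::group_by(.data$cleft_radius) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) return(tibble(term = character(), estimate = numeric()))
      f <- fit_quadratic(d$mean_nn, d$mean_peak_pA)
      out <- f$coefficients
      out$r_squared <- f$r_squared
      out
    }) |>
    dplyr::ungroup()
  new_sweep_result(trials, cells, fits, "fixed_n")
}

#' Sweep the synaptic cleft size at fixed PSD
#'
#' Varies the cleft radius `R` (and optionally the receptor count, i.e. the
#' density on the unchanged PSD) with the PSD radius held at the base value.
#' A wider cleft retains glutamate in two dimensions for longer, boosting
#' receptor activation.
#'
#' @inheritParams sweep_density_constant
#' @param cleft_radii Cleft radii (nm) to visit; must all be `>= r_a`.
#' @param n_receptors Receptor counts to cross with `cleft_radii`; defaults
#'   to the base count.
#' @return A `sweep_result` over the `(R, N)` grid.
#' @export
sweep_cleft_size <- function(config, cleft_radii, n_receptors = NULL,
                             n_trials = 20, base_seed = 1) {
  kind <- sweep_kind(config)
  ra <- config$geometry$psd_radius
  n_receptors <- n_receptors %||% nrow(config$layouts[[1]])
  trials <- list()
  for (R in cleft_radii) {
    if (ra > R) {
      warn(sprintf("skipping cell r_a=%g > R=%g", ra, R))
      next
    }
    for (n in n_receptors) {
      cell <- run_cell(config, kind, R, ra, as.integer(n), n_trials, base_seed)
      trials[[length(trials) + 1]] <- collect_cell_trials(cell, R, ra,
                                                          as.integer(n))
    }
  }
  trials <- dplyr::bind_rows(trials)
  if (nrow(trials) == 0) trials <- empty_trials_tbl()
  new_sweep_result(trials, summarise_cells(trials), NULL, "cleft_size")
}
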