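# Run configuration files: YAML documents in which every physical quantity
# carries an explicit unit string. One conversion layer owns all unit
# arithmetic (internal units: nm, us, mV, um^2/ms for diffusion).

.unit_table <- list(
  length = c(nm = 1, um = 1e3, "µm" = 1e3),
  time = c(us = 1, "µs" = 1, ms = 1e3, s = 1e6),
  potential = c(mV = 1),
  diffusion = c(um2_per_ms = 1, nm2_per_us = 1e-3)
)

convert_quantity <- function(x, dimension, what) {
  if (!is.list(x) || is.null(x$value) || is.null(x$unit))
    abort(sprintf("`%s` must be written as {value: ..., unit: ...}", what))
  tab <- .unit_table[[dimension]]
  if (!x$unit %in% names(tab))
    abort(sprintf("`%s`: unknown %s unit '%s' (expected one of %s)",
                  what, dimension, x$unit, paste(names(tab), collapse = ", ")))
  as.numeric(x$value) * tab[[x$unit]]
}

quantity <- function(value, unit) list(value = value, unit = unit)

check_known_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0)
    abort(sprintf("unknown key(s) in %s: %s", where,
                  paste(extra, collapse = ", ")))
}

#' Read or write a simulation run configuration
#'
#' A run configuration is a YAML document with sections `geometry`,
#' `receptors`, `release`, `engine` and `seeds`; every physical quantity is a
#' `{value, unit}` pair and unknown keys are rejected. `read_run_config()`
#' validates and normalises to internal units (nm, us, mV); the parse /
#' serialise round trip is idempotent.
#'
#' @param path File path.
#' @return `read_run_config()`: a `run_config` list; `write_run_config()`:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  check_known_keys(y, c("geometry", "receptors", "release", "engine", "seeds"),
                   path)
  g <- y$geometry %||% list()
  check_known_keys(g, c("cleft_radius", "psd_radius", "cleft_height",
                        "outer_radius"), "geometry")
  geom <- synapse_geometry(
    cleft_radius = if (is.null(g$cleft_radius)) 200
                   else convert_quantity(g$cleft_radius, "length", "cleft_radius"),
    psd_radius = if (is.null(g$psd_radius)) 110
                 else convert_quantity(g$psd_radius, "length", "psd_radius"),
    cleft_height = if (is.null(g$cleft_height)) 19
                   else convert_quantity(g$cleft_height, "length", "cleft_height"),
    outer_radius = if (is.null(g$outer_radius)) 2000
                   else convert_quantity(g$outer_radius, "length", "outer_radius")
  )
  # receptor counts use the key `count` (a bare `n:` is a YAML 1.1 boolean)
  receptors <- lapply(y$receptors %||% list(list(kind = "AMPAR", count = 50)),
                      function(r) {
    check_known_keys(r, c("kind", "count", "scheme"), "receptors")
    if (is.null(r$kind) || is.null(r$count))
      abort("each receptors entry needs `kind` and `count`")
    list(kind = as.character(r$kind), n = as.integer(r$count),
         scheme = r$scheme)
  })
  rel <- y$release %||% list()
  check_known_keys(rel, c("q", "mode"), "release")
  eng <- y$engine %||% list()
  check_known_keys(eng, c("dt", "duration", "v_m", "d_in", "d_out", "dr",
                          "rho_local", "record_dt"), "engine")
  seeds <- y$seeds %||% list()
  check_known_keys(seeds, c("base_seed", "n_trials"), "seeds")
  structure(
    list(
      geometry = geom,
      receptors = receptors,
      q = as.integer(rel$q %||% 2700),
      release_mode = match.arg(rel$mode %||% "centre",
                               c("centre", "random_active_zone")),
      dt = if (is.null(eng$dt)) 0.1 else convert_quantity(eng$dt, "time", "dt"),
      duration = if (is.null(eng$duration)) NULL
                 else convert_quantity(eng$duration, "time", "duration"),
      v_m = if (is.null(eng$v_m)) -80
            else convert_quantity(eng$v_m, "potential", "v_m"),
      d_in = if (is.null(eng$d_in)) 0.33
             else convert_quantity(eng$d_in, "diffusion", "d_in"),
      d_out = if (is.null(eng$d_out)) 0.4
              else convert_quantity(eng$d_out, "diffusion", "d_out"),
      dr = if (is.null(eng$dr)) 10 else convert_quantity(eng$dr, "length", "dr"),
      rho_local = if (is.null(eng$rho_local)) 20
                  else convert_quantity(eng$rho_local, "length", "rho_local"),
      record_dt = if (is.null(eng$record_dt)) 1
                  else convert_quantity(eng$record_dt, "time", "record_dt"),
      base_seed = as.integer(seeds$base_seed %||% 1),
      n_trials = as.integer(seeds$n_trials %||% 20)
    ),
    class = "run_config"
  )
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  g <- config$geometry
  y <- list(
    geometry = list(cleft_radius = quantity(g$cleft_radius, "nm"),
                    psd_radius = quantity(g$psd_radius, "nm"),
                    cleft_height = quantity(g$cleft_height, "nm"),
                    outer_radius = quantity(g$outer_radius, "nm")),
    receptors = lapply(config$receptors, function(r)
      if (is.null(r$scheme)) list(kind = r$kind, count = r$n)
      else list(kind = r$kind, count = r$n, scheme = r$scheme)),
    release = list(q = config$q, mode = config$release_mode),
    engine = list(dt = quantity(config$dt, "us"),
                  v_m = quantity(config$v_m, "mV"),
                  d_in = quantity(config$d_in, "um2_per_ms"),
                  d_out = quantity(config$d_out, "um2_per_ms"),
                  dr = quantity(config$dr, "nm"),
                  rho_local = quantity(config$rho_local, "nm"),
                  record_dt = quantity(config$record_dt, "us")),
    seeds = list(base_seed = config$base_seed, n_trials = config$n_trials)
  )
  if (!is.null(config$duration))
    y$engine$duration <- quantity(config$duration, "us")
  # keep key order stable for byte-identical round trips
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Build a [trial_config()] from a parsed run configuration
#' @param config A `run_config` from [read_run_config()].
#' @param seed Optional seed overriding the file's `base_seed` for layout
#'   generation.
#' @return A `trial_config`.
#' @export
as_trial_config <- function(config, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- seed %||% config$base_seed
  layouts <- list(); schemes <- list()
  for (i in seq_along(config$receptors)) {
    r <- config$receptors[[i]]
    layouts[[i]] <- place_receptors(config$geometry, r$n, kind = r$kind,
                                    seed = seed + i)
    if (!is.null(r$scheme)) schemes[[r$kind]] <- load_scheme(r$scheme)
  }
  trial_config(config$geometry, layouts,
               schemes = if (length(schemes)) schemes else NULL,
               release_mode = config$release_mode, q = config$q,
               dt = config$dt, duration = config$duration, v_m = config$v_m,
               d_in = config$d_in, d_out = config$d_out, dr = config$dr,
               rho_local = config$rho_local, record_dt = config$record_dt)
}
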