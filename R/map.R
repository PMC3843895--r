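# Parametric map of peak current over (receptor surface density, PSD radius)
# and the steepest-change ("most economical") direction field.

#' Peak-current map over receptor density and pool size
#'
#' Evaluates the ensemble-mean peak current on a grid of receptor surface
#' density (receptors/nm^2, defined as \eqn{N/\pi r_a^2}) by PSD radius (nm),
#' then estimates at every interior node the direction of fastest change of
#' the surface by central differences. The two axes carry different units;
#' gradients are reported per-axis in those units and the unit-vector
#' direction is computed on the raw axis scales (no cross-axis
#' normalisation — flagged in the result so users can renormalise).
#'
#' Receptor counts are `round(density * pi * r_a^2)`; cells whose count falls
#' outside `n_range` are skipped.
#'
#' @param config Base [trial_config()] (single receptor pool).
#' @param densities Grid of receptor surface densities (nm^-2). Defaults to
#'   0.6--1.6 times the base configuration's density (4 points).
#' @param psd_radii Grid of PSD radii (nm); defaults to 4 points spanning
#'   60--180 nm, capped by the cleft radius.
#' @param n_trials Trials per cell.
#' @param base_seed Seed; cells share streams with sweeps visiting the same
#'   configuration.
#' @param n_range Admissible receptor-count range (default 2 to 300).
#' @param peak_fun Optional function `(density, psd_radius) -> peak` that
#'   replaces the simulation (used to verify the gradient estimator against
#'   analytic surfaces).
#' @return A `parametric_map` with `$surface` (one row per cell) and
#'   `$gradient` (interior nodes: partial derivatives, unit direction,
#'   `flat` flag where the gradient vanishes).
#' @export
parametric_map <- function(config, densities = NULL, psd_radii = NULL,
                           n_trials = 20, base_seed = 1,
                           n_range = c(2, 300), peak_fun = NULL) {
  kind <- if (is.null(peak_fun)) sweep_kind(config) else
    (if (length(config$kinds)) config$kinds[[1]] else "AMPAR")
  ra0 <- config$geometry$psd_radius
  d0 <- nrow(config$layouts[[1]]) / (pi * ra0^2)
  densities <- densities %||% (d0 * c(0.6, 1.0, 1.3, 1.6))
  psd_radii <- psd_radii %||%
    pmin(config$geometry$cleft_radius, c(60, 100, 140, 180))
  if (length(densities) < 3 || length(psd_radii) < 3)
    warn("parametric map grid smaller than 3x3; gradients will be sparse")
  grid <- tidyr::expand_grid(density = sort(densities),
                             psd_radius = sort(psd_radii))
  rows <- purrr::pmap(grid, function(density, psd_radius) {
    n <- as.integer(round(density * pi * psd_radius^2))
    if (is.null(peak_fun) && (n < n_range[1] || n > n_range[2])) return(NULL)
    if (!is.null(peak_fun)) {
      peak <- peak_fun(density, psd_radius)
      return(tibble(density = density, psd_radius = psd_radius,
                    n_receptors = n, mean_peak_pA = peak,
                    sd_peak_pA = NA_real_, mean_nn = NA_real_))
    }
    cell <- run_cell(config, kind, config$geometry$cleft_radius, psd_radius,
                     n, n_trials, base_seed)
    g <- glance(cell$ensemble)
    g <- g[g$kind == kind, ]
    tibble(density = density, psd_radius = psd_radius, n_receptors = n,
           mean_peak_pA = g$mean_peak_pA, sd_peak_pA = g$sd_peak_pA,
           mean_nn = cell$mean_nn)
  })
  surface <- dplyr::bind_rows(rows)

  dvals <- sort(unique(surface$density))
  rvals <- sort(unique(surface$psd_radius))
  getz <- function(d, r) {
    z <- surface$mean_peak_pA[surface$density == d & surface$psd_radius == r]
    if (length(z) == 1) z else NA_real_
  }
  grads <- list()
  if (length(dvals) >= 3 && length(rvals) >= 3) {
    for (i in 2:(length(dvals) - 1)) {
      for (j in 2:(length(rvals) - 1)) {
        z_dp <- getz(dvals[i + 1], rvals[j]); z_dm <- getz(dvals[i - 1], rvals[j])
        z_rp <- getz(dvals[i], rvals[j + 1]); z_rm <- getz(dvals[i], rvals[j - 1])
        if (anyNA(c(z_dp, z_dm, z_rp, z_rm))) next
        gd <- (z_dp - z_dm) / (dvals[i + 1] - dvals[i - 1])
        gr <- (z_rp - z_rm) / (rvals[j + 1] - rvals[j - 1])
        nrm <- sqrt(gd^2 + gr^2)
        flat <- nrm < .Machine$double.eps^0.5
        grads[[length(grads) + 1]] <- tibble(
          density = dvals[i], psd_radius = rvals[j],
          d_peak_d_density = gd, d_peak_d_radius = gr,
          dir_density = if (flat) NA_real_ else gd / nrm,
          dir_radius = if (flat) NA_real_ else gr / nrm,
          flat = flat
        )
      }
    }
  }
  structure(
    list(surface = surface, gradient = dplyr::bind_rows(grads),
         axis_units = c(density = "nm^-2", psd_radius = "nm"),
         normalisation = "raw axis units (no cross-axis normalisation)",
         n_trials = n_trials, base_seed = base_seed),
    class = "parametric_map"
  )
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %d cells, %d gradient nodes (%s)\n",
              nrow(x$surface), nrow(x$gradient), x$normalisation))
  print(x$surface)
  invisible(x)
}

#' @export
tidy.parametric_map <- function(x, ...) x$surface

#' Least-squares polynomial fits for sweep summaries
#'
#' Thin wrappers around [stats::lm()] producing tidy coefficient tables:
#' `fit_linear()` fits `y ~ x`, `fit_quadratic()` fits `y ~ x + x^2`.
#'
#' @param x,y Numeric vectors of equal length (at least degree + 1 points).
#' @return A `polyfit` list: `coefficients` (tibble with `term`, `estimate`,
#'   `std_error`), `r_squared`, `residuals`, `degree`.
#' @examples
#' fit_linear(1:5, 2 * (1:5) + 1)$coefficients
#' @export
fit_linear <- function(x, y) fit_poly(x, y, 1L)

#' @rdname fit_linear
#' @export
fit_quadratic <- function(x, y) fit_poly(x, y, 2L)

fit_poly <- function(x, y, degree) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < degree + 1)
    abort(sprintf("need at least %d points for a degree-%d fit",
                  degree + 1, degree))
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  if (any(is.na(coef(fit))))
    abort("rank-deficient fit (x values are degenerate)")
  sm <- suppressWarnings(summary(fit))  # exact fits warn about perfect R^2
  terms <- c("intercept", "x", "x^2")[seq_len(degree + 1)]
  structure(
    list(coefficients = tibble(term = terms,
                               estimate = unname(coef(fit)),
                               std_error = unname(sm$coefficients[, 2])),
         r_squared = sm$r.squared,
         residuals = unname(stats::residuals(fit)),
         degree = degree),
    class = "polyfit"
  )
}

#' @export
print.polyfit <- function(x, ...) {
  cat(sprintf("<polyfit> degree %d, R^2 = %.4f\n", x$degree, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.polyfit <- function(x, ...) x$coefficients

#' @export
glance.polyfit <- function(x, ...) {
  tibble(r_squared = x$r_squared, degree = x$degree,
         n = length(x$residuals))
}
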