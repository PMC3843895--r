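#' Define the synapse geometry
#'
#' The synaptic apposition is modelled as a flat cylindrical cleft of radius
#' `cleft_radius` and height `cleft_height` between the pre- and postsynaptic
#' membranes. The postsynaptic density (PSD) is a concentric disc of radius
#' `psd_radius` holding the receptors; the presynaptic active zone, where
#' release occurs, opposes it. Outside the cleft rim, transmitter diffuses in
#' open three-dimensional space bounded by an absorbing sphere of radius
#' `outer_radius`, which stands in for loss into the surrounding neuropil.
#'
#' Defaults describe the typical small excitatory synapse: a 200 nm cleft with
#' a 110 nm PSD and a 19 nm cleft height.
#'
#' @param cleft_radius Cleft radius \eqn{R} in nm (typical range 180--240).
#' @param psd_radius PSD radius \eqn{r_a} in nm (typical range 60--200); must
#'   not exceed `cleft_radius`.
#' @param cleft_height Cleft height \eqn{\delta} in nm.
#' @param outer_radius Radius of the absorbing outer boundary in nm.
#' @return An object of class `synapse_geometry`.
#' @examples
#' synapse_geometry()
#' synapse_geometry(cleft_radius = 240, psd_radius = 160)
#' @export
synapse_geometry <- function(cleft_radius = 200, psd_radius = 110,
                             cleft_height = 19, outer_radius = 2000) {
  if (!is.numeric(cleft_radius) || cleft_radius <= 0)
    abort("`cleft_radius` must be a positive length in nm")
  if (!is.numeric(psd_radius) || psd_radius <= 0 || psd_radius > cleft_radius)
    abort("`psd_radius` must satisfy 0 < psd_radius <= cleft_radius")
  if (!is.numeric(cleft_height) || cleft_height <= 0)
    abort("`cleft_height` must be a positive length in nm")
  if (!is.numeric(outer_radius) || outer_radius <= cleft_radius)
    abort("`outer_radius` must exceed `cleft_radius`")
  structure(
    list(cleft_radius = as.numeric(cleft_radius),
         psd_radius = as.numeric(psd_radius),
         cleft_height = as.numeric(cleft_height),
         outer_radius = as.numeric(outer_radius)),
    class = "synapse_geometry"
  )
}

#' @export
print.synapse_geometry <- function(x, ...) {
  cat("<synapse_geometry>\n")
  cat(sprintf("  cleft radius R      : %g nm\n", x$cleft_radius))
  cat(sprintf("  PSD radius r_a      : %g nm\n", x$psd_radius))
  cat(sprintf("  cleft height delta  : %g nm\n", x$cleft_height))
  cat(sprintf("  absorbing boundary  : %g nm\n", x$outer_radius))
  invisible(x)
}

is_synapse_geometry <- function(x) inherits(x, "synapse_geometry")

#' Scatter receptors uniformly over the PSD
#'
#' Draws `n` receptor positions independently and uniformly at random over the
#' PSD disc, the spatial null model for receptor placement used throughout the
#' package (a binomial point process; Poisson-like for the pool sizes
#' considered here).
#'
#' @param geometry A [synapse_geometry()].
#' @param n Number of receptors (non-negative integer).
#' @param kind Receptor kind label, `"AMPAR"` or `"NMDAR"` (any string is
#'   accepted so custom schemes can be attached by name).
#' @param seed Optional integer seed; with a fixed seed the layout is
#'   reproducible. Leaves the global RNG state untouched.
#' @return A `receptor_layout`: a tibble with columns `kind`, `x`, `y` (nm,
#'   relative to the cleft axis) and the PSD radius stored as attribute
#'   `psd_radius`.
#' @examples
#' geom <- synapse_geometry()
#' lay <- place_receptors(geom, 50, "AMPAR", seed = 1)
#' mean_nn_distance(lay)
#' @export
place_receptors <- function(geometry, n, kind = "AMPAR", seed = NULL) {
  stopifnot(is_synapse_geometry(geometry))
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n))
    abort("`n` must be a single non-negative integer")
  draw <- function() {
    r <- geometry$psd_radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    tibble(kind = rep(as.character(kind), n), x = r * cos(th), y = r * sin(th))
  }
  pts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_receptor_layout(pts, psd_radius = geometry$psd_radius)
}

new_receptor_layout <- function(df, psd_radius) {
  structure(as_tibble(df), psd_radius = psd_radius,
            class = c("receptor_layout", class(as_tibble(df))))
}

#' @export
print.receptor_layout <- function(x, ...) {
  cat(sprintf("<receptor_layout> %d receptor(s) on a PSD of radius %g nm\n",
              nrow(x), attr(x, "psd_radius")))
  NextMethod()
}

#' Mean nearest-neighbour distance of a receptor layout
#'
#' For each receptor, the distance to its closest neighbour; the arithmetic
#' mean over the pool summarises receptor crowding. For a uniformly random
#' pattern with intensity \eqn{\lambda} the expectation approaches the planar
#' Poisson value \eqn{0.5/\sqrt{\lambda}} (modulo edge effects).
#'
#' @param layout A `receptor_layout` or any data frame with `x`, `y` columns
#'   (at least two rows).
#' @param interior_margin Border-correction margin in nm: when positive, the
#'   average runs only over receptors at least this far from the PSD edge
#'   (their neighbours may be anywhere), the textbook border-method estimator
#'   that removes the upward edge bias when comparing against the unbounded
#'   Poisson expectation. Requires a `psd_radius` attribute. Default 0
#'   (plain mean over all receptors).
#' @return Mean nearest-neighbour distance in nm.
#' @export
mean_nn_distance <- function(layout, interior_margin = 0) {
  if (nrow(layout) < 2)
    abort("nearest-neighbour distance is undefined for fewer than 2 receptors")
  d <- as.matrix(stats::dist(cbind(layout$x, layout$y)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  if (interior_margin > 0) {
    ra <- attr(layout, "psd_radius")
    if (is.null(ra)) abort("`interior_margin` needs a `psd_radius` attribute")
    keep <- sqrt(layout$x^2 + layout$y^2) <= ra - interior_margin
    if (!any(keep)) return(NA_real_)
    nn <- nn[keep]
  }
  mean(nn)
}

#' Rescale a receptor layout to a new PSD radius
#'
#' Two modes mirror the two potentiation scenarios studied with this model:
#'
#' * `"density_constant"`: the PSD is expanded (or shrunk) and the receptor
#'   count is rescaled by the area ratio, `n' = round(n * (new/old)^2)`, so
#'   the surface density is preserved; a fresh uniform layout of `n'`
#'   receptors is drawn. Receptor counts are integers, hence the rounding.
#' * `"fixed_n"`: the receptor count is kept and the existing positions are
#'   rescaled radially onto the new disc (receptor crowding/declustering);
#'   nearest-neighbour distances scale exactly by `new/old`.
#'
#' @param layout A `receptor_layout`.
#' @param new_psd_radius Target PSD radius in nm.
#' @param mode `"density_constant"` or `"fixed_n"`.
#' @param seed Seed for the fresh draw in density-constant mode.
#' @param n_override Optional explicit receptor count overriding the
#'   area-ratio rule (density-constant mode only), for running alternative
#'   published readings of a scenario.
#' @param geometry Optional [synapse_geometry()] used to check that the new
#'   radius stays within the cleft.
#' @return A new `receptor_layout`.
#' @export
scale_layout <- function(layout, new_psd_radius,
                         mode = c("density_constant", "fixed_n"),
                         seed = NULL, n_override = NULL, geometry = NULL) {
  mode <- match.arg(mode)
  old_ra <- attr(layout, "psd_radius")
  if (is.null(old_ra)) abort("`layout` carries no `psd_radius` attribute")
  if (new_psd_radius <= 0) abort("`new_psd_radius` must be positive")
  if (!is.null(geometry) && new_psd_radius > geometry$cleft_radius)
    abort("`new_psd_radius` exceeds the cleft radius")
  kind <- if (nrow(layout) > 0) layout$kind[[1]] else "AMPAR"
  if (mode == "fixed_n") {
    s <- new_psd_radius / old_ra
    out <- tibble(kind = layout$kind, x = layout$x * s, y = layout$y * s)
    return(new_receptor_layout(out, psd_radius = new_psd_radius))
  }
  n_new <- if (!is.null(n_override)) as.integer(n_override)
           else as.integer(round(nrow(layout) * (new_psd_radius / old_ra)^2))
  if (n_new == 0 && nrow(layout) > 0)
    warn("density-constant rescaling produced an empty layout")
  g <- synapse_geometry(
    cleft_radius = max(new_psd_radius, old_ra,
                       if (!is.null(geometry)) geometry$cleft_radius else 0),
    psd_radius = new_psd_radius,
    cleft_height = if (!is.null(geometry)) geometry$cleft_height else 19,
    outer_radius = if (!is.null(geometry)) geometry$outer_radius
                   else max(2000, 2 * new_psd_radius)
  )
  place_receptors(g, n_new, kind = kind, seed = seed)
}

#' Read or write a receptor layout as tab-separated text
#'
#' One receptor per row with columns `kind`, `x_nm`, `y_nm`; the PSD radius is
#' kept in a `# psd_radius_nm:` header comment.
#'
#' @param layout A `receptor_layout`.
#' @param path File path.
#' @return `write_layout()` returns `path` invisibly; `read_layout()` returns
#'   a `receptor_layout`.
#' @export
write_layout <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# psd_radius_nm: %g", attr(layout, "psd_radius")), con)
  writeLines("kind\tx_nm\ty_nm", con)
  if (nrow(layout) > 0)
    writeLines(sprintf("%s\t%.6g\t%.6g", layout$kind, layout$x, layout$y), con)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# psd_radius_nm:", lines, value = TRUE)
  if (length(hdr) != 1) abort("layout file lacks a `# psd_radius_nm:` header")
  ra <- as.numeric(sub("^# psd_radius_nm:\\s*", "", hdr))
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new_receptor_layout(
    tibble(kind = as.character(df$kind), x = df$x_nm, y = df$y_nm),
    psd_radius = ra
  )
}
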