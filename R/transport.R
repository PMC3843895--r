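#' Quantal release of glutamate into the cleft
#'
#' Places all `q` transmitter molecules of one vesicle at a point source on
#' the presynaptic face of the cleft (z = cleft height), either on the cleft
#' axis (`"centre"`, the rotationally symmetric case) or at a point drawn
#' uniformly over the active-zone disc of radius equal to the PSD radius
#' (`"random_active_zone"`). Release is treated as instantaneous: all
#' molecules are free at t = 0.
#'
#' @param geometry A [synapse_geometry()].
#' @param q Number of molecules in the quantum (default 2700).
#' @param mode `"centre"` or `"random_active_zone"`.
#' @param seed Optional integer seed for the random release location.
#' @return A `molecule_ensemble`: tibble with columns `x`, `y`, `z` (nm) and
#'   `region` (`"cleft"`, `"extracellular"` or `"absorbed"`).
#' @examples
#' mols <- release_molecules(synapse_geometry(), q = 2700)
#' @export
release_molecules <- function(geometry, q = 2700,
                              mode = c("centre", "random_active_zone"),
                              seed = NULL) {
  stopifnot(is_synapse_geometry(geometry))
  mode <- match.arg(mode)
  if (!is.numeric(q) || length(q) != 1 || q < 0 || q != round(q))
    abort("`q` must be a single non-negative integer")
  pt <- c(0, 0)
  if (mode == "random_active_zone") {
    draw <- function() {
      r <- geometry$psd_radius * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      c(r * cos(th), r * sin(th))
    }
    pt <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  out <- tibble(
    x = rep(pt[1], q), y = rep(pt[2], q),
    z = rep(geometry$cleft_height, q),
    region = factor(rep("cleft", q),
                    levels = c("cleft", "extracellular", "absorbed"))
  )
  structure(out, class = c("molecule_ensemble", class(out)))
}

#' Advance free molecules by one Brownian step
#'
#' Each free molecule takes an isotropic Gaussian step with per-axis variance
#' `2 D dt`, with `D` chosen by its current region. Rules at the boundaries:
#' molecules inside the cleft reflect at both membranes (z = 0 and
#' z = cleft height) and become extracellular once their radial distance
#' exceeds the cleft radius; extracellular molecules diffuse freely in 3-D,
#' may re-enter the cleft through the rim, cannot cross the terminal
#' membranes, and are absorbed (and stop moving) once they reach the outer
#' boundary sphere. Absorbed molecules are never revived, so the absorbed
#' count is monotone.
#'
#' @param molecules A `molecule_ensemble` (or data frame with `x`, `y`, `z`,
#'   `region`).
#' @param geometry A [synapse_geometry()].
#' @param dt Time step in microseconds (default 0.1).
#' @param d_in,d_out Diffusion coefficients inside/outside the cleft in
#'   um^2/ms (defaults 0.33 and 0.4; 0.33 um^2/ms = 330 nm^2/us).
#' @param sealed_rim If `TRUE`, the cleft rim reflects instead of letting
#'   molecules out (useful for conservation checks on a closed cleft).
#' @return The updated `molecule_ensemble`.
#' @export
step_brownian <- function(molecules, geometry, dt = 0.1,
                          d_in = 0.33, d_out = 0.4, sealed_rim = FALSE) {
  stopifnot(is_synapse_geometry(geometry))
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be a positive time in us")
  n <- nrow(molecules)
  if (n == 0) return(molecules)
  R <- geometry$cleft_radius; delta <- geometry$cleft_height
  Rout <- geometry$outer_radius
  x <- molecules$x; y <- molecules$y; z <- molecules$z
  region <- as.character(molecules$region)

  free <- region != "absorbed"
  Dnm <- ifelse(region == "cleft", d_in, d_out) * 1000  # nm^2/us
  sg <- sqrt(2 * Dnm * dt)
  nx <- x; ny <- y; nz <- z
  nf <- sum(free)
  if (nf > 0) {
    nx[free] <- x[free] + sg[free] * stats::rnorm(nf)
    ny[free] <- y[free] + sg[free] * stats::rnorm(nf)
    nz[free] <- z[free] + sg[free] * stats::rnorm(nf)
  }

  cleft <- free & region == "cleft"
  if (any(cleft)) {
    # fold z back into [0, delta] (repeated reflection == triangle-wave fold)
    zm <- nz[cleft] %% (2 * delta)
    nz[cleft] <- ifelse(zm > delta, 2 * delta - zm, zm)
    r2 <- nx[cleft]^2 + ny[cleft]^2
    if (sealed_rim) {
      out <- r2 > R^2
      if (any(out)) {
        r <- sqrt(r2[out])
        s <- (2 * R - r) / r          # radial reflection at the rim
        s[s < 0] <- 0                  # guard against pathological large steps
        nx[cleft][out] <- nx[cleft][out] * s
        ny[cleft][out] <- ny[cleft][out] * s
      }
    } else {
      region[cleft][r2 > R^2] <- "extracellular"
    }
  }

  extr <- free & region == "extracellular" & !(cleft)
  if (any(extr)) {
    r2 <- nx[extr]^2 + ny[extr]^2
    inside_rim <- r2 < R^2
    ok_z <- nz[extr] >= 0 & nz[extr] <= delta
    # re-entry through the rim gap
    region[extr][inside_rim & ok_z] <- "cleft"
    # proposed move crosses a terminal membrane: reject it
    rej <- inside_rim & !ok_z
    nx[extr][rej] <- x[extr][rej]
    ny[extr][rej] <- y[extr][rej]
    nz[extr][rej] <- z[extr][rej]
    zc <- nz[extr] - delta / 2
    absorbed <- !inside_rim & (nx[extr]^2 + ny[extr]^2 + zc^2 > Rout^2)
    region[extr][absorbed] <- "absorbed"
  }

  out <- tibble(x = nx, y = ny, z = nz,
                region = factor(region,
                                levels = c("cleft", "extracellular", "absorbed")))
  structure(out, class = c("molecule_ensemble", class(out)))
}

#' Radial concentration profile inside the cleft
#'
#' Bins in-cleft molecules into concentric rings of width `dr` and converts
#' counts to concentration as \eqn{C = N_\delta / (2\pi r \delta \Delta r)}
#' with `r` the ring mid-radius (the innermost ring is the disc of radius
#' `dr`, volume \eqn{\pi \Delta r^2 \delta}; both follow from the exact
#' annulus volume used here). 1 mM corresponds to 6.022e-4 molecules/nm^3.
#'
#' @param molecules A `molecule_ensemble`.
#' @param geometry A [synapse_geometry()].
#' @param dr Ring width in nm (default 10).
#' @param time Optional timestamp in us, stored in the output.
#' @return A tibble with one row per ring: `bin`, `r_inner`, `r_mid`,
#'   `r_outer` (nm), `n_molecules`, `volume_nm3`, `concentration_mM` and
#'   `time_us`.
#' @export
concentration_profile <- function(molecules, geometry, dr = 10, time = NA_real_) {
  stopifnot(is_synapse_geometry(geometry))
  if (!is.numeric(dr) || dr <= 0) abort("`dr` must be a positive length in nm")
  R <- geometry$cleft_radius; delta <- geometry$cleft_height
  nb <- ceiling(R / dr)
  edges <- (0:nb) * dr
  incl <- molecules$region == "cleft"
  r <- sqrt(molecules$x[incl]^2 + molecules$y[incl]^2)
  b <- pmin(floor(r / dr), nb - 1)
  counts <- tabulate(b + 1, nbins = nb)
  vol <- pi * (edges[-1]^2 - edges[-(nb + 1)]^2) * delta
  tibble(
    bin = seq_len(nb),
    r_inner = edges[-(nb + 1)],
    r_mid = (edges[-1] + edges[-(nb + 1)]) / 2,
    r_outer = edges[-1],
    n_molecules = counts,
    volume_nm3 = vol,
    concentration_mM = counts / vol / .mol_per_nm3_per_mM,
    time_us = time
  )
}

#' Local glutamate concentration at given membrane positions
#'
#' Counts in-cleft molecules whose planar distance to each query position is
#' at most `rho_local` and divides by the sampling-cylinder volume
#' \eqn{\pi \rho^2 \delta}. This per-receptor estimator replaces the ring
#' profile when release is off-centre and rotational symmetry fails.
#'
#' @param molecules A `molecule_ensemble`.
#' @param positions Data frame with `x`, `y` columns (nm), e.g. a
#'   `receptor_layout`.
#' @param geometry A [synapse_geometry()].
#' @param rho_local Sampling radius in nm (default 20).
#' @return Numeric vector of concentrations in mM, one per query position.
#' @export
local_concentration <- function(molecules, positions, geometry, rho_local = 20) {
  stopifnot(is_synapse_geometry(geometry))
  if (!is.numeric(rho_local) || rho_local <= 0)
    abort("`rho_local` must be a positive length in nm")
  delta <- geometry$cleft_height
  incl <- molecules$region == "cleft"
  mx <- molecules$x[incl]; my <- molecules$y[incl]
  vol <- pi * rho_local^2 * delta
  vapply(seq_len(nrow(positions)), function(i) {
    cnt <- sum((mx - positions$x[i])^2 + (my - positions$y[i])^2 <= rho_local^2)
    cnt / vol / .mol_per_nm3_per_mM
  }, numeric(1))
}

#' Tabulate molecule counts by region
#' @param molecules A `molecule_ensemble`.
#' @return A tibble with columns `region` and `n`.
#' @export
count_regions <- function(molecules) {
  tibble(region = c("cleft", "extracellular", "absorbed"),
         n = as.integer(table(molecules$region)[c("cleft", "extracellular",
                                                  "absorbed")]))
}
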