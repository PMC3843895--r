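#' Advance an occupancy vector by one hybrid step
#'
#' Propagates the master equation \eqn{dP/dt = Q(C)^T P} over `dt` with the
#' glutamate concentration frozen within the step (the hybrid algorithm's
#' receptor update). The integrator is classical RK4, sub-stepped so the
#' fastest exit rate times the sub-step stays below 0.25, which conserves
#' total probability to round-off and keeps occupancies non-negative even
#' during the stiff concentration spike right after release.
#'
#' @param p Occupancy vector over the scheme's states (non-negative, sums to
#'   one within 1e-6).
#' @param scheme A [kinetic_scheme()].
#' @param conc Local glutamate concentration in mM (frozen during the step).
#' @param dt Step length in us.
#' @return The updated occupancy vector (named by state).
#' @examples
#' sc <- load_scheme("AMPAR")
#' p <- setNames(c(1, rep(0, 6)), sc$states)
#' propagate_hybrid(p, sc, conc = 1, dt = 0.1)
#' @export
propagate_hybrid <- function(p, scheme, conc, dt) {
  scheme <- load_scheme(scheme)
  k <- length(scheme$states)
  if (length(p) != k) abort("`p` length does not match the scheme")
  if (any(p < -1e-12)) abort("`p` must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) abort("`p` must sum to 1 within 1e-6")
  if (!is.numeric(conc) || conc < 0) abort("`conc` must be >= 0 (mM)")
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be positive (us)")
  out <- cpp_propagate_hybrid(as.numeric(p), scheme$q0, scheme$q1, conc, dt)
  setNames(out, scheme$states)
}

#' Advance discrete receptor states by one stochastic step
#'
#' Continuous-time Markov jump simulation of individual receptors over one
#' step with the concentration frozen: exponential waiting times are sampled
#' and jumps executed until the step is exhausted (exact within the step,
#' any number of jumps allowed). Uses R's RNG, so wrap in
#' [withr::with_seed()] for reproducibility.
#'
#' @param state Integer vector of current state indices (1-based) or
#'   character vector of state labels; one entry per receptor.
#' @param scheme A [kinetic_scheme()].
#' @param conc Concentration in mM; either a scalar or one value per receptor.
#' @param dt Step length in us.
#' @return Integer vector of new state indices (named by state label).
#' @export
propagate_stochastic <- function(state, scheme, conc, dt) {
  scheme <- load_scheme(scheme)
  k <- length(scheme$states)
  if (is.character(state)) state <- match(state, scheme$states)
  if (anyNA(state) || any(state < 1 | state > k))
    abort("`state` contains unknown states")
  conc <- rep_len(conc, length(state))
  if (any(conc < 0)) abort("`conc` must be >= 0 (mM)")
  if (dt <= 0) abort("`dt` must be positive (us)")
  out <- vapply(seq_along(state), function(i) {
    s <- state[i]
    rates0 <- scheme$q0[s, ]; rates1 <- scheme$q1[s, ]
    t_rem <- dt
    repeat {
      r <- rates0 + conc[i] * rates1
      lam <- sum(r)
      if (lam <= 0) break
      tj <- stats::rexp(1, rate = lam)
      if (tj > t_rem) break
      t_rem <- t_rem - tj
      s <- sample.int(k, 1, prob = r)
      rates0 <- scheme$q0[s, ]; rates1 <- scheme$q1[s, ]
    }
    s
  }, integer(1))
  setNames(out, scheme$states[out])
}

#' Open fraction of a receptor state
#'
#' Summed occupancy of the scheme's conducting states. Accepts either an
#' occupancy (probability) vector or discrete state indices/labels, in which
#' case the fraction of receptors in an open state is returned.
#'
#' @param state Occupancy vector (length = number of states) or integer /
#'   character vector of per-receptor states.
#' @param scheme A [kinetic_scheme()].
#' @return A probability in `[0, 1]`.
#' @export
open_fraction <- function(state, scheme) {
  scheme <- load_scheme(scheme)
  open_idx <- match(scheme$open_states, scheme$states)
  if (is.character(state)) {
    s <- match(state, scheme$states)
    if (anyNA(s)) abort("`state` contains unknown states")
    return(mean(s %in% open_idx))
  }
  if (length(state) == length(scheme$states) && !is.integer(state)) {
    return(sum(state[open_idx]))
  }
  mean(as.integer(state) %in% open_idx)
}

#' Steady-state occupancy at constant concentration
#'
#' Solves \eqn{Q(C)^T P = 0} with \eqn{\sum P = 1} directly (null-space of
#' the generator); used as an independent check of the time-stepping
#' propagators.
#'
#' @param scheme A [kinetic_scheme()].
#' @param conc Concentration in mM.
#' @return Named occupancy vector.
#' @export
steady_state <- function(scheme, conc) {
  scheme <- load_scheme(scheme)
  k <- length(scheme$states)
  q <- scheme$q0 + conc * scheme$q1
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  a <- rbind(t(q), rep(1, k))
  b <- c(rep(0, k), 1)
  p <- stats::lsfit(a, b, intercept = FALSE)$coefficients
  setNames(pmax(p, 0) / sum(pmax(p, 0)), scheme$states)
}
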