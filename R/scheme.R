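#' Build a ligand-gated kinetic scheme
#'
#' Low-level constructor for a Markov kinetic scheme of one receptor type.
#' Most users will call [load_scheme()] with a preset or a parameter file;
#' this constructor is exposed for writing custom (e.g. two-state) schemes in
#' code.
#'
#' Transitions with `ligand = TRUE` are binding steps whose rate is the base
#' rate multiplied by the local glutamate concentration; their `rate` is in
#' 1/(M s), all others in 1/s. All rates are multiplied by the temperature
#' factor `q10 ^ ((temp_target - temp_ref)/10)` when the generator matrices
#' are built.
#'
#' @param states Character vector of state labels.
#' @param transitions Data frame with columns `from`, `to`, `rate`, `ligand`.
#' @param open_states Character vector naming the conducting state(s).
#' @param conductance_pS Single-channel conductance in pS.
#' @param reversal_mV Reversal potential in mV (default 0).
#' @param q10,temp_ref,temp_target Temperature scaling: Q10 factor and the
#'   reference/target temperatures in degrees C. Defaults apply no scaling.
#' @param initial_state State holding all occupancy before release; defaults
#'   to the first state.
#' @param name Scheme label.
#' @return A `kinetic_scheme` object carrying the transition table plus the
#'   generator split `q0` (ligand-independent, 1/us) and `q1`
#'   (ligand-dependent, 1/(mM us)) used by the propagators.
#' @export
kinetic_scheme <- function(states, transitions, open_states, conductance_pS,
                           reversal_mV = 0, q10 = 1, temp_ref = 23,
                           temp_target = 23, initial_state = states[[1]],
                           name = "custom") {
  states <- as.character(states)
  if (anyDuplicated(states)) abort("duplicate state labels")
  tr <- as_tibble(transitions)
  req <- c("from", "to", "rate", "ligand")
  if (!all(req %in% names(tr)))
    abort("`transitions` needs columns from, to, rate, ligand")
  for (i in seq_len(nrow(tr))) {
    if (!(tr$from[i] %in% states) || !(tr$to[i] %in% states))
      abort(sprintf("transition %d (%s -> %s): unknown state",
                    i, tr$from[i], tr$to[i]))
    if (!is.finite(tr$rate[i]) || tr$rate[i] < 0)
      abort(sprintf("transition %d (%s -> %s): negative or non-finite rate",
                    i, tr$from[i], tr$to[i]))
  }
  if (length(open_states) < 1) abort("at least one open state is required")
  if (!all(open_states %in% states))
    abort("`open_states` contains labels not in `states`")
  if (!is.numeric(conductance_pS) || length(conductance_pS) != 1 ||
      !is.finite(conductance_pS) || conductance_pS <= 0)
    abort("missing or invalid `conductance_pS`")
  if (!(initial_state %in% states)) abort("unknown `initial_state`")

  k <- length(states)
  tf <- q10^((temp_target - temp_ref) / 10)
  q0 <- matrix(0, k, k, dimnames = list(states, states))
  q1 <- matrix(0, k, k, dimnames = list(states, states))
  for (i in seq_len(nrow(tr))) {
    a <- match(tr$from[i], states); b <- match(tr$to[i], states)
    if (a == b) abort(sprintf("transition %d is a self-loop", i))
    if (isTRUE(tr$ligand[i])) {
      # 1/(M s) -> 1/(mM us)
      q1[a, b] <- q1[a, b] + tr$rate[i] * tf * 1e-9
    } else {
      q0[a, b] <- q0[a, b] + tr$rate[i] * tf * 1e-6  # 1/s -> 1/us
    }
  }
  # connectivity: every open state reachable from the initial state when
  # ligand is present (all transitions available)
  adj <- (q0 + q1) > 0
  reach <- rep(FALSE, k); reach[match(initial_state, states)] <- TRUE
  repeat {
    nxt <- reach | (reach %*% adj > 0)
    if (all(nxt == reach)) break
    reach <- as.vector(nxt)
  }
  for (os in open_states) {
    if (!reach[match(os, states)])
      abort(sprintf("open state %s is unreachable from %s", os, initial_state))
  }
  structure(
    list(name = name, states = states, transitions = tr,
         open_states = as.character(open_states),
         conductance_pS = conductance_pS, reversal_mV = reversal_mV,
         q10 = q10, temp_ref = temp_ref, temp_target = temp_target,
         temp_factor = tf, initial_state = initial_state,
         q0 = q0, q1 = q1),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme> %s\n", x$name))
  cat(sprintf("  states: %s (open: %s)\n", paste(x$states, collapse = ", "),
              paste(x$open_states, collapse = ", ")))
  cat(sprintf("  %d transitions; conductance %g pS; E_rev %g mV\n",
              nrow(x$transitions), x$conductance_pS, x$reversal_mV))
  cat(sprintf("  temperature factor %.3f (Q10 %g, %g -> %g C)\n",
              x$temp_factor, x$q10, x$temp_ref, x$temp_target))
  invisible(x)
}

is_kinetic_scheme <- function(x) inherits(x, "kinetic_scheme")

scheme_preset_path <- function(preset) {
  fn <- switch(preset,
               AMPAR = "ampar_scheme.yml",
               NMDAR = "nmdar_scheme.yml",
               abort(sprintf("unknown scheme preset '%s'", preset)))
  system.file("extdata", fn, package = "cleftsim", mustWork = TRUE)
}

#' Load a receptor kinetic scheme
#'
#' Loads either one of the shipped presets (`"AMPAR"`: a seven-state
#' multi-stage scheme with two sequential binding steps, one open state and a
#' three-state desensitised branch, after the hippocampal AMPAR model of
#' Jonas, Major & Sakmann; `"NMDAR"`: a five-state scheme with two binding
#' steps, one desensitised and one open state, after Lester & Jahr) or any
#' scheme parameter file in the same YAML format. Preset rates are scaled to
#' 33--35 degrees C with a uniform Q10 multiplier declared in the file.
#'
#' All rate constants live in the parameter files (under
#' `system.file("extdata", package = "cleftsim")`), so the transcription from
#' the source literature is auditable and swappable.
#'
#' @param scheme `"AMPAR"`, `"NMDAR"`, or a path to a scheme YAML file.
#' @return A `kinetic_scheme`.
#' @examples
#' load_scheme("AMPAR")$conductance_pS  # 12.5
#' @export
load_scheme <- function(scheme = c("AMPAR", "NMDAR")) {
  if (is_kinetic_scheme(scheme)) return(scheme)
  stopifnot(is.character(scheme), length(scheme) == 1)
  path <- if (scheme %in% c("AMPAR", "NMDAR")) scheme_preset_path(scheme)
          else scheme
  if (!file.exists(path))
    abort(sprintf("scheme file not found: %s", path))
  y <- yaml::read_yaml(path)
  need <- c("name", "states", "open_states", "conductance_pS", "transitions")
  miss <- setdiff(need, names(y))
  if (length(miss) > 0)
    abort(sprintf("%s: missing field(s): %s", path, paste(miss, collapse = ", ")))
  tr <- purrr::map_dfr(seq_along(y$transitions), function(i) {
    t <- y$transitions[[i]]
    for (f in c("from", "to", "rate", "unit"))
      if (is.null(t[[f]]))
        abort(sprintf("%s: transition %d is missing `%s`", path, i, f))
    if (!t$unit %in% c("per_s", "per_M_per_s"))
      abort(sprintf("%s: transition %d (%s -> %s): unknown unit '%s'",
                    path, i, t$from, t$to, t$unit))
    tibble(from = t$from, to = t$to, rate = as.numeric(t$rate),
           ligand = identical(t$unit, "per_M_per_s"))
  })
  temp <- y$temperature %||% list()
  sc <- kinetic_scheme(
    states = y$states, transitions = tr, open_states = y$open_states,
    conductance_pS = y$conductance_pS,
    reversal_mV = y$reversal_mV %||% 0,
    q10 = temp$q10 %||% 1,
    temp_ref = temp$reference_C %||% 23,
    temp_target = temp$target_C %||% 23,
    initial_state = y$initial_state %||% y$states[[1]],
    name = y$name
  )
  attr(sc, "path") <- path
  sc
}

#' Write a kinetic scheme back to its YAML parameter format
#' @param scheme A `kinetic_scheme`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(is_kinetic_scheme(scheme))
  y <- list(
    name = scheme$name,
    states = as.list(scheme$states),
    initial_state = scheme$initial_state,
    open_states = as.list(scheme$open_states),
    conductance_pS = scheme$conductance_pS,
    reversal_mV = scheme$reversal_mV,
    temperature = list(q10 = scheme$q10, reference_C = scheme$temp_ref,
                       target_C = scheme$temp_target),
    transitions = purrr::pmap(scheme$transitions, function(from, to, rate, ligand)
      list(from = from, to = to, rate = rate,
           unit = if (ligand) "per_M_per_s" else "per_s"))
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
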