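#' Build a stimulus frame
#'
#' A stimulus frame pairs an odour code with a reinforcement code. Odour
#' identity is binary over the two projection neurons: `"A"` = (1,0),
#' `"B"` = (0,1), `"AB"` = (1,1), `"none"` = (0,0). The unconditional
#' stimulus is binary over (reward, punishment): `"sugar"` = (1,0),
#' `"shock"` = (0,1), `"none"` = (0,0).
#'
#' @param odour One of `"A"`, `"B"`, `"AB"`, `"none"`, or a 0/1 vector of
#'   length 2.
#' @param us One of `"sugar"`, `"shock"`, `"none"`, or a 0/1 vector of
#'   length 2.
#' @return An object of class `ic_stimulus` with fields `cs` and `us`.
#' @export
#' @examples
#' stimulus_frame("B", "shock")
stimulus_frame <- function(odour = "none", us = "none") {
  code <- function(x, table) {
    if (is.character(x)) {
      if (!x %in% names(table)) stop("unknown code: ", x, call. = FALSE)
      table[[x]]
    } else {
      stopifnot(length(x) == 2, all(x %in% c(0, 1)))
      as.numeric(x)
    }
  }
  cs <- code(odour, list(A = c(1, 0), B = c(0, 1), AB = c(1, 1), none = c(0, 0)))
  us <- code(us, list(sugar = c(1, 0), shock = c(0, 1), none = c(0, 0)))
  structure(list(cs = cs, us = us), class = "ic_stimulus")
}

#' Initialise the circuit state
#'
#' All activities start at zero and every KC->MBON synapse starts at the
#' resting weight `w_rest`, so the initial memory strength
#' `|W_k2m - w_rest|` is zero everywhere.
#'
#' @param params An `ic_parameters` object.
#' @return An object of class `ic_state` with fields `p`, `k`, `d`, `m`,
#'   `W_k2m` and time-step counter `t`.
#' @export
initial_state <- function(params = default_parameters()) {
  labels <- params$neuron_labels
  W <- matrix(params$w_rest, params$n_kc, params$n_mbon,
              dimnames = list(paste0("k", seq_len(params$n_kc)), labels$mbon))
  structure(list(
    p = numeric(params$n_pn),
    k = numeric(params$n_kc),
    d = stats::setNames(numeric(params$n_dan), labels$dan),
    m = stats::setNames(numeric(params$n_mbon), labels$mbon),
    W_k2m = W,
    t = 0L
  ), class = "ic_state")
}

#' Memory strength of the plastic synapses
#'
#' Any deviation of a KC->MBON weight from its resting value represents a
#' stored memory; its magnitude is the memory strength.
#'
#' @param state An `ic_state` object.
#' @param params An `ic_parameters` object (for `w_rest`).
#' @return A non-negative matrix of the same shape as `state$W_k2m`.
#' @export
memory_strength <- function(state, params = default_parameters()) {
  abs(state$W_k2m - params$w_rest)
}

#' Kenyon-cell response to a stimulus
#'
#' The PN odour code is projected through `W_p2k`, independent Gaussian noise
#' of scale `eta_scale` is added per KC, and the winner-take-all filter keeps
#' the top `wta_fraction` of KCs active (retaining their drive). The result
#' is clamped at zero: KC output is non-negative. Uses the current RNG
#' stream; set the seed upstream for reproducibility.
#'
#' @param stim An `ic_stimulus` (or any list with a `cs` field).
#' @param params An `ic_parameters` object.
#' @return Numeric vector of length `n_kc`.
#' @export
kc_response <- function(stim, params = default_parameters()) {
  stopifnot(length(stim$cs) == params$n_pn)
  drive <- as.numeric(stim$cs %*% params$W_p2k) +
    stats::rnorm(params$n_kc, mean = 0, sd = params$eta_scale)
  pmax(wta_fraction_filter(drive, params$wta_fraction), 0)
}

#' One synchronous DAN/MBON update
#'
#' Computes the DAN drive `u.W_u2d + m.W_m2d + b_d` and the MBON drive
#' `k.W_k2m + m.W_m2m + b_m`, both using the previous step's MBON activity,
#' then applies the chosen discretisation: `"literal"` sets the new activity
#' to the bounded-rectified drive divided by `tau`; `"leaky"` retains a
#' `(1 - 1/tau)` fraction of the previous activity and mixes in the drive at
#' rate `1/tau`. Activities are always within `[0, activation_cap]`.
#'
#' @param state An `ic_state` object (supplies `k`, `m`, `W_k2m`).
#' @param stim An `ic_stimulus` (supplies `us`).
#' @param params An `ic_parameters` object.
#' @return A list with numeric vectors `d` and `m`.
#' @export
neuron_step <- function(state, stim, params = default_parameters()) {
  if (length(stim$us) != 2L)
    stop("US code must have length 2", call. = FALSE)
  if (length(state$k) != params$n_kc ||
      !identical(dim(state$W_k2m), c(as.integer(params$n_kc), as.integer(params$n_mbon))))
    stop("state does not match parameter shapes", call. = FALSE)
  drive_d <- as.numeric(stim$us %*% params$W_u2d) +
    as.numeric(state$m %*% params$W_m2d) + params$b_d
  drive_m <- as.numeric(state$k %*% state$W_k2m) +
    as.numeric(state$m %*% params$W_m2m) + params$b_m
  cap <- params$activation_cap
  if (identical(params$integration, "leaky")) {
    d_new <- bounded_relu((1 - 1 / params$tau) * state$d + drive_d / params$tau, cap)
    m_new <- bounded_relu((1 - 1 / params$tau) * state$m + drive_m / params$tau, cap)
  } else {
    d_new <- bounded_relu(drive_d / params$tau, cap)
    m_new <- bounded_relu(drive_m / params$tau, cap)
  }
  list(d = stats::setNames(d_new, params$neuron_labels$dan),
       m = stats::setNames(m_new, params$neuron_labels$mbon))
}

#' Advance the circuit by one time-step
#'
#' The KC response (including its noise draw) is computed once per time-step;
#' the neuron update, dopaminergic factor and weight update are then repeated
#' `repeats` times (default 4) to smooth out ordering bias between the value
#' and weight updates. Optionally clamps intervention targets after each
#' neuron update and before plasticity.
#'
#' @param state An `ic_state` object.
#' @param stim An `ic_stimulus` object.
#' @param params An `ic_parameters` object.
#' @param rule Plasticity rule: `"dpr"` (default), `"rpe"`, or a function
#'   `(W, k, delta, m, params) -> W'`.
#' @param repeats Number of forward-propagation repeats per time-step.
#' @param intervention `NULL` or an `ic_intervention` (see
#'   [intervention_spec()]); applied after each neuron update.
#' @return The updated `ic_state`, with `t` incremented by 1.
#' @export
forward_step <- function(state, stim, params = default_parameters(),
                         rule = "dpr", repeats = 4L, intervention = NULL) {
  stopifnot(repeats >= 1L)
  update <- plasticity_rule(rule)
  state$p <- stim$cs
  state$k <- kc_response(stim, params)
  for (r in seq_len(repeats)) {
    act <- neuron_step(state, stim, params)
    state$d <- act$d
    state$m <- act$m
    if (!is.null(intervention)) {
      clamped <- clamp_activities(state$d, state$m, intervention, params)
      state$d <- clamped$d
      state$m <- clamped$m
    }
    delta <- dopaminergic_factor_static(state$d, params$W_d2km)
    state$W_k2m <- update(state$W_k2m, state$k, delta, state$m, params)
  }
  state$t <- state$t + 1L
  state
}

#' Tidy snapshot of a circuit state
#'
#' @param x An `ic_state` object.
#' @param ... Unused.
#' @return A data.frame with columns `time_step`, `neuron_or_synapse_id`,
#'   `value`, covering DAN and MBON activities, KC activities and all
#'   KC->MBON weights.
#' @export
as.data.frame.ic_state <- function(x, ...) {
  syn <- as.vector(x$W_k2m)
  syn_id <- as.vector(outer(rownames(x$W_k2m), colnames(x$W_k2m),
                            function(a, b) paste(a, b, sep = ">")))
  data.frame(
    time_step = x$t,
    neuron_or_synapse_id = c(names(x$d), names(x$m),
                             paste0("k", seq_along(x$k)), syn_id),
    value = c(unname(x$d), unname(x$m), x$k, syn),
    stringsAsFactors = FALSE
  )
}
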