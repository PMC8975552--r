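#' Define a CS/US pairing protocol
#'
#' Describes one high-resolution pairing of a 0.5-s odour (CS) pulse with a
#' 0.6-s reinforcement (US) pulse, separated by `delta_s` = US start minus
#' CS start (negative values mean the US precedes the CS, i.e. backward
#' pairing). The simulation runs at `sampling_hz` and is padded after the
#' last pulse so the dopamine kinetics decay back to baseline.
#'
#' The dopamine components use `tau_short` = 60 samples (0.6 s at 100 Hz,
#' the fast, high-peak depression pathway) and `tau_long` = 100 samples
#' (1 s, the slow, low-peak potentiation pathway); see the vignette for how
#' these timescales were chosen.
#'
#' @param delta_s US start minus CS start, in seconds.
#' @param cs_duration,us_duration Pulse durations in seconds.
#' @param sampling_hz Sampling rate (samples per second).
#' @param tau_short,tau_long Kinetics constants in samples; must satisfy
#'   [validate_time_constants()].
#' @param kc_on KC activity during the CS pulse (default: the activation
#'   cap, 2, so the cAMP term `D_dep * (k - w_rest)` is active).
#' @param us_gain US drive onto the DAN (default 2, as in the circuit's
#'   US->DAN weights).
#' @param mbon_inhibition MBON->DAN weight (default -0.3, the susceptible
#'   microcircuit's feedback inhibition).
#' @param w_rest Resting synaptic weight.
#' @param tail_s Seconds simulated after the last pulse.
#' @return An object of class `ic_protocol`.
#' @export
pairing_protocol <- function(delta_s, cs_duration = 0.5, us_duration = 0.6,
                             sampling_hz = 100, tau_short = 60, tau_long = 100,
                             kc_on = 2, us_gain = 2, mbon_inhibition = -0.3,
                             w_rest = 1, tail_s = 15) {
  stopifnot(sampling_hz > 0, cs_duration > 0, us_duration > 0)
  validate_time_constants(tau_short, tau_long)
  structure(list(delta_s = delta_s, cs_duration = cs_duration,
                 us_duration = us_duration, sampling_hz = sampling_hz,
                 tau_short = tau_short, tau_long = tau_long,
                 kc_on = kc_on, us_gain = us_gain,
                 mbon_inhibition = mbon_inhibition, w_rest = w_rest,
                 tail_s = tail_s), class = "ic_protocol")
}

#' ER-Ca2+ and cAMP proxies of a synapse
#'
#' The postulated second-messenger levels at a KC->MBON synapse, as
#' functions of the local information (proportionality constants set to 1):
#' `ER_Ca = -D_pot * (k - w_rest) - (D_pot - D_dep) * W` and
#' `cAMP = D_dep * (k - w_rest)`. Substituting these into the postulate
#' that the weight change is proportional to `-ER_Ca - cAMP` recovers the
#' dopaminergic plasticity rule with factor `delta = D_pot - D_dep`.
#'
#' @param D_dep,D_pot Depression/potentiation dopamine components.
#' @param k KC activity.
#' @param W Synaptic weight.
#' @param w_rest Resting weight.
#' @return A list with numeric `ER_Ca` and `cAMP` (vectorised).
#' @export
er_camp_levels <- function(D_dep, D_pot, k, W, w_rest = 1) {
  list(ER_Ca = -D_pot * (k - w_rest) - (D_pot - D_dep) * W,
       cAMP = D_dep * (k - w_rest))
}

#' Simulate one pairing in the susceptible-memory motif
#'
#' Runs a single KC -> MBON synapse with one depressing DAN terminal (no
#' positive dopaminergic effect) at high temporal resolution. The CS pulse
#' drives the KC, the US pulse drives the DAN (which the MBON inhibits, as
#' in the susceptible microcircuit), [kinetics_step()] evolves the two
#' dopamine components, and the weight is updated each sample by
#' `dW = (D_pot - D_dep) * (k + W - w_rest) * dt`.
#'
#' @param protocol An `ic_protocol` from [pairing_protocol()].
#' @return A data.frame of class `ic_messenger_trace` with per-sample
#'   columns `time`, `k`, `d`, `D_dep`, `D_pot`, `delta`, `W`, `ER_Ca`,
#'   `cAMP`.
#' @export
run_pairing <- function(protocol) {
  fs <- protocol$sampling_hz
  dt <- 1 / fs
  cs_start <- max(0, -protocol$delta_s)
  us_start <- cs_start + protocol$delta_s
  t_end <- max(cs_start + protocol$cs_duration,
               us_start + protocol$us_duration) + protocol$tail_s
  time <- seq(0, t_end, by = dt)
  n <- length(time)

  cs_on <- time >= cs_start & time < cs_start + protocol$cs_duration
  us_on <- time >= us_start & time < us_start + protocol$us_duration

  # depressing-only terminal: the DAN's effect on this synapse is -1
  kin <- dopamine_kinetics(matrix(-1, 1, 1), protocol$tau_short, protocol$tau_long)
  W <- protocol$w_rest
  w_rest <- protocol$w_rest

  out <- data.frame(time = time, k = 0, d = 0, D_dep = 0, D_pot = 0,
                    delta = 0, W = NA_real_, ER_Ca = 0, cAMP = 0)
  for (i in seq_len(n)) {
    k <- if (cs_on[i]) protocol$kc_on else 0
    m <- bounded_relu(k * W)
    d <- bounded_relu(protocol$us_gain * as.numeric(us_on[i]) +
                        protocol$mbon_inhibition * m)
    kin <- kinetics_step(kin, d)
    comp <- kinetics_components(kin)
    lev <- er_camp_levels(comp$D_dep, comp$D_pot, k, W, w_rest)
    W <- max(W + comp$delta * (k + W - w_rest) * dt, 0)
    out$k[i] <- k; out$d[i] <- d
    out$D_dep[i] <- comp$D_dep; out$D_pot[i] <- comp$D_pot
    out$delta[i] <- comp$delta; out$W[i] <- W
    out$ER_Ca[i] <- lev$ER_Ca; out$cAMP[i] <- lev$cAMP
  }
  class(out) <- c("ic_messenger_trace", "data.frame")
  out
}

#' Mean synaptic-weight change of a pairing trace
#'
#' The unnormalised mean change implied by the second-messenger levels:
#' `(1/T) * sum(-ER_Ca - cAMP)`; linear in the messenger traces.
#'
#' @param trace An `ic_messenger_trace` from [run_pairing()].
#' @return A single number.
#' @export
mean_weight_change <- function(trace) {
  if (!nrow(trace)) stop("empty trace", call. = FALSE)
  mean(-trace$ER_Ca - trace$cAMP)
}

#' Sweep the CS/US interval
#'
#' Runs [run_pairing()] over a grid of `delta_s` values and reports the
#' mean weight change of each, normalised to the maximum absolute change of
#' the sweep. Forward pairings (US during or just after CS onset) yield
#' depression; backward pairings (US sufficiently before CS) yield
#' potentiation; widely separated pulses yield no change.
#'
#' @param delta_s Numeric vector of US-start minus CS-start offsets in
#'   seconds (default -5 to 5 in 0.5-s steps).
#' @param ... Passed on to [pairing_protocol()].
#' @return A data.frame with columns `delta_s`, `mean_change`,
#'   `normalised_change`.
#' @export
#' @examples
#' \donttest{
#' sweep <- backward_sweep(seq(-3, 1, by = 1))
#' }
backward_sweep <- function(delta_s = seq(-5, 5, by = 0.5), ...) {
  changes <- vapply(delta_s, function(ds) {
    mean_weight_change(run_pairing(pairing_protocol(delta_s = ds, ...)))
  }, numeric(1))
  scale <- max(abs(changes))
  data.frame(delta_s = delta_s, mean_change = changes,
             normalised_change = if (scale > 0) changes / scale else changes)
}
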