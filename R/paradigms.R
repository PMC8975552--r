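#' Build the 24-trial aversive conditioning schedule
#'
#' Trials alternate odour A (odd trials, 1-based) and odour B (even trials).
#' Each trial has three in-trial time-steps; odour is presented at steps 2
#' and 3 only. The phases are: 2 pre-training trials (no US), 10 acquisition
#' trials with the US paired to odour B at in-trial step 3, 2 resting trials,
#' and 10 forgetting trials whose content depends on `forgetting`:
#' `"extinction"` delivers no US; `"unpaired"` delivers the US at in-trial
#' step 1 of odour-A trials (temporally separated from the odour);
#' `"reversal"` pairs the US with odour A at in-trial step 3.
#'
#' @param forgetting One of `"extinction"`, `"unpaired"`, `"reversal"`.
#' @param us US identity used throughout, `"shock"` (default) or `"sugar"`.
#' @return A data.frame of class `ic_schedule` with one row per trial:
#'   `trial`, `phase`, `odour`, `us_step` (0 = none, 1 = unpaired,
#'   3 = paired) and `us`.
#' @export
#' @examples
#' sched <- build_aversive_paradigm("extinction")
#' table(sched$phase)
build_aversive_paradigm <- function(forgetting = c("extinction", "unpaired", "reversal"),
                                    us = c("shock", "sugar")) {
  forgetting <- match.arg(forgetting)
  us <- match.arg(us)
  trial <- 1:24
  odour <- ifelse(trial %% 2 == 1, "A", "B")
  phase <- rep(c("pre_training", "acquisition", "resting", forgetting),
               times = c(2, 10, 2, 10))
  us_step <- integer(24)
  us_step[phase == "acquisition" & odour == "B"] <- 3L
  if (forgetting == "unpaired") us_step[phase == forgetting & odour == "A"] <- 1L
  if (forgetting == "reversal") us_step[phase == forgetting & odour == "A"] <- 3L
  sched <- data.frame(trial = trial, phase = phase, odour = odour,
                      us_step = us_step, us = ifelse(us_step > 0, us, "none"),
                      stringsAsFactors = FALSE)
  class(sched) <- c("ic_schedule", "data.frame")
  sched
}

#' Build the classic unpaired conditioning schedule
#'
#' Identical trial skeleton to [build_aversive_paradigm()], but during
#' acquisition odour B is omitted: even trials deliver the US alone (no
#' odour, US at in-trial step 3) while odd trials present odour A without
#' US. The forgetting phase is an extinction test in which odours A and B
#' alternate with no US.
#'
#' @inheritParams build_aversive_paradigm
#' @return A data.frame of class `ic_schedule` (phase label for the test
#'   trials is `"extinction"`).
#' @export
build_unpaired_conditioning_paradigm <- function(us = c("shock", "sugar")) {
  us <- match.arg(us)
  sched <- build_aversive_paradigm("extinction", us = us)
  acq_b <- sched$phase == "acquisition" & sched$odour == "B"
  sched$odour[acq_b] <- "none"
  sched$us_step[acq_b] <- 3L
  sched$us[acq_b] <- us
  sched
}

# Expand a per-trial schedule into per-time-step stimulus frames.
# Step 1 is the initialisation step (no odour, no US).
expand_schedule <- function(sched) {
  rows <- list(data.frame(t = 1L, trial = 0L, in_trial_step = 0L,
                          phase = "initialisation", odour = "none",
                          us = "none", stringsAsFactors = FALSE))
  t <- 1L
  for (i in seq_len(nrow(sched))) {
    for (s in 1:3) {
      t <- t + 1L
      odour <- if (s >= 2) sched$odour[i] else "none"
      us <- if (sched$us_step[i] == s) sched$us[i] else "none"
      rows[[t]] <- data.frame(t = t, trial = sched$trial[i], in_trial_step = s,
                              phase = sched$phase[i], odour = odour, us = us,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run a conditioning experiment
#'
#' Initialises the circuit (all weights at `w_rest`), expands the trial
#' schedule into `1 + 3 * n_trials` time-steps (the first is an
#' odourless, US-free initialisation step), and advances the circuit with
#' [forward_step()] at each step. The trajectory is a pure function of
#' `(params, schedule, rule, seed)`.
#'
#' @param schedule An `ic_schedule` data.frame.
#' @param params An `ic_parameters` object.
#' @param rule Plasticity rule, `"dpr"` (default) or `"rpe"` or a function.
#' @param seed Integer seed for the KC noise stream.
#' @param repeats Forward-propagation repeats per time-step (default 4).
#' @param intervention `NULL` or an `ic_intervention`; it is applied during
#'   the trial phases named in its `phases` field.
#' @return An object of class `ic_experiment_log`: a list with the expanded
#'   `timeline` data.frame and matrices `k` (T x n_kc), `d` (T x n_dan),
#'   `m` (T x n_mbon) and array `W` (T x n_kc x n_mbon) of post-step
#'   snapshots.
#' @export
#' @examples
#' log <- run_experiment(build_aversive_paradigm("extinction"), seed = 1)
#' nrow(log$timeline)  # 73
run_experiment <- function(schedule, params = default_parameters(),
                           rule = "dpr", seed = 1L, repeats = 4L,
                           intervention = NULL) {
  set.seed(seed)
  timeline <- expand_schedule(schedule)
  n_t <- nrow(timeline)
  state <- initial_state(params)
  k_log <- matrix(NA_real_, n_t, params$n_kc)
  d_log <- matrix(NA_real_, n_t, params$n_dan,
                  dimnames = list(NULL, params$neuron_labels$dan))
  m_log <- matrix(NA_real_, n_t, params$n_mbon,
                  dimnames = list(NULL, params$neuron_labels$mbon))
  W_log <- array(NA_real_, c(n_t, params$n_kc, params$n_mbon),
                 dimnames = list(NULL, NULL, params$neuron_labels$mbon))
  for (i in seq_len(n_t)) {
    stim <- stimulus_frame(timeline$odour[i], timeline$us[i])
    iv <- NULL
    if (!is.null(intervention) && timeline$phase[i] %in% intervention$phases)
      iv <- intervention
    state <- forward_step(state, stim, params, rule = rule,
                          repeats = repeats, intervention = iv)
    k_log[i, ] <- state$k
    d_log[i, ] <- state$d
    m_log[i, ] <- state$m
    W_log[i, , ] <- state$W_k2m
  }
  structure(list(timeline = timeline, k = k_log, d = d_log, m = m_log,
                 W = W_log, params = params, rule = if (is.function(rule)) "custom" else rule,
                 seed = seed, final_state = state),
            class = "ic_experiment_log")
}

#' @export
print.ic_experiment_log <- function(x, ...) {
  cat(sprintf("Incentive-circuit experiment log: %d time-steps, %d trials, rule = %s\n",
              nrow(x$timeline), max(x$timeline$trial), x$rule))
  invisible(x)
}

#' Per-trial off-/on-shock summaries of a model run
#'
#' For every trial, reports each neuron's response at in-trial step 2 (the
#' odour-only, "off-shock" step) and step 3 (the step at which a paired US
#' would be delivered, "on-shock"), matching how trial responses are read
#' off imaging experiments.
#'
#' @param log An `ic_experiment_log` from [run_experiment()].
#' @return A data.frame with columns `trial`, `phase`, `odour`, `neuron`,
#'   `off_shock`, `on_shock`.
#' @export
extract_trial_summaries <- function(log) {
  tl <- log$timeline
  act <- cbind(log$d, log$m)
  trials <- unique(tl$trial[tl$trial > 0])
  out <- lapply(trials, function(tr) {
    i_off <- which(tl$trial == tr & tl$in_trial_step == 2L)
    i_on  <- which(tl$trial == tr & tl$in_trial_step == 3L)
    data.frame(trial = tr, phase = tl$phase[i_off], odour = tl$odour[i_off],
               neuron = colnames(act),
               off_shock = act[i_off, ], on_shock = act[i_on, ],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tidy per-time-step export of an experiment log
#'
#' @param x An `ic_experiment_log`.
#' @param ... Unused.
#' @return A long data.frame with columns `t`, `trial`, `in_trial_step`,
#'   `phase`, `odour`, `us`, `neuron`, `value` for all DANs and MBONs.
#' @export
as.data.frame.ic_experiment_log <- function(x, ...) {
  act <- cbind(x$d, x$m)
  n_neuron <- ncol(act)
  data.frame(
    x$timeline[rep(seq_len(nrow(x$timeline)), each = n_neuron), ],
    neuron = rep(colnames(act), times = nrow(act)),
    value = as.vector(t(act)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
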