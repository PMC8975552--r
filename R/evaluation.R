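#' Summarise trial-aligned imaging-style traces
#'
#' Traces follow the imaging protocol: 100 samples per trial at 5 Hz (20 s),
#' odour between samples 25 and 50, possible shock at sample 45. The
#' off-shock window is samples 28-42 inclusive (15 samples per fly, odour
#' before any shock) and the on-shock window samples 44-48 inclusive (5 per
#' fly, around the time shock could occur). For each neuron and trial the
#' mean and standard deviation are pooled over the n_flies x 15 (off) and
#' n_flies x 5 (on) sample matrices.
#'
#' @param traces A long data.frame with columns `neuron`, `fly`, `trial`,
#'   `sample_index` (1-100), `value`.
#' @return A data.frame with one row per neuron x trial: `neuron`, `trial`,
#'   `n_flies`, `off_mean`, `off_sd`, `on_mean`, `on_sd`.
#' @export
summarise_imaging_traces <- function(traces) {
  needed <- c("neuron", "fly", "trial", "sample_index", "value")
  if (!all(needed %in% names(traces)))
    stop("traces must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  n_samp <- stats::aggregate(sample_index ~ neuron + fly + trial, traces, length)
  if (any(n_samp$sample_index != 100L))
    stop("each (neuron, fly, trial) trace must have exactly 100 samples",
         call. = FALSE)
  off_win <- 28:42
  on_win <- 44:48
  groups <- unique(traces[, c("neuron", "trial")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- traces[traces$neuron == groups$neuron[i] &
                  traces$trial == groups$trial[i], ]
    off <- g$value[g$sample_index %in% off_win]
    on <- g$value[g$sample_index %in% on_win]
    data.frame(neuron = groups$neuron[i], trial = groups$trial[i],
               n_flies = length(unique(g$fly)),
               off_mean = mean(off), off_sd = stats::sd(off),
               on_mean = mean(on), on_sd = stats::sd(on),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate synthetic imaging-style traces
#'
#' Emits traces with the documented 100-sample / 5 Hz structure whose
#' off-window and on-window means equal given ground truths plus Gaussian
#' noise. The trace is zero outside the odour window; samples 25-43 carry
#' the off-shock level and samples 44-50 the on-shock level. Synthetic data
#' for exercising [summarise_imaging_traces()]; it emulates window means
#' only, not the shape of recorded calcium transients.
#'
#' @param truth A data.frame with columns `neuron`, `trial`, `off`, `on`.
#' @param n_flies Flies per neuron.
#' @param noise_sd Gaussian noise sd added per sample.
#' @param seed Integer seed.
#' @return A long data.frame in the schema of [summarise_imaging_traces()].
#' @export
generate_synthetic_traces <- function(truth, n_flies = 8L, noise_sd = 0.1,
                                      seed = 1L) {
  stopifnot(n_flies >= 1, all(c("neuron", "trial", "off", "on") %in% names(truth)))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    base <- numeric(100)
    base[25:43] <- truth$off[i]
    base[44:50] <- truth$on[i]
    do.call(rbind, lapply(seq_len(n_flies), function(f) {
      data.frame(neuron = truth$neuron[i], fly = f, trial = truth$trial[i],
                 sample_index = 1:100,
                 value = base + stats::rnorm(100, 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Write / read trace tables as CSV
#'
#' Plain-CSV round trip for the long trace schema (and any other tidy
#' table); values survive to full double precision.
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_traces_csv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) format(v, digits = 17, trim = TRUE,
                                              scientific = FALSE))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Specify a neuron intervention
#'
#' During the listed trial phases, the target neurons' activities are
#' clamped after each neuron update and before plasticity: to 0 for
#' `"silence"`, to the activation cap for `"activate"`.
#'
#' @param neurons Character vector of neuron labels (DANs or MBONs, see
#'   [neuron_labels()]).
#' @param mode `"silence"` or `"activate"`.
#' @param phases Trial phases during which the clamp applies.
#' @return An object of class `ic_intervention`.
#' @export
#' @examples
#' intervention_spec("s_at", "silence", "acquisition")
intervention_spec <- function(neurons, mode = c("silence", "activate"),
                              phases = "acquisition") {
  mode <- match.arg(mode)
  labels <- neuron_labels()
  unknown <- setdiff(neurons, c(labels$dan, labels$mbon))
  if (length(unknown))
    stop("unknown neuron(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(neurons = neurons, mode = mode, phases = phases),
            class = "ic_intervention")
}

# Clamp targeted activities in place; used by forward_step().
clamp_activities <- function(d, m, intervention, params) {
  value <- if (intervention$mode == "silence") 0 else params$activation_cap
  d[names(d) %in% intervention$neurons] <- value
  m[names(m) %in% intervention$neurons] <- value
  list(d = d, m = m)
}

#' Preference index from MBON responses
#'
#' For each odour, the behavioural score is the mean of the three attraction
#' MBONs minus the mean of the three avoidance MBONs; the preference index
#' is `(score_A - score_B) / (|score_A| + |score_B|)`, or 0 when both
#' scores are 0. Positive values mean odour A is preferred.
#'
#' @param m_A,m_B MBON activity vectors (length 6, label order) recorded
#'   while each odour was presented.
#' @return A single number in `[-1, 1]`.
#' @export
model_preference_from_mbons <- function(m_A, m_B) {
  score <- function(m) mean(m[c(1, 3, 5)]) - mean(m[c(2, 4, 6)])
  sA <- score(m_A)
  sB <- score(m_B)
  if (sA == 0 && sB == 0) return(0)
  (sA - sB) / (abs(sA) + abs(sB))
}

#' Model preference after a conditioning run
#'
#' Reads the MBON responses at the odour-only (off-shock) step of the first
#' test-phase presentation of each odour and converts them to a preference
#' index with [model_preference_from_mbons()].
#'
#' @param log An `ic_experiment_log`.
#' @param phase Phase used as the test readout (default `"extinction"`).
#' @return A single number in `[-1, 1]`.
#' @export
paradigm_preference <- function(log, phase = "extinction") {
  tl <- log$timeline
  iA <- which(tl$phase == phase & tl$odour == "A" & tl$in_trial_step == 2L)[1]
  iB <- which(tl$phase == phase & tl$odour == "B" & tl$in_trial_step == 2L)[1]
  if (is.na(iA) || is.na(iB))
    stop("no test-phase presentation of both odours in this log", call. = FALSE)
  model_preference_from_mbons(log$m[iA, ], log$m[iB, ])
}

#' Run an intervention screen
#'
#' For each row of the screen table, runs a control conditioning experiment
#' and one with the specified neurons clamped, computes the model effect
#' `delta_f = PI(intervention) - PI(control)`, and finally the Pearson
#' correlation between model and experimental effects across rows. Rows
#' with missing experimental values are skipped with a warning; a screen
#' with zero variance in either column yields `r = NA` with a warning.
#'
#' @param screen A data.frame with columns `neuron` (one label or several
#'   separated by `+`), `mode` (`"silence"`/`"activate"`), `phase` (one
#'   phase or several separated by `+`), `us` (`"shock"`/`"sugar"`) and
#'   `delta_f` (experimental effect, signed).
#' @param params An `ic_parameters` object.
#' @param seed Integer seed (shared by control and intervention runs).
#' @param forgetting Forgetting condition of the paradigm used as protocol.
#' @return A list with the per-row `results` data.frame (columns of
#'   `screen` plus `model_delta_f`) and the Pearson correlation `r`.
#' @export
run_intervention_screen <- function(screen, params = default_parameters(),
                                    seed = 1L, forgetting = "extinction") {
  needed <- c("neuron", "mode", "phase", "us", "delta_f")
  if (!all(needed %in% names(screen)))
    stop("screen must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  keep <- !is.na(screen$delta_f)
  if (any(!keep))
    warning(sum(!keep), " row(s) without experimental values skipped")
  screen <- screen[keep, , drop = FALSE]

  controls <- new.env()
  control_pi <- function(us) {
    if (is.null(controls[[us]])) {
      log <- run_experiment(build_aversive_paradigm(forgetting, us = us),
                            params, seed = seed)
      controls[[us]] <- paradigm_preference(log)
    }
    controls[[us]]
  }
  model <- vapply(seq_len(nrow(screen)), function(i) {
    iv <- intervention_spec(strsplit(screen$neuron[i], "\\+")[[1]],
                            screen$mode[i],
                            strsplit(screen$phase[i], "\\+")[[1]])
    log <- run_experiment(build_aversive_paradigm(forgetting, us = screen$us[i]),
                          params, seed = seed, intervention = iv)
    paradigm_preference(log) - control_pi(screen$us[i])
  }, numeric(1))
  results <- cbind(screen, model_delta_f = model)
  r <- if (nrow(screen) >= 2 && stats::sd(model) > 0 && stats::sd(screen$delta_f) > 0) {
    stats::cor(model, screen$delta_f)
  } else {
    warning("correlation undefined (fewer than 2 rows or zero variance)")
    NA_real_
  }
  list(results = results, r = r)
}
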