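#' Parameters of the two-odour arena
#'
#' The arena is an unbounded plane with two Gaussian odour fields. Positions
#' are complex numbers `x + iy` (metres). Odour A's source sits at
#' `mu_A = -0.6`, odour B's at `mu_B = +0.6`; each field is the univariate
#' Gaussian density of the Euclidean distance from the source with spread
#' `sigma`. An odour is detected where its density exceeds `theta_CS`, which
#' makes the detectable radius about 0.58 m; reinforcement is delivered only
#' within `rho_US` = 0.3 m of a reinforced source, during the training
#' window. Each repeat of the experiment lasts 100 steps at 1 Hz: 20 s
#' pre-training, 30 s training (steps 21-50) and 50 s post-training.
#'
#' @param mu_A,mu_B Complex (or real) source positions in metres.
#' @param sigma_A,sigma_B Odour-field spreads in metres.
#' @param theta_CS Detection threshold on the density.
#' @param rho_US Reinforcement radius in metres.
#' @param step_speed Normalised step size in m/s.
#' @param motion_noise_sigma Per-axis Gaussian velocity noise.
#' @param n_flies Number of simulated flies.
#' @param n_repeats Number of repeats of the 100-s experiment; brains persist
#'   across repeats, positions reset to the centre.
#' @param n_steps Steps per repeat at 1 Hz.
#' @param train_window 1-based step indices during which reinforcement can
#'   be delivered.
#' @return An object of class `ic_arena`.
#' @export
arena_parameters <- function(mu_A = -0.6 + 0i, mu_B = 0.6 + 0i,
                             sigma_A = 0.3, sigma_B = 0.3,
                             theta_CS = 0.2, rho_US = 0.3,
                             step_speed = 0.05, motion_noise_sigma = 0.1,
                             n_flies = 100L, n_repeats = 10L, n_steps = 100L,
                             train_window = 21:50) {
  stopifnot(sigma_A > 0, sigma_B > 0, theta_CS > 0, rho_US > 0,
            step_speed > 0, n_flies >= 1, n_repeats >= 1)
  peak <- stats::dnorm(0, sd = min(sigma_A, sigma_B))
  if (theta_CS >= peak)
    stop("theta_CS must be below the peak odour density", call. = FALSE)
  structure(list(
    mu_A = as.complex(mu_A), mu_B = as.complex(mu_B),
    sigma_A = sigma_A, sigma_B = sigma_B,
    theta_CS = theta_CS, rho_US = rho_US,
    step_speed = step_speed, motion_noise_sigma = motion_noise_sigma,
    n_flies = as.integer(n_flies), n_repeats = as.integer(n_repeats),
    n_steps = as.integer(n_steps), train_window = as.integer(train_window)
  ), class = "ic_arena")
}

# univariate Gaussian density of the distance from a source
odour_density <- function(position, mu, sigma) {
  stats::dnorm(Mod(position - mu), mean = 0, sd = sigma)
}

#' Odour detection at a position
#'
#' Evaluates both odour densities at the fly's position and thresholds each
#' at `theta_CS`. The PN code is binary: detection does not scale with
#' intensity.
#'
#' @param position Complex vector of positions.
#' @param arena An `ic_arena` object.
#' @return A matrix with columns `A` and `B` of 0/1 detections, one row per
#'   position.
#' @export
#' @examples
#' arena <- arena_parameters()
#' odour_stimulus(arena$mu_A, arena)   # A detected, B not
odour_stimulus <- function(position, arena = arena_parameters()) {
  cbind(A = as.numeric(odour_density(position, arena$mu_A, arena$sigma_A) > arena$theta_CS),
        B = as.numeric(odour_density(position, arena$mu_B, arena$sigma_B) > arena$theta_CS))
}

#' Detectable radius of an odour field
#'
#' Solves `density(r) = theta_CS` for the distance `r` at which an odour
#' becomes undetectable, using the univariate Gaussian density with the
#' arena's spread. With the defaults (`sigma` = 0.3, `theta_CS` = 0.2) the
#' radius is about 0.58 m.
#'
#' @param arena An `ic_arena` object.
#' @param sigma Odour spread; defaults to the arena's `sigma_A`.
#' @return The detection radius in metres.
#' @export
#' @examples
#' detection_radius(arena_parameters())
detection_radius <- function(arena = arena_parameters(), sigma = arena$sigma_A) {
  f <- function(r) stats::dnorm(r, sd = sigma) - arena$theta_CS
  stats::uniroot(f, lower = 0, upper = 10 * sigma, tol = 1e-12)$root
}

#' Reinforcement at a position
#'
#' During the training window only, returns the condition's US for flies
#' within `rho_US` of a reinforced source; otherwise the zero US.
#'
#' @param position Complex vector of positions.
#' @param arena An `ic_arena` object.
#' @param step 1-based step index within the 100-step repeat.
#' @param condition One of `"shock_a"`, `"shock_b"`, `"shock_ab"`,
#'   `"sugar_a"`, `"sugar_b"`, `"sugar_ab"`.
#' @return A matrix with columns `sugar` and `shock` of 0/1 codes, one row
#'   per position.
#' @export
reinforcement_at <- function(position, arena, step, condition) {
  condition <- match.arg(condition, c("shock_a", "shock_b", "shock_ab",
                                      "sugar_a", "sugar_b", "sugar_ab"))
  n <- length(position)
  us <- matrix(0, n, 2, dimnames = list(NULL, c("sugar", "shock")))
  if (!step %in% arena$train_window) return(us)
  parts <- strsplit(condition, "_")[[1]]
  near <- rep(FALSE, n)
  if (grepl("a", parts[2])) near <- near | Mod(position - arena$mu_A) < arena$rho_US
  if (grepl("b", parts[2])) near <- near | Mod(position - arena$mu_B) < arena$rho_US
  us[near, parts[1]] <- 1
  us
}

#' Posterior probability of being closer to each odour source
#'
#' With equal priors, `P_A = N_A / (N_A + N_B)` from the two Gaussian
#' densities at the position; where both densities underflow to zero the
#' posterior falls back to 0.5/0.5.
#'
#' @param position Complex vector of positions.
#' @param arena An `ic_arena` object.
#' @return A matrix with columns `P_A`, `P_B`.
#' @export
closeness_posterior <- function(position, arena = arena_parameters()) {
  nA <- odour_density(position, arena$mu_A, arena$sigma_A)
  nB <- odour_density(position, arena$mu_B, arena$sigma_B)
  tot <- nA + nB
  pA <- ifelse(tot > 0, nA / tot, 0.5)
  cbind(P_A = pA, P_B = 1 - pA)
}

#' MBON-driven attraction force
#'
#' For each odour, the mean of the three attraction MBONs minus the mean of
#' the three avoidance MBONs scales the unit vector from the fly towards
#' that odour's source; the two odour forces are combined weighted by the
#' closeness posterior. At a source position the unit vector is undefined
#' and that odour's contribution is zero.
#'
#' @param m MBON activity: a vector of length 6 or a matrix with one row
#'   per fly (columns in `neuron_labels()$mbon` order).
#' @param position Complex vector of positions (length = rows of `m`).
#' @param arena An `ic_arena` object.
#' @return A complex vector of forces.
#' @export
attraction_force <- function(m, position, arena = arena_parameters()) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  att <- rowMeans(m[, c(1, 3, 5), drop = FALSE])  # s_at, r_at, m_at
  av  <- rowMeans(m[, c(2, 4, 6), drop = FALSE])  # s_av, r_av, m_av
  unit_to <- function(mu) {
    v <- mu - position
    d <- Mod(v)
    ifelse(d > 0, v / d, 0 + 0i)
  }
  p <- closeness_posterior(position, arena)
  pA <- unname(p[, "P_A"])
  unname(att - av) * (pA * unit_to(arena$mu_A) + (1 - pA) * unit_to(arena$mu_B))
}

#' Velocity update of the simulated flies
#'
#' Adds the attraction force and per-axis Gaussian noise to the previous
#' (executed) velocity, then rescales the result to the fixed step speed so
#' that direction is retained but every moved step has magnitude
#' `step_speed`. A zero pre-normalisation velocity (probability zero under
#' Gaussian noise) triggers a redraw of the noise.
#'
#' @param v_prev Complex vector of previous velocities.
#' @param force Complex vector of attraction forces.
#' @param arena An `ic_arena` object.
#' @return A complex vector of velocities, all of magnitude `step_speed`.
#' @export
velocity_update <- function(v_prev, force, arena = arena_parameters()) {
  n <- length(v_prev)
  sd <- arena$motion_noise_sigma
  v <- v_prev + force + complex(real = stats::rnorm(n, 0, sd),
                                imaginary = stats::rnorm(n, 0, sd))
  while (any(Mod(v) == 0)) {
    i <- which(Mod(v) == 0)
    v[i] <- v_prev[i] + force[i] + complex(real = stats::rnorm(length(i), 0, sd),
                                           imaginary = stats::rnorm(length(i), 0, sd))
  }
  arena$step_speed * v / Mod(v)
}

# ---- batched circuit (one row per fly) ----------------------------------

batch_init <- function(n, params) {
  list(
    d = matrix(0, n, params$n_dan),
    m = matrix(0, n, params$n_mbon),
    W = array(params$w_rest, c(n, params$n_kc, params$n_mbon))
  )
}

batch_kc_response <- function(cs, params) {
  drive <- cs %*% params$W_p2k +
    matrix(stats::rnorm(nrow(cs) * params$n_kc, 0, params$eta_scale),
           nrow(cs), params$n_kc)
  k <- t(apply(drive, 1, wta_fraction_filter, fraction = params$wta_fraction))
  pmax(k, 0)
}

# One time-step (with `repeats` inner repeats) for a batch of brains.
# cs, us: n x 2 matrices. Mirrors forward_step() row-for-row.
batch_forward_step <- function(bs, cs, us, params, rule = "dpr", repeats = 4L) {
  n <- nrow(bs$d)
  cap <- params$activation_cap
  tau <- params$tau
  k <- batch_kc_response(cs, params)
  leaky <- identical(params$integration, "leaky")
  for (r in seq_len(repeats)) {
    drive_d <- us %*% params$W_u2d + bs$m %*% params$W_m2d +
      matrix(params$b_d, n, params$n_dan, byrow = TRUE)
    km <- sapply(seq_len(params$n_mbon), function(j) rowSums(k * bs$W[, , j]))
    if (n == 1L) km <- matrix(km, nrow = 1)
    drive_m <- km + bs$m %*% params$W_m2m +
      matrix(params$b_m, n, params$n_mbon, byrow = TRUE)
    if (leaky) {
      bs$d <- pmin(pmax((1 - 1 / tau) * bs$d + drive_d / tau, 0), cap)
      bs$m <- pmin(pmax((1 - 1 / tau) * bs$m + drive_m / tau, 0), cap)
    } else {
      bs$d <- pmin(pmax(drive_d / tau, 0), cap)
      bs$m <- pmin(pmax(drive_m / tau, 0), cap)
    }
    delta <- bs$d %*% params$W_d2km
    if (identical(rule, "dpr")) {
      for (j in seq_len(params$n_mbon))
        bs$W[, , j] <- pmax(bs$W[, , j] +
          delta[, j] * (k + bs$W[, , j] - params$w_rest) / tau, 0)
    } else {
      for (j in seq_len(params$n_mbon))
        bs$W[, , j] <- pmax(bs$W[, , j] +
          k * (delta[, j] - bs$m[, j] + params$w_rest) / tau, 0)
    }
  }
  bs$k <- k
  bs
}

#' Run the arena behaviour experiment
#'
#' Simulates `n_flies` flies, each with its own incentive-circuit brain, for
#' `n_repeats` repeats of the 100-step (1 Hz) experiment. Within each step a
#' fly senses the odours at its position, receives reinforcement if inside
#' the reinforced area during training, updates its brain with one circuit
#' time-step, converts MBON output to an attraction force, and moves at the
#' fixed step speed. Positions and velocities reset to the centre between
#' repeats; brains persist, so long-term memory accumulates across repeats.
#'
#' @param condition Training condition, e.g. `"shock_a"` (see
#'   [reinforcement_at()]).
#' @param arena An `ic_arena` object.
#' @param params An `ic_parameters` object.
#' @param rule `"dpr"` or `"rpe"`.
#' @param seed Integer seed.
#' @return An object of class `ic_behaviour_log`: arrays `pos`, `det_A`,
#'   `det_B`, `us_on` of shape (fly, step, repeat), the `phase` vector of
#'   step labels, the condition and arena, and the final brain batch.
#' @export
run_arena_experiment <- function(condition, arena = arena_parameters(),
                                 params = default_parameters(), rule = "dpr",
                                 seed = 1L) {
  set.seed(seed)
  n <- arena$n_flies
  n_steps <- arena$n_steps
  phase <- rep("post", n_steps)
  phase[seq_len(min(arena$train_window) - 1L)] <- "pre"
  phase[arena$train_window] <- "train"

  dims <- c(n, n_steps, arena$n_repeats)
  pos_log <- array(complex(real = NA_real_), dims)
  det_A <- array(NA, dims); det_B <- array(NA, dims); us_on <- array(NA, dims)
  brains <- batch_init(n, params)

  for (rep_i in seq_len(arena$n_repeats)) {
    pos <- rep(0 + 0i, n)
    v <- rep(0 + 0i, n)
    for (s in seq_len(n_steps)) {
      cs <- odour_stimulus(pos, arena)
      us <- reinforcement_at(pos, arena, s, condition)
      pos_log[, s, rep_i] <- pos
      det_A[, s, rep_i] <- cs[, "A"] > 0
      det_B[, s, rep_i] <- cs[, "B"] > 0
      us_on[, s, rep_i] <- rowSums(us) > 0
      brains <- batch_forward_step(brains, cs, us, params, rule = rule)
      force <- attraction_force(brains$m, pos, arena)
      v <- velocity_update(v, force, arena)
      pos <- pos + v
    }
  }
  structure(list(pos = pos_log, det_A = det_A, det_B = det_B, us_on = us_on,
                 phase = phase, condition = condition, arena = arena,
                 rule = rule, seed = seed, brains = brains),
            class = "ic_behaviour_log")
}

#' @export
print.ic_behaviour_log <- function(x, ...) {
  cat(sprintf("Arena behaviour log: %d flies x %d steps x %d repeats, condition %s, rule %s\n",
              dim(x$pos)[1], dim(x$pos)[2], dim(x$pos)[3], x$condition, x$rule))
  invisible(x)
}

#' Normalised cumulative odour exposure
#'
#' Sums, over repeats 1..R, the fraction of the phase's steps during which
#' each fly detected the odour. The value for one repeat lies in [0, 1], so
#' the cumulative value after R repeats lies in [0, R].
#'
#' @param log An `ic_behaviour_log`.
#' @param odour `"A"` or `"B"`.
#' @param phase `"pre"`, `"train"` or `"post"`.
#' @param up_to_repeat Last repeat included (default: all).
#' @return A numeric vector of per-fly cumulative exposures.
#' @export
cumulative_exposure <- function(log, odour = c("A", "B"),
                                phase = c("post", "pre", "train"),
                                up_to_repeat = dim(log$pos)[3]) {
  odour <- match.arg(odour)
  phase <- match.arg(phase)
  det <- if (odour == "A") log$det_A else log$det_B
  steps <- which(log$phase == phase)
  reps <- seq_len(up_to_repeat)
  counts <- apply(det[, steps, reps, drop = FALSE], c(1, 3), sum)
  rowSums(counts) / length(steps)
}

#' Preference index from cumulative exposures
#'
#' `PI = (C_A - C_B) / (C_A + C_B)`; flies with zero total exposure have an
#' undefined PI and are returned as `NA` so they can be excluded from
#' population summaries.
#'
#' @param C_A,C_B Numeric vectors of cumulative exposures.
#' @return A numeric vector in `[-1, 1]` with `NA` where undefined.
#' @export
#' @examples
#' preference_index(0.2, 0.6)
preference_index <- function(C_A, C_B) {
  stopifnot(all(C_A + C_B >= 0))
  ifelse(C_A + C_B > 0, (C_A - C_B) / (C_A + C_B), NA_real_)
}

#' Flies that visited both odours
#'
#' Returns the indices of flies that detected each odour for at least one
#' step over the whole experiment; population summaries are restricted to
#' these flies.
#'
#' @param log An `ic_behaviour_log`.
#' @return An integer vector of fly indices.
#' @export
filter_both_odour_visitors <- function(log) {
  a <- apply(log$det_A, 1, any)
  b <- apply(log$det_B, 1, any)
  which(a & b)
}

#' Per-fly preference summary of an arena run
#'
#' Convenience wrapper combining [cumulative_exposure()],
#' [preference_index()] and [filter_both_odour_visitors()].
#'
#' @param log An `ic_behaviour_log`.
#' @param phase Phase to summarise (default `"post"`).
#' @param up_to_repeat Last repeat included (default: all).
#' @return A data.frame with columns `fly`, `C_A`, `C_B`, `PI`,
#'   `visited_both`.
#' @export
arena_preference <- function(log, phase = "post", up_to_repeat = dim(log$pos)[3]) {
  C_A <- cumulative_exposure(log, "A", phase, up_to_repeat)
  C_B <- cumulative_exposure(log, "B", phase, up_to_repeat)
  data.frame(fly = seq_along(C_A), C_A = C_A, C_B = C_B,
             PI = preference_index(C_A, C_B),
             visited_both = seq_along(C_A) %in% filter_both_odour_visitors(log))
}

#' Tidy trajectory export of an arena run
#'
#' @param x An `ic_behaviour_log`.
#' @param ... Unused.
#' @return A data.frame with columns `fly`, `repeat_i`, `step`, `phase`,
#'   `x`, `y`, `detected_A`, `detected_B`, `us`.
#' @export
as.data.frame.ic_behaviour_log <- function(x, ...) {
  d <- dim(x$pos)
  grid <- expand.grid(fly = seq_len(d[1]), step = seq_len(d[2]),
                      repeat_i = seq_len(d[3]))
  data.frame(
    fly = grid$fly, repeat_i = grid$repeat_i, step = grid$step,
    phase = x$phase[grid$step],
    x = Re(as.vector(x$pos)), y = Im(as.vector(x$pos)),
    detected_A = as.vector(x$det_A), detected_B = as.vector(x$det_B),
    us = as.vector(x$us_on)
  )
}
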