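#' Static dopaminergic factor
#'
#' Maps instantaneous DAN activity to the signed per-MBON dopaminergic
#' effect, `delta = d . W_d2km`. Negative components drive depression (with
#' KC activity) or recovery towards the resting weight (without); positive
#' components drive potentiation or saturation away from rest.
#'
#' @param d Numeric vector of DAN activities (length `n_dan`), or a matrix
#'   with one row per agent.
#' @param W_d2km The DAN function matrix (`n_dan` x `n_mbon`).
#' @return Numeric vector (or matrix) of per-MBON dopaminergic factors.
#' @export
#' @examples
#' p <- default_parameters()
#' d <- c(d_at = 0, d_av = 1, c_at = 0, c_av = 0, f_at = 0, f_av = 0)
#' dopaminergic_factor_static(d, p$W_d2km)  # depresses s_at only
dopaminergic_factor_static <- function(d, W_d2km) {
  if (is.matrix(d)) d %*% W_d2km else as.numeric(d %*% W_d2km)[drop = TRUE]
}

#' Dopaminergic plasticity rule (DPR) update
#'
#' One discrete update of the KC->MBON weights:
#' `dW[i,j] = delta[j] * (k[i] + W[i,j] - w_rest) / tau`, followed by a
#' clamp at zero. Depending on the sign of `delta` and the presence of KC
#' activity this produces four effects: depression, potentiation, recovery
#' (drift back to `w_rest`) and saturation (drift away from it).
#'
#' @param W_k2m Weight matrix (`n_kc` x `n_mbon`), non-negative.
#' @param k KC activity vector (length `n_kc`).
#' @param delta Dopaminergic factor vector (length `n_mbon`).
#' @param params An `ic_parameters` object (uses `tau`, `w_rest`).
#' @return The updated non-negative weight matrix.
#' @export
dpr_update <- function(W_k2m, k, delta, params = default_parameters()) {
  dW <- sweep(sweep(W_k2m - params$w_rest, 1, k, `+`), 2, delta, `*`) / params$tau
  pmax(W_k2m + dW, 0)
}

#' Reward-prediction-error (RPE) update
#'
#' Drop-in alternative to [dpr_update()] in which learning is gated by KC
#' activity and proportional to the difference between the dopaminergic
#' factor and the MBON's current output:
#' `dW[i,j] = k[i] * (delta[j] - m[j] + w_rest) / tau`, with the same
#' non-negativity clamp. Without KC activity no learning occurs, and during
#' odour-only presentations weights relax towards the point where the MBON
#' "prediction" matches the (absent) reinforcement.
#'
#' @inheritParams dpr_update
#' @param m MBON activity vector (length `n_mbon`).
#' @return The updated non-negative weight matrix.
#' @export
rpe_update <- function(W_k2m, k, delta, m, params = default_parameters()) {
  dW <- outer(k, delta - m + params$w_rest) / params$tau
  pmax(W_k2m + dW, 0)
}

# Resolve a rule name or function to a common signature
# (W, k, delta, m, params) -> W'
plasticity_rule <- function(rule) {
  if (is.function(rule)) return(rule)
  switch(match.arg(rule, c("dpr", "rpe")),
    dpr = function(W, k, delta, m, params) dpr_update(W, k, delta, params),
    rpe = function(W, k, delta, m, params) rpe_update(W, k, delta, m, params)
  )
}

#' Validate dopamine-kinetics time constants
#'
#' The short and long decay constants of the two dopamine components must
#' satisfy `0 < 1/tau_short + 1/tau_long <= 2` for the discrete dynamics to
#' be stable. `tau_long = Inf` is the sentinel for `1/tau_long = 0`.
#'
#' @param tau_short,tau_long Decay constants in samples.
#' @return `TRUE`, invisibly, if valid; otherwise an error naming the
#'   constraint.
#' @export
#' @examples
#' validate_time_constants(60, 100)
#' validate_time_constants(1, Inf)
validate_time_constants <- function(tau_short, tau_long) {
  s <- 1 / tau_short + 1 / tau_long
  if (!(s > 0 && s <= 2))
    stop("time constants must satisfy 0 < 1/tau_short + 1/tau_long <= 2 ",
         sprintf("(got %g)", s), call. = FALSE)
  invisible(TRUE)
}

#' Time-resolved decomposition of the dopaminergic factor
#'
#' Splits the dopaminergic effect into a depression component `D_dep` and a
#' potentiation component `D_pot` with distinct kinetics, abstracting the two
#' dopamine-receptor pathways. The DAN function matrix is split by sign:
#' `W_pos` carries the potentiating/saturating effects and `W_neg` the
#' magnitudes of the depressing/recovering ones, so
#' `W_pos - W_neg` reconstructs `W_d2km` exactly. Each of the four
#' channel x component pairs is a first-order low-pass filter: the
#' depressing channel feeds `D_dep` through the *short* (fast, high-peak)
#' constant and `D_pot` through the *long* (slow, low-peak) one, and
#' vice versa for the potentiating channel. With `tau_short = 1`,
#' `tau_long = Inf` the filters collapse and `D_pot - D_dep` equals the
#' static factor `d . W_d2km` at every sample.
#'
#' @param W_d2km DAN function matrix (`n_dan` x `n_mbon`).
#' @param tau_short,tau_long Decay constants in samples; must pass
#'   [validate_time_constants()].
#' @return An object of class `ic_kinetics` holding the channel filter
#'   states and the split matrices.
#' @export
dopamine_kinetics <- function(W_d2km, tau_short = 60, tau_long = 100) {
  validate_time_constants(tau_short, tau_long)
  n_mbon <- ncol(W_d2km)
  z <- stats::setNames(numeric(n_mbon), colnames(W_d2km))
  structure(list(
    W_pos = pmax(W_d2km, 0),
    W_neg = pmax(-W_d2km, 0),
    tau_short = tau_short, tau_long = tau_long,
    # filter states: <input channel>_<time constant>
    neg_short = z, neg_long = z, pos_short = z, pos_long = z
  ), class = "ic_kinetics")
}

#' Advance the dopamine kinetics by one sample
#'
#' Applies one low-pass step `y <- y + (x - y)/tau` to each of the four
#' channel states, with `x` the instantaneous DAN input through the
#' corresponding sign-split matrix. The depression component is
#' `D_dep = neg_short + pos_long` and the potentiation component
#' `D_pot = pos_short + neg_long`, so a depressing-only terminal yields a
#' `D_dep` with a higher peak and faster decay than its `D_pot`.
#'
#' @param kin An `ic_kinetics` object.
#' @param d Numeric vector of DAN activities (length `n_dan`).
#' @return The updated `ic_kinetics` object.
#' @export
kinetics_step <- function(kin, d) {
  x_pos <- as.numeric(d %*% kin$W_pos)
  x_neg <- as.numeric(d %*% kin$W_neg)
  a_s <- 1 / kin$tau_short
  a_l <- 1 / kin$tau_long  # Inf sentinel -> 0: channel stays at rest
  kin$neg_short <- kin$neg_short + a_s * (x_neg - kin$neg_short)
  kin$pos_short <- kin$pos_short + a_s * (x_pos - kin$pos_short)
  kin$neg_long  <- kin$neg_long  + a_l * (x_neg - kin$neg_long)
  kin$pos_long  <- kin$pos_long  + a_l * (x_pos - kin$pos_long)
  kin
}

#' Dopamine components and factor of a kinetics state
#'
#' @param kin An `ic_kinetics` object.
#' @return A list with vectors `D_dep`, `D_pot` and `delta = D_pot - D_dep`.
#' @export
kinetics_components <- function(kin) {
  D_dep <- kin$neg_short + kin$pos_long
  D_pot <- kin$pos_short + kin$neg_long
  list(D_dep = D_dep, D_pot = D_pot, delta = D_pot - D_dep)
}
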