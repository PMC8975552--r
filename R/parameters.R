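#' Neuron labels of the incentive circuit
#'
#' The circuit contains six dopaminergic neurons (DANs) and six mushroom body
#' output neurons (MBONs), organised as attraction/avoidance pairs of three
#' functional types: discharging (`d_`) and charging (`c_`) and forgetting
#' (`f_`) DANs; susceptible (`s_`), restrained (`r_`) and long-term-memory
#' (`m_`) MBONs. The ordering of these labels fixes the axis order of every
#' matrix and activity vector in the package and is part of the public
#' contract.
#'
#' @return A list with character vectors `dan` and `mbon`.
#' @export
#' @examples
#' neuron_labels()$dan
neuron_labels <- function() {
  list(
    dan  = c("d_at", "d_av", "c_at", "c_av", "f_at", "f_av"),
    mbon = c("s_at", "s_av", "r_at", "r_av", "m_at", "m_av")
  )
}

#' Default parameter set of the incentive circuit
#'
#' Returns the fixed connectivity, biases and constants of the model. None of
#' these values is fitted at run time: odour identity reaches 10 Kenyon cells
#' (KCs) through 2 projection neurons (PNs) with weight 0.8 (4 KCs respond
#' only to odour A, 3 only to B and 3 to both); reward excites the attraction
#' discharging and charging DANs and punishment their avoidance counterparts
#' (weight 2); MBON->DAN and MBON->MBON connections implement the reciprocal
#' microcircuits (susceptible MBONs inhibit opposite discharging DANs and
#' opposite restrained MBONs; restrained and LTM MBONs excite same-valence
#' charging and forgetting DANs); and the DAN function matrix `W_d2km` maps
#' DAN activity to the signed dopaminergic effect on each MBON's KC synapses.
#'
#' @param integration Either `"literal"` (default), in which a neuron's new
#'   activity is the bounded-rectified drive divided by `tau`, or `"leaky"`,
#'   the standard leaky-integrator discretisation that retains a
#'   `(1 - 1/tau)` fraction of the previous activity. See the package
#'   vignette for why both are offered.
#' @return An object of class `ic_parameters`: a list with matrices `W_p2k`,
#'   `W_u2d`, `W_m2d`, `W_m2m`, `W_d2km`, bias vectors `b_d`, `b_m`, and
#'   scalars `n_pn`, `n_kc`, `n_dan`, `n_mbon`, `tau`, `w_rest`, `eta_scale`,
#'   `wta_fraction`, `activation_cap`, plus the `neuron_labels`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$W_p2k[1, ]          # odour-A drive to the 10 KCs
#' p$b_m                 # MBON biases
default_parameters <- function(integration = c("literal", "leaky")) {
  integration <- match.arg(integration)
  labels <- neuron_labels()

  W_p2k <- rbind(
    A = c(rep(0.8, 7), rep(0, 3)),
    B = c(rep(0, 4), rep(0.8, 6))
  )
  colnames(W_p2k) <- paste0("k", 1:10)

  W_u2d <- rbind(
    sugar = c(2, 0, 2, 0, 0, 0),
    shock = c(0, 2, 0, 2, 0, 0)
  )
  colnames(W_u2d) <- labels$dan

  # rows: presynaptic MBON; cols: postsynaptic DAN
  W_m2d <- rbind(
    s_at = c(0, -0.3, 0,   0,   0,   0),
    s_av = c(-0.3, 0, 0,   0,   0,   0),
    r_at = c(0,  0,   0.5, 0,   0,   0),
    r_av = c(0,  0,   0,   0.5, 0,   0),
    m_at = c(0,  0,   0.3, 0,   0.5, 0),
    m_av = c(0,  0,   0,   0.3, 0,   0.5)
  )
  colnames(W_m2d) <- labels$dan

  # rows: presynaptic MBON; cols: postsynaptic MBON
  W_m2m <- matrix(0, 6, 6, dimnames = list(labels$mbon, labels$mbon))
  W_m2m["s_at", "r_av"] <- -1
  W_m2m["s_av", "r_at"] <- -1

  # rows: DAN; cols: MBON whose KC synapses the DAN modulates
  W_d2km <- rbind(
    d_at = c(0, -1,  0,    0,    0,    0),
    d_av = c(-1, 0,  0,    0,    0,    0),
    c_at = c(0,  0,  0,   -1,    0.3,  0),
    c_av = c(0,  0, -1,    0,    0,    0.3),
    f_at = c(0,  0, -0.3,  0,    0,   -1),
    f_av = c(0,  0,  0,   -0.3, -1,    0)
  )
  colnames(W_d2km) <- labels$mbon

  b_d <- c(-0.5, -0.5, -0.15, -0.15, -0.15, -0.15)
  names(b_d) <- labels$dan
  b_m <- c(-2, -2, -0.5, -0.5, -0.5, -0.5)
  names(b_m) <- labels$mbon

  params <- list(
    n_pn = 2L, n_kc = 10L, n_dan = 6L, n_mbon = 6L,
    W_p2k = W_p2k, W_u2d = W_u2d, W_m2d = W_m2d, W_m2m = W_m2m,
    W_d2km = W_d2km, b_d = b_d, b_m = b_m,
    tau = 3, w_rest = 1, eta_scale = 0.001,
    wta_fraction = 0.5, activation_cap = 2,
    integration = integration,
    neuron_labels = labels
  )
  class(params) <- "ic_parameters"
  validate_parameters(params)
  params
}

#' Validate a circuit parameter set
#'
#' Checks shape consistency of all matrices against the neuron counts and the
#' basic constraints `w_rest > 0`, `tau >= 1`, `0 < wta_fraction <= 1`,
#' `activation_cap > 0`.
#'
#' @param params An `ic_parameters` object.
#' @return `params`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "ic_parameters"))
  with(params, {
    if (!identical(dim(W_p2k), c(as.integer(n_pn), as.integer(n_kc))))
      stop("W_p2k must be n_pn x n_kc", call. = FALSE)
    if (!identical(dim(W_u2d), c(2L, as.integer(n_dan))))
      stop("W_u2d must be 2 x n_dan", call. = FALSE)
    if (!identical(dim(W_m2d), c(as.integer(n_mbon), as.integer(n_dan))))
      stop("W_m2d must be n_mbon x n_dan", call. = FALSE)
    if (!identical(dim(W_m2m), c(as.integer(n_mbon), as.integer(n_mbon))))
      stop("W_m2m must be n_mbon x n_mbon", call. = FALSE)
    if (!identical(dim(W_d2km), c(as.integer(n_dan), as.integer(n_mbon))))
      stop("W_d2km must be n_dan x n_mbon", call. = FALSE)
    if (length(b_d) != n_dan || length(b_m) != n_mbon)
      stop("bias vectors must match neuron counts", call. = FALSE)
    if (w_rest <= 0) stop("w_rest must be positive", call. = FALSE)
    if (tau < 1) stop("tau must be >= 1", call. = FALSE)
    if (wta_fraction <= 0 || wta_fraction > 1)
      stop("wta_fraction must be in (0, 1]", call. = FALSE)
    if (activation_cap <= 0) stop("activation_cap must be positive", call. = FALSE)
  })
  invisible(params)
}

#' @export
print.ic_parameters <- function(x, ...) {
  cat("Incentive-circuit parameters:",
      sprintf("%d PNs -> %d KCs -> %d MBONs; %d DANs", x$n_pn, x$n_kc,
              x$n_mbon, x$n_dan), "\n")
  cat(sprintf("tau = %g, w_rest = %g, activation cap = %g, WTA fraction = %g, integration = %s\n",
              x$tau, x$w_rest, x$activation_cap, x$wta_fraction, x$integration))
  invisible(x)
}

#' Bounded rectified-linear activation
#'
#' Element-wise activation used for DANs and MBONs: negative drive is clamped
#' to 0 and the output saturates at `cap`. Saturation prevents activity from
#' exploding while the self-sustaining long-term-memory MBONs charge.
#'
#' @param x Numeric vector or matrix.
#' @param cap Upper bound (default 2).
#' @return Same shape as `x`, values in `[0, cap]`.
#' @export
#' @examples
#' bounded_relu(c(-1, 1, 5))
bounded_relu <- function(x, cap = 2) {
  pmin(pmax(x, 0), cap)
}

#' Winner-take-all fraction filter over Kenyon cells
#'
#' Retains the top `ceiling(fraction * length(x))` entries of `x` (by value,
#' ties broken towards the lowest index via a stable sort) and zeroes the
#' rest. Retained entries keep their input magnitude; the filter performs
#' sparsification, not binarisation.
#'
#' @param x Numeric vector of KC drives.
#' @param fraction Fraction of entries kept active (default 0.5).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' wta_fraction_filter(1:10)            # keeps 6..10
#' wta_fraction_filter(rep(0.8, 10))    # tie: keeps the first five
wta_fraction_filter <- function(x, fraction = 0.5) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n_keep <- as.integer(ceiling(fraction * length(x)))
  keep <- order(x, decreasing = TRUE)[seq_len(n_keep)]  # stable: lowest index wins ties
  out <- numeric(length(x))
  out[keep] <- x[keep]
  out
}

#' Write circuit parameters to a YAML config file
#'
#' Matrices are stored row-wise as nested lists under keys mirroring the
#' field names, so a config can be edited by hand and read back with
#' [read_parameters()].
#'
#' @param params An `ic_parameters` object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  mat2list <- function(m) apply(unname(m), 1, as.numeric, simplify = FALSE)
  cfg <- list(
    n_pn = params$n_pn, n_kc = params$n_kc,
    n_dan = params$n_dan, n_mbon = params$n_mbon,
    W_p2k = mat2list(params$W_p2k), W_u2d = mat2list(params$W_u2d),
    W_m2d = mat2list(params$W_m2d), W_m2m = mat2list(params$W_m2m),
    W_d2km = mat2list(params$W_d2km),
    b_d = as.numeric(params$b_d), b_m = as.numeric(params$b_m),
    tau = params$tau, w_rest = params$w_rest,
    eta_scale = params$eta_scale, wta_fraction = params$wta_fraction,
    activation_cap = params$activation_cap,
    integration = params$integration
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read circuit parameters from a YAML config file
#'
#' @param path File written by [write_parameters()] (or hand-edited with the
#'   same keys).
#' @return An `ic_parameters` object.
#' @export
read_parameters <- function(path) {
  cfg <- yaml::read_yaml(path)
  labels <- neuron_labels()
  list2mat <- function(l, rn, cn) {
    m <- do.call(rbind, lapply(l, as.numeric))
    dimnames(m) <- list(rn, cn)
    m
  }
  kc_names <- paste0("k", seq_len(cfg$n_kc))
  params <- list(
    n_pn = as.integer(cfg$n_pn), n_kc = as.integer(cfg$n_kc),
    n_dan = as.integer(cfg$n_dan), n_mbon = as.integer(cfg$n_mbon),
    W_p2k = list2mat(cfg$W_p2k, c("A", "B"), kc_names),
    W_u2d = list2mat(cfg$W_u2d, c("sugar", "shock"), labels$dan),
    W_m2d = list2mat(cfg$W_m2d, labels$mbon, labels$dan),
    W_m2m = list2mat(cfg$W_m2m, labels$mbon, labels$mbon),
    W_d2km = list2mat(cfg$W_d2km, labels$dan, labels$mbon),
    b_d = stats::setNames(as.numeric(cfg$b_d), labels$dan),
    b_m = stats::setNames(as.numeric(cfg$b_m), labels$mbon),
    tau = cfg$tau, w_rest = cfg$w_rest, eta_scale = cfg$eta_scale,
    wta_fraction = cfg$wta_fraction, activation_cap = cfg$activation_cap,
    integration = if (is.null(cfg$integration)) "literal" else cfg$integration,
    neuron_labels = labels
  )
  class(params) <- "ic_parameters"
  validate_parameters(params)
  params
}
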