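# Independent oracles, written straight-line so they share no code path with
# the implementation they check.

# Winner-take-all by explicit stable sort of (value, index) pairs.
oracle_wta <- function(x, fraction = 0.5) {
  n_keep <- ceiling(fraction * length(x))
  ord <- order(-x, seq_along(x))  # stable: lowest index wins ties
  out <- numeric(length(x))
  for (i in seq_len(n_keep)) out[ord[i]] <- x[ord[i]]
  out
}

# One DAN/MBON update written as explicit scalar loops over the printed
# drive terms, literal composition.
oracle_neuron_step <- function(k, m, d, W_k2m, us, params) {
  nd <- params$n_dan
  nm <- params$n_mbon
  d_new <- numeric(nd)
  for (j in seq_len(nd)) {
    drive <- params$b_d[[j]]
    for (u in 1:2) drive <- drive + us[u] * params$W_u2d[u, j]
    for (i in seq_len(nm)) drive <- drive + m[i] * params$W_m2d[i, j]
    d_new[j] <- min(max(drive / params$tau, 0), params$activation_cap)
  }
  m_new <- numeric(nm)
  for (j in seq_len(nm)) {
    drive <- params$b_m[[j]]
    for (i in seq_len(params$n_kc)) drive <- drive + k[i] * W_k2m[i, j]
    for (i in seq_len(nm)) drive <- drive + m[i] * params$W_m2m[i, j]
    m_new[j] <- min(max(drive / params$tau, 0), params$activation_cap)
  }
  list(d = d_new, m = m_new)
}

# A random (valid) circuit state under the default shapes.
random_state <- function(params) {
  s <- initial_state(params)
  s$k <- runif(params$n_kc, 0, 1)
  s$d <- stats::setNames(runif(params$n_dan, 0, params$activation_cap),
                         params$neuron_labels$dan)
  s$m <- stats::setNames(runif(params$n_mbon, 0, params$activation_cap),
                         params$neuron_labels$mbon)
  s$W_k2m[] <- runif(params$n_kc * params$n_mbon, 0, 2)
  s
}

# A small ground-truth table for the synthetic imaging traces.
example_truth <- function() {
  data.frame(neuron = c("s_at", "s_at", "r_av"), trial = c(1, 2, 1),
             off = c(0.8, 0.3, 0.5), on = c(0.6, 0.1, 1.2),
             stringsAsFactors = FALSE)
}
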