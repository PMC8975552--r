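test_that("trace summariser uses the printed windows", {
  # constant trace: off mean = on mean = c, sd = 0
  traces <- data.frame(neuron = "s_at", fly = rep(1:3, each = 100), trial = 1,
                       sample_index = rep(1:100, 3), value = 0.42)
  s <- summarise_imaging_traces(traces)
  expect_equal(s$off_mean, 0.42)
  expect_equal(s$on_mean, 0.42)
  expect_equal(s$off_sd, 0)
  expect_equal(s$n_flies, 3L)
  # window sizes: 15 off-shock and 5 on-shock samples per fly
  traces$value <- 0
  traces$value[traces$sample_index %in% 28:42] <- 1
  s <- summarise_imaging_traces(traces)
  expect_equal(s$off_mean, 1)
  expect_equal(s$on_mean, 0)
  traces$value <- as.numeric(traces$sample_index %in% 44:48)
  s <- summarise_imaging_traces(traces)
  expect_equal(s$on_mean, 1)
  expect_equal(s$off_mean, 0)
  # malformed length is rejected
  expect_error(summarise_imaging_traces(traces[traces$sample_index <= 99, ]),
               "100 samples")
})

test_that("summaries are invariant to fly and trial ordering", {
  truth <- example_truth()
  traces <- generate_synthetic_traces(truth, n_flies = 5, noise_sd = 0.2,
                                      seed = 3)
  shuffled <- traces[sample(nrow(traces)), ]
  a <- summarise_imaging_traces(traces)
  b <- summarise_imaging_traces(shuffled)
  b <- b[match(paste(a$neuron, a$trial), paste(b$neuron, b$trial)), ]
  expect_equal(a$off_mean, b$off_mean)
  expect_equal(a$on_sd, b$on_sd)
})

test_that("synthetic traces round-trip through the summariser", {
  truth <- example_truth()
  # noiseless: exact recovery of the ground-truth window means
  clean <- summarise_imaging_traces(
    generate_synthetic_traces(truth, n_flies = 4, noise_sd = 0, seed = 1))
  key <- paste(clean$neuron, clean$trial)
  want <- paste(truth$neuron, truth$trial)
  expect_equal(clean$off_mean[match(want, key)], truth$off)
  expect_equal(clean$on_mean[match(want, key)], truth$on)
  # noisy: recovery within 3 standard errors of the pooled window mean
  noisy <- summarise_imaging_traces(
    generate_synthetic_traces(truth, n_flies = 50, noise_sd = 0.1, seed = 2))
  se_off <- 0.1 / sqrt(50 * 15)
  expect_true(all(abs(noisy$off_mean[match(want, key)] - truth$off) <
                    3 * se_off))
  # identical seed, identical output
  a <- generate_synthetic_traces(truth, n_flies = 3, noise_sd = 0.1, seed = 7)
  b <- generate_synthetic_traces(truth, n_flies = 3, noise_sd = 0.1, seed = 7)
  expect_identical(a, b)
})

test_that("trace CSV round trip is lossless", {
  truth <- example_truth()
  traces <- generate_synthetic_traces(truth, n_flies = 2, noise_sd = 0.3,
                                      seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(traces, path)
  back <- read_traces_csv(path)
  expect_equal(back$value, traces$value, tolerance = 1e-12)
  expect_equal(back$neuron, traces$neuron)
  expect_equal(back$sample_index, traces$sample_index)
})

test_that("interventions clamp the right neurons at the right phases", {
  expect_error(intervention_spec("nope", "silence"), "unknown neuron")
  p <- default_parameters()
  sched <- build_aversive_paradigm("extinction")
  base <- run_experiment(sched, p, seed = 2)
  # a no-op intervention (valid target, phase that never occurs) is identity
  noop <- run_experiment(sched, p, seed = 2,
                         intervention = intervention_spec("s_at", "silence",
                                                          phases = "never"))
  expect_identical(noop$m, base$m)
  expect_identical(noop$W, base$W)
  # silencing s_at during acquisition zeroes its logged activity there
  iv <- intervention_spec("s_at", "silence", "acquisition")
  sil <- run_experiment(sched, p, seed = 2, intervention = iv)
  acq <- sil$timeline$phase == "acquisition"
  expect_true(all(sil$m[acq, "s_at"] == 0))
  expect_true(any(base$m[acq, "s_at"] > 0))
  # outside the clamped phase, dynamics resume (no hidden state leak):
  # the clamp is released from the first resting step onwards
  rest <- sil$timeline$phase == "resting"
  expect_gt(max(sil$m[rest, "s_at"]), 0)
})

test_that("DAN-driven plasticity persists when MBONs are silenced", {
  p <- default_parameters()
  sched <- build_aversive_paradigm("extinction")
  iv <- intervention_spec(neuron_labels()$mbon, "silence", "acquisition")
  sil <- run_experiment(sched, p, seed = 2, intervention = iv)
  # aversive learning still depresses the s_at weights for odour-B KCs:
  # DANs, not MBONs, gate the dopaminergic factor
  end_acq <- max(which(sil$timeline$phase == "acquisition"))
  expect_lt(mean(sil$W[end_acq, 8:10, 1]), 0.6)
})

test_that("activating an avoidance DAN without a US depresses s_at synapses", {
  p <- default_parameters()
  sched <- build_aversive_paradigm("extinction")
  sched$us_step[] <- 0L  # no US anywhere
  sched$us[] <- "none"
  iv <- intervention_spec("d_av", "activate",
                          phases = c("pre_training", "acquisition"))
  act <- run_experiment(sched, p, seed = 2, intervention = iv)
  base <- run_experiment(sched, p, seed = 2)
  end_acq <- max(which(act$timeline$phase == "acquisition"))
  expect_lt(mean(act$W[end_acq, , 1]), mean(base$W[end_acq, , 1]))
})

test_that("MBON preference index respects its sign convention", {
  labels <- neuron_labels()$mbon
  m <- stats::setNames(rep(0.5, 6), labels)
  expect_equal(model_preference_from_mbons(m, m), 0)
  expect_equal(model_preference_from_mbons(numeric(6), numeric(6)), 0)
  # avoidance dominant for B only: A is preferred
  m_B <- stats::setNames(c(0, 1, 0, 1, 0, 1), labels)
  expect_gt(model_preference_from_mbons(m, m_B), 0)
  # attraction dominant for B only: B is preferred
  m_B2 <- stats::setNames(c(1, 0, 1, 0, 1, 0), labels)
  expect_lt(model_preference_from_mbons(m, m_B2), 0)
})

test_that("the intervention screen recovers agreement and flags degeneracy", {
  p <- default_parameters()
  screen <- data.frame(
    neuron = c("s_at", "d_av", "c_av"),
    mode = c("silence", "silence", "activate"),
    phase = "acquisition",
    us = "shock",
    delta_f = NA_real_, stringsAsFactors = FALSE)
  # rows without experimental values are skipped with a warning (and the
  # emptied screen then has no defined correlation)
  expect_warning(
    expect_warning(run_intervention_screen(screen, p, seed = 3), "skipped"),
    "undefined")
  # first pass computes the model effects; feed them back as "experimental"
  # values: a screen in perfect agreement must give r = 1
  screen$delta_f <- {
    tmp <- screen; tmp$delta_f <- 0
    suppressWarnings(run_intervention_screen(tmp, p, seed = 3))$results$model_delta_f
  }
  expect_gt(stats::sd(screen$delta_f), 0)
  out <- run_intervention_screen(screen, p, seed = 3)
  expect_equal(out$r, 1, tolerance = 1e-9)
  expect_equal(nrow(out$results), 3L)
  # anti-correlated experimental values give r = -1
  flipped <- screen
  flipped$delta_f <- -screen$delta_f
  expect_equal(run_intervention_screen(flipped, p, seed = 3)$r, -1,
               tolerance = 1e-9)
  # zero-variance experimental column: r undefined, with a warning
  const <- screen
  const$delta_f <- 0.5
  expect_warning(out <- run_intervention_screen(const, p, seed = 3),
                 "undefined|variance")
  expect_true(is.na(out$r))
})
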