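test_that("odour detection thresholds the Gaussian density", {
  arena <- arena_parameters()
  # at the source the density is the Gaussian peak 1/(sigma*sqrt(2*pi))
  expect_equal(odour_stimulus(arena$mu_A, arena)[1, ], c(A = 1, B = 0))
  expect_equal(odour_stimulus(arena$mu_B, arena)[1, ], c(A = 0, B = 1))
  # far away, nothing is detected
  expect_equal(odour_stimulus(10 + 10i, arena)[1, ], c(A = 0, B = 0))
  # the centre of the arena is odour-free (0.6 m from both sources)
  expect_equal(odour_stimulus(0 + 0i, arena)[1, ], c(A = 0, B = 0))
  # boundary: detectable just inside the detection radius, not outside
  r <- detection_radius(arena)
  expect_equal(unname(odour_stimulus(arena$mu_A + (r - 1e-6), arena)[1, "A"]), 1)
  expect_equal(unname(odour_stimulus(arena$mu_A + (r + 1e-6), arena)[1, "A"]), 0)
})

test_that("detection radius solves density = threshold in closed form", {
  arena <- arena_parameters()
  r <- detection_radius(arena)
  # independent closed form: r = sigma * sqrt(-2 log(theta * sigma * sqrt(2*pi)))
  r_closed <- 0.3 * sqrt(-2 * log(0.2 * 0.3 * sqrt(2 * pi)))
  expect_equal(r, r_closed, tolerance = 1e-9)
  expect_equal(stats::dnorm(r, sd = 0.3), 0.2, tolerance = 1e-9)
})

test_that("reinforcement is confined to the training window and radius", {
  arena <- arena_parameters()
  near_A <- arena$mu_A + 0.1
  # pre-training step: nothing
  expect_equal(sum(reinforcement_at(near_A, arena, 5, "shock_a")), 0)
  # training step, inside the reinforced area
  expect_equal(reinforcement_at(near_A, arena, 25, "shock_a")[1, ],
               c(sugar = 0, shock = 1))
  expect_equal(reinforcement_at(near_A, arena, 25, "sugar_a")[1, ],
               c(sugar = 1, shock = 0))
  # outside rho_US but still within smelling distance: no US
  expect_equal(sum(reinforcement_at(arena$mu_A + 0.4, arena, 25, "shock_a")), 0)
  # condition targets the right source(s)
  near_B <- arena$mu_B + 0.1
  expect_equal(sum(reinforcement_at(near_B, arena, 25, "shock_a")), 0)
  expect_equal(unname(reinforcement_at(near_B, arena, 25, "shock_ab")[1, "shock"]), 1)
  # post-training step: nothing
  expect_equal(sum(reinforcement_at(near_A, arena, 60, "shock_a")), 0)
})

test_that("closeness posterior follows the Gaussian ratio", {
  arena <- arena_parameters()
  expect_equal(closeness_posterior(0 + 0i, arena)[1, ],
               c(P_A = 0.5, P_B = 0.5))
  expect_gt(closeness_posterior(arena$mu_A, arena)[1, "P_A"], 0.5)
  # closed-form check at position 0.3
  nA <- dnorm(abs(0.3 - (-0.6)), sd = 0.3)
  nB <- dnorm(abs(0.3 - 0.6), sd = 0.3)
  expect_equal(unname(closeness_posterior(0.3 + 0i, arena)[1, "P_A"]),
               nA / (nA + nB), tolerance = 1e-12)
  # numerically-dead zone falls back to 0.5
  expect_equal(unname(closeness_posterior(1e6 + 0i, arena)[1, "P_A"]), 0.5)
})

test_that("attraction force balances and points as the MBONs dictate", {
  arena <- arena_parameters()
  labels <- neuron_labels()$mbon
  # equal attraction and avoidance: no force anywhere
  m <- stats::setNames(rep(0.7, 6), labels)
  expect_equal(Mod(attraction_force(m, 0.2 + 0.4i, arena)), 0)
  # avoidance dominant, fly near A and closer to A: force points away
  m <- stats::setNames(c(0, 1, 0, 1, 0, 1), labels)
  f <- attraction_force(m, arena$mu_A + 0.1, arena)
  expect_gt(Re(f), 0)  # away from mu_A = -0.6
  # LTM attraction only, deep in A's basin: force ~ 0.3 x unit towards A
  m <- stats::setNames(c(0, 0, 0, 0, 0.9, 0), labels)
  pos <- -0.45 + 0i
  f <- attraction_force(m, pos, arena)
  p <- closeness_posterior(pos, arena)[1, ]
  expect_equal(f, 0.3 * (p[["P_A"]] * (-1) + p[["P_B"]] * (+1)) + 0i,
               tolerance = 1e-12)
  expect_lt(Re(f), -0.29)  # essentially 0.3 towards the A source
  # at a source the unit vector is undefined and contributes nothing
  f <- attraction_force(m, arena$mu_A, arena)
  expect_equal(p[["P_A"]] > 0, TRUE)
  expect_true(is.finite(Mod(f)))
})

test_that("velocity updates keep the fixed step speed and are reproducible", {
  arena <- arena_parameters()
  set.seed(1)
  v <- velocity_update(rep(0 + 0i, 50), rep(0 + 0i, 50), arena)
  expect_equal(Mod(v), rep(0.05, 50))
  v2 <- velocity_update(v, rep(0.5 + 0i, 50), arena)
  expect_equal(Mod(v2), rep(0.05, 50))
  set.seed(9); a <- velocity_update(rep(0i, 5), rep(0i, 5), arena)
  set.seed(9); b <- velocity_update(rep(0i, 5), rep(0i, 5), arena)
  expect_identical(a, b)
})

test_that("the batched brain matches the single-fly circuit step for step", {
  p <- default_parameters()
  stims <- list(stimulus_frame("A", "shock"), stimulus_frame("B"),
                stimulus_frame("none"), stimulus_frame("A", "sugar"))
  for (rule in c("dpr", "rpe")) {
    set.seed(31)
    bs <- incentivecircuit:::batch_init(1L, p)
    for (i in 1:8) {
      st <- stims[[1 + (i %% 4)]]
      bs <- incentivecircuit:::batch_forward_step(
        bs, matrix(st$cs, 1), matrix(st$us, 1), p, rule = rule)
    }
    set.seed(31)
    s <- initial_state(p)
    for (i in 1:8) s <- forward_step(s, stims[[1 + (i %% 4)]], p, rule = rule)
    expect_equal(as.numeric(bs$d), unname(s$d), tolerance = 1e-12)
    expect_equal(as.numeric(bs$m), unname(s$m), tolerance = 1e-12)
    expect_equal(bs$W[1, , ], unname(s$W_k2m), tolerance = 1e-12)
  }
})

test_that("arena runs conserve speed and fill the logged dimensions", {
  arena <- arena_parameters(n_flies = 8L, n_repeats = 2L)
  log <- run_arena_experiment("shock_a", arena, seed = 4)
  expect_equal(dim(log$pos), c(8, 100, 2))
  expect_equal(as.vector(table(log$phase)[c("pre", "train", "post")]),
               c(20L, 30L, 50L))
  # every moved step has displacement magnitude 0.05
  for (rep_i in 1:2) {
    disp <- Mod(log$pos[, -1, rep_i] - log$pos[, -100, rep_i])
    expect_equal(disp, matrix(0.05, 8, 99), tolerance = 1e-12)
  }
  # positions reset to the centre between repeats
  expect_true(all(log$pos[, 1, ] == 0 + 0i))
  # determinism
  log2 <- run_arena_experiment("shock_a", arena, seed = 4)
  expect_identical(log$pos, log2$pos)
})

test_that("exposure and preference arithmetic follow their definitions", {
  expect_equal(preference_index(0.2, 0.6), -0.5)
  expect_equal(preference_index(0.3, 0.3), 0)
  expect_equal(preference_index(0.4, 0), 1)
  expect_true(is.na(preference_index(0, 0)))
  x <- runif(100); y <- runif(100)
  pis <- preference_index(x, y)
  expect_true(all(pis >= -1 & pis <= 1))

  # hand-built log: fly 1 detects A half of every post phase for 4 repeats,
  # fly 2 never detects anything
  dims <- c(2, 100, 4)
  log <- structure(list(
    pos = array(0 + 0i, dims),
    det_A = array(FALSE, dims), det_B = array(FALSE, dims),
    us_on = array(FALSE, dims),
    phase = rep(c("pre", "train", "post"), c(20, 30, 50))
  ), class = "ic_behaviour_log")
  log$det_A[1, 51:75, ] <- TRUE
  expect_equal(cumulative_exposure(log, "A", "post"), c(2, 0))
  expect_equal(cumulative_exposure(log, "A", "post", up_to_repeat = 2), c(1, 0))
  expect_equal(cumulative_exposure(log, "B", "post"), c(0, 0))
  pr <- arena_preference(log)
  expect_equal(pr$PI, c(1, NA_real_))
  # visitor filter: fly 1 has not visited B, fly 2 nothing
  expect_equal(filter_both_odour_visitors(log), integer(0))
  log$det_B[1, 90, 1] <- TRUE  # a single step in B suffices
  expect_equal(filter_both_odour_visitors(log), 1L)
})

test_that("cumulative exposure is non-decreasing in the repeat index", {
  arena <- arena_parameters(n_flies = 6L, n_repeats = 3L)
  log <- run_arena_experiment("sugar_a", arena, seed = 2)
  for (odour in c("A", "B")) {
    prev <- rep(0, 6)
    for (R in 1:3) {
      cur <- cumulative_exposure(log, odour, "post", R)
      expect_true(all(cur >= prev - 1e-12))
      prev <- cur
    }
  }
})

test_that("naive flies show no systematic bias towards either source", {
  arena <- arena_parameters(n_flies = 60L, n_repeats = 1L)
  log <- run_arena_experiment("shock_a", arena, seed = 6)
  # pre-training phase of the first repeat: behaviour is noise-driven
  pre_x <- Re(log$pos[, 20, 1])
  expect_lt(abs(mean(pre_x)), 0.1)
})
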