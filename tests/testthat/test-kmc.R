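test_that("the event-rate table matches the stated channels", {
  p <- sim_params(k_spawn = 5, v_ret = 0.09, v_ext = 0.28)
  # no pili: spawn only
  r0 <- event_rates(NULL, p)
  expect_equal(r0$event, "spawn")
  expect_equal(attr(r0, "total"), 5)

  # one retracting free pilus: v_ret / delta = 22.5 steps per second
  st <- data.frame(bound = FALSE, motor = "retracting", stalled = FALSE)
  r1 <- event_rates(st, p)
  expect_equal(r1$rate[r1$event == "retract_step"], 0.09 / 0.004)

  # stalled bound pilus: its retraction channel is excluded
  st2 <- data.frame(bound = TRUE, motor = "retracting", stalled = TRUE)
  r2 <- event_rates(st2, p)
  expect_false("retract_step" %in% r2$event)
  expect_true("detach" %in% r2$event)

  # extending pilus carries motor-off and step-out channels
  st3 <- data.frame(bound = FALSE, motor = "extending", stalled = FALSE)
  r3 <- event_rates(st3, p)
  expect_setequal(r3$event, c("spawn", "resample", "ext_motor_off",
                              "extend_step"))
  expect_equal(r3$rate[r3$event == "extend_step"], 0.28 / 0.004)
})

test_that("simulations are reproducible and respect count invariants", {
  p <- validation_params()
  s1 <- suppressWarnings(simulate_twitching(p, duration = 30, seed = 42))
  s2 <- suppressWarnings(simulate_twitching(p, duration = 30, seed = 42))
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$pili, s2$pili)

  tr <- s1$trajectory
  expect_equal(diff(tr$t), rep(0.1, nrow(tr) - 1))
  expect_true(all(tr$n_taut <= tr$n_bound))
  expect_true(all(tr$n_bound <= tr$n_tfp))
  expect_true(all(tr$n_vis03 <= tr$n_tfp))
  expect_true(all(abs(sqrt(tr$bx^2 + tr$by^2 + tr$bz^2) - 1) < 1e-6))
})

test_that("a pilus-free simulation stays put", {
  p <- update_params(validation_params(), k_spawn = 0)
  s <- simulate_twitching(p, duration = 5, seed = 1)
  tr <- s$trajectory
  expect_equal(stats::sd(tr$x_lead), 0)
  expect_equal(stats::sd(tr$y_lead), 0)
  expect_equal(nrow(s$pili), 0)
})

test_that("spawn events occur at the configured rate", {
  p <- update_params(validation_params(), k_spawn = 5)
  s <- suppressWarnings(simulate_twitching(p, duration = 200, seed = 9))
  n_spawned <- nrow(s$pili)
  # Poisson count: 1000 +/- ~3 sqrt(1000)
  expect_lt(abs(n_spawned - 1000), 3.5 * sqrt(1000))
})

test_that("a single dragging pilus moves the body at the retraction speed", {
  p <- update_params(validation_params(), tau_dwell = Inf, k_spawn = 0,
                     v_ret = 0.09)
  ip <- data.frame(da_x = 2.0, da_y = 0, da_z = 0,
                   na_x = 1, na_y = 0, na_z = 0,
                   n_seg = 500, bound = 1, rb_x = 4.0, rb_y = 0, rb_z = 0,
                   motor = 5)
  s <- suppressWarnings(simulate_twitching(p, duration = 16, seed = 2,
                                           init_pili = ip))
  tr <- s$trajectory
  i0 <- which.min(abs(tr$t - 2)); i1 <- which.min(abs(tr$t - 14))
  v <- (tr$x_lead[i1] - tr$x_lead[i0]) / (tr$t[i1] - tr$t[i0])
  # the overdamped pose tracks the reeling motor to within the stall
  # hysteresis, slightly below v_ret
  expect_equal(v, 0.09, tolerance = 0.1)
})

test_that("opposed bound pili stall each other into a fixed point", {
  p <- update_params(validation_params(), tau_dwell = Inf, k_spawn = 0)
  ip <- data.frame(da_x = c(2, -2), da_y = 0, da_z = 0,
                   na_x = c(1, -1), na_y = 0, na_z = 0,
                   n_seg = c(400, 400), bound = 1,
                   rb_x = c(3.6, -3.6), rb_y = 0, rb_z = 0, motor = 5)
  s <- suppressWarnings(simulate_twitching(p, duration = 30, seed = 3,
                                           init_pili = ip))
  tr <- s$trajectory
  # symmetric tug: no net translation along the pili axis
  expect_lt(abs(tr$x_lead[nrow(tr)] - tr$x_lead[1]), 0.05)
  # both pili end up stalled at the stall force and stay bound
  tail_frames <- tr[tr$t > 20, ]
  expect_true(all(tail_frames$n_stalled == 2))
  expect_true(all(tail_frames$n_bound == 2))
})

test_that("free-pilus population matches the birth-death balance", {
  p <- update_params(validation_params(), k_spawn = 5)
  s <- suppressWarnings(simulate_twitching(p, duration = 300, seed = 4,
                                           binding = FALSE))
  tr <- s$trajectory
  expect_equal(sum(tr$n_bound), 0) # binding disabled
  set.seed(5)
  EL <- pilus_lifetime_oracle(p, n = 1500)
  # discard the fill-up transient, then mean count = k_spawn * E[lifetime]
  steady <- tr$n_tfp[tr$t > 100]
  expect_equal(mean(steady), 5 * EL, tolerance = 0.08)
})

test_that("rest lengths stay multiples of the discretisation step", {
  p <- validation_params()
  s <- suppressWarnings(simulate_twitching(p, duration = 20, seed = 6))
  # max_len is accumulated from n_seg * delta, so it must be a multiple
  ml <- s$pili$max_len / p$delta_step
  expect_equal(ml, round(ml), tolerance = 1e-9)
})

test_that("crawling in a deep well stays crawling; a repulsive surface does not", {
  p <- validation_params() # attractive well, eps = 50
  s <- suppressWarnings(simulate_twitching(p, duration = 150, seed = 7))
  cl <- classify_trajectory(s)
  expect_equal(cl$label, "crawling")
  expect_gt(cl$b_min, 3.5) # axis stays in-plane

  pr <- sim_params(mode = "crawling", surface = surface_potential("repulsive"),
                   tau_dwell = 1, kappa = 2.5, v_ret = 0.5, k_spawn = 5)
  sr <- suppressWarnings(simulate_twitching(pr, duration = 150, seed = 7))
  tw <- transition_time(sr, "crawling_to_walking")
  expect_true(attr(tw, "transitioned"))
  expect_lt(tw, 100)
})

test_that("pilus diagnostics summarise counts, visibility and contact", {
  s <- suppressWarnings(simulate_twitching(validation_params(),
                                           duration = 100, seed = 8))
  d <- tfp_diagnostics(s)
  expect_true(d$mean_taut <= d$mean_bound)
  expect_true(d$mean_bound <= d$mean_total)
  # threshold zero equals the total count; visibility decreases with the
  # threshold
  expect_equal(unname(d$mean_visible["0"]), d$mean_total)
  expect_true(d$mean_visible["0.3"] >= d$mean_visible["1"])
  expect_true(d$contact_fraction > 0 && d$contact_fraction < 1)
  expect_true(d$mean_dx >= 0)
})
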