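test_that("the rejection core accepts the reference and respects scaling", {
  set.seed(1)
  S <- cbind(a = rnorm(200, 1, 0.3), b = rnorm(200, 5, 2))
  ref <- S[17, ]
  rej <- abc_reject(S, ref, m = 10)
  expect_true(rej$accepted[17])
  expect_equal(rej$rho[17], 0)
  expect_equal(rej$weight[17], 1)

  # standardisation invariance: rescaling one statistic across all samples
  # leaves the accepted set unchanged
  S2 <- S; S2[, 2] <- S2[, 2] * 1000
  rej2 <- abc_reject(S2, c(ref[1], ref[2] * 1000), m = 10)
  expect_identical(rej$accepted, rej2$accepted)

  # boundary: m = n accepts everything with kernel weights
  rej3 <- abc_reject(S, ref, m = 200)
  expect_true(all(rej3$accepted))
  expect_true(all(rej3$weight >= 0 & rej3$weight <= 1))

  # degenerate column is dropped with a warning
  S4 <- cbind(S, c = 1)
  expect_warning(rej4 <- abc_reject(S4, c(ref, c = 1), m = 10), "degenerate")
  expect_identical(rej4$accepted, rej$accepted)
})

test_that("rejection ABC recovers the toy-Gaussian posterior", {
  # conjugate toy: theta ~ U(-3, 3), x_i ~ N(theta, 1), summary = mean of
  # 5 draws.  For reference 0 the posterior approaches N(0, 1/5) as the
  # acceptance threshold shrinks.
  set.seed(2)
  n <- 6000
  theta <- runif(n, -3, 3)
  xbar <- rnorm(n, theta, 1 / sqrt(5))
  S <- cbind(xbar = xbar)
  sd_acc <- function(m) {
    rej <- abc_reject(S, c(xbar = 0), m)
    stats::sd(theta[rej$accepted])
  }
  sd_tight <- sd_acc(60)
  sd_loose <- sd_acc(1200)
  expect_equal(sd_tight, sqrt(1 / 5), tolerance = 0.15)
  # shrinking the acceptance fraction moves the sample towards the
  # true posterior spread
  expect_lt(abs(sd_tight - sqrt(1 / 5)), abs(sd_loose - sqrt(1 / 5)))
  rej <- abc_reject(S, c(xbar = 0), 60)
  expect_lt(abs(mean(theta[rej$accepted])), 0.12)
})

test_that("posterior summaries find the mode of a known distribution", {
  set.seed(3)
  prior <- parameter_box(c("kappa", "v_ret"), c(1, 0.01), c(15, 1))
  n <- 1000
  acc <- data.frame(kappa = pmin(pmax(rnorm(n, 6, 1.2), 1), 15),
                    v_ret = pmin(pmax(rnorm(n, 0.4, 0.08), 0.01), 1),
                    weight = rep(1, n), accepted = TRUE)
  fake <- structure(list(samples = acc, prior = prior), class = "abc_result")
  post <- posterior_summaries(fake)
  # a KDE mode at this sample size carries sampling noise of roughly a
  # fifth of sigma regardless of bandwidth choice
  expect_lt(abs(post$summary$mle[1] - 6), 0.25 * 1.2)
  expect_lt(abs(post$summary$mle[2] - 0.4), 0.25 * 0.08)
  # central interval close to the normal quantiles
  expect_equal(post$summary$ci_lo[1], qnorm(0.05, 6, 1.2), tolerance = 0.25)
  expect_equal(post$summary$ci_hi[1], qnorm(0.95, 6, 1.2), tolerance = 0.25)
  expect_true(all(post$summary$mle >= post$summary$ci_lo &
                  post$summary$mle <= post$summary$ci_hi))
})

test_that("degenerate weight concentrations are flagged", {
  prior <- parameter_box("kappa", 1, 15)
  acc <- data.frame(kappa = c(5, 7, 9), weight = c(1, 0, 0),
                    accepted = TRUE)
  fake <- structure(list(samples = acc, prior = prior), class = "abc_result")
  w <- capture_warnings(post <- posterior_summaries(fake))
  expect_true(any(grepl("single sample", w)))
  expect_equal(post$summary$mle[1], 5, tolerance = 1)
})

test_that("accepted dispersion contracts for pinned-down quantities", {
  set.seed(4)
  prior <- parameter_box("kappa", 1, 15)
  n <- 400
  samples <- data.frame(kappa = runif(n, 1, 15),
                        pinned = rnorm(n),
                        free = rnorm(n),
                        accepted = FALSE)
  # acceptance correlated with `pinned`, independent of `free`
  samples$accepted <- rank(abs(samples$pinned)) <= 40
  fake <- structure(list(samples = samples, prior = prior),
                    class = "abc_result")
  r_pinned <- accepted_dispersion(fake, "pinned")
  r_free <- accepted_dispersion(fake, "free")
  expect_lt(r_pinned, 0.5)
  expect_gt(r_free, 0.7)
  samples$accepted <- TRUE
  fake$samples <- samples
  expect_equal(accepted_dispersion(fake, "free"), 1)
  expect_error(accepted_dispersion(fake, "nope"), "no such")
})

test_that("evaluate_sample honours the stopping rule", {
  ev <- evaluate_sample(c(tau_dwell = 2, kappa = 2.5, v_ret = 0.09,
                          k_spawn = 5),
                        duration = 120, max_traj = 5, target_steps = 20,
                        seed = 1)
  # a moving sample reaches the step target before the trajectory cap
  expect_lt(ev$n_traj, 5)
  expect_gte(ev$n_steps, 20)
  expect_true(all(is.finite(ev$stats)))

  # an immotile sample exhausts its trajectory budget with no steps
  ev0 <- evaluate_sample(c(tau_dwell = 2, kappa = 2.5, v_ret = 0.09,
                           k_spawn = 0),
                         duration = 30, max_traj = 2, target_steps = 20,
                         seed = 1)
  expect_equal(ev0$n_traj, 2)
  expect_equal(ev0$n_steps, 0)
  expect_true(all(is.na(ev0$stats)))
})

test_that("a scaled-down ABC run is reproducible end to end", {
  ref <- c(mean_speed = 0.08, var_dev = 1.0, q_hat = 0.45, a_hat = 0.06)
  run <- function() {
    suppressWarnings(rejection_abc(ref, n = 12, m = 3, duration = 40,
                                   max_traj = 1, target_steps = 10,
                                   seed = 99))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$samples, r2$samples)
  expect_equal(sum(r1$samples$accepted), 3)
  expect_true(all(r1$samples$weight[r1$samples$accepted] >= 0))
})
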