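test_that("linearisation reproduces the greedy fixed-length scan", {
  # straight track at 0.06 um/s for 10 s at 10 fps: a step is completed
  # every 2 s (first frame at cumulative displacement >= 0.12 um), so 5
  # steps of exactly 0.12 um at 0.06 um/s
  t <- seq(0, 10, 0.1)
  tr <- data.frame(t = t, x = 0.06 * t, y = 0)
  l <- linearise(tr)
  expect_equal(nrow(l), 5)
  expect_equal(l$dt, rep(2, 5))
  expect_equal(sqrt((l$x1 - l$x0)^2 + (l$y1 - l$y0)^2), rep(0.12, 5))
  expect_equal(l$speed, rep(0.06, 5))

  # sub-threshold jitter never completes a step
  set.seed(1)
  tj <- data.frame(t = t, x = rnorm(length(t), 0, 0.01),
                   y = rnorm(length(t), 0, 0.01))
  lj <- linearise(tj)
  expect_equal(nrow(lj), 0)
  expect_true(attr(lj, "flagged"))

  # one 1.2 um dash within a single frame is one undivided step
  td <- data.frame(t = c(0, 0.1, 0.2), x = c(0, 1.2, 1.2), y = 0)
  ld <- linearise(td)
  expect_equal(nrow(ld), 1)
  expect_equal(ld$speed, 12)
})

test_that("linearisation is idempotent and rigid-motion invariant", {
  set.seed(2)
  t <- seq(0, 60, 0.1)
  x <- cumsum(rnorm(length(t), 0.004, 0.02))
  y <- cumsum(rnorm(length(t), 0, 0.02))
  tr <- data.frame(t = t, x = x, y = y)
  l1 <- linearise(tr)
  # re-linearising the accepted points changes nothing
  tr2 <- data.frame(t = l1$t1, x = l1$x1, y = l1$y1)
  l2 <- linearise(rbind(data.frame(t = l1$t0[1], x = l1$x0[1], y = l1$y0[1]),
                        tr2))
  expect_equal(nrow(l2), nrow(l1))
  expect_equal(l2$speed, l1$speed, tolerance = 1e-12)

  # rotation + translation of the track leaves step lengths and speeds
  phi <- 0.7
  xr <- cos(phi) * x - sin(phi) * y + 5
  yr <- sin(phi) * x + cos(phi) * y - 3
  lr <- linearise(data.frame(t = t, x = xr, y = yr))
  expect_equal(lr$speed, l1$speed, tolerance = 1e-10)
  expect_equal(nrow(lr), nrow(l1))
})

test_that("summary statistics have the PRW fixed points", {
  # constant velocity: q = 1, a = 0
  l <- lin_from_velocities(rep(0.1, 50), rep(0, 50))
  s <- summary_stats(l, trim = 0)
  expect_equal(s$q_hat, 1)
  expect_equal(s$a_hat, 0)
  expect_equal(s$mean_speed, 0.1)
  expect_equal(s$var_dev, 0) # straight along the axis

  # i.i.d. zero-mean Gaussian velocities: q ~ 0, a ~ component sd
  set.seed(3)
  n <- 1e4
  l2 <- lin_from_velocities(rnorm(n, 0, 0.05), rnorm(n, 0, 0.05))
  s2 <- summary_stats(l2, trim = 0)
  expect_lt(abs(s2$q_hat), 0.025)
  expect_equal(s2$a_hat, 0.05, tolerance = 0.02)
})

test_that("PRW parameters are recovered across the persistence range", {
  set.seed(4)
  for (q in c(0, 0.4, 0.8)) {
    v <- prw_velocities(4000, q, 0.1)
    s <- summary_stats(lin_from_velocities(v[, 1], v[, 2]), trim = 0)
    se_q <- sqrt((1 - q^2) / 4000)
    expect_lt(abs(s$q_hat - q), 3 * se_q + 0.005)
    expect_equal(s$a_hat, 0.1, tolerance = 0.01)
  }
})

test_that("velocity trimming protects the persistence estimates", {
  set.seed(5)
  v <- prw_velocities(4000, 0.42, 0.1)
  base <- summary_stats(lin_from_velocities(v[, 1], v[, 2]), trim = 0.01)
  # inject 0.5% wild outliers (100x speed)
  idx <- sample(4000, 20)
  v[idx, ] <- v[idx, ] * 100
  pert <- summary_stats(lin_from_velocities(v[, 1], v[, 2]), trim = 0.01)
  expect_lt(abs(pert$q_hat - base$q_hat), 0.02)
})

test_that("summary statistics are invariant under global rotation", {
  set.seed(6)
  v <- prw_velocities(800, 0.4, 0.1)
  phi <- 1.1
  vr <- cbind(cos(phi) * v[, 1] - sin(phi) * v[, 2],
              sin(phi) * v[, 1] + cos(phi) * v[, 2])
  s1 <- summary_stats(lin_from_velocities(v[, 1], v[, 2], 1, 0))
  s2 <- summary_stats(lin_from_velocities(vr[, 1], vr[, 2],
                                          cos(phi), sin(phi)))
  expect_equal(s1$q_hat, s2$q_hat, tolerance = 1e-10)
  expect_equal(s1$var_dev, s2$var_dev, tolerance = 1e-10)
  expect_equal(s1$mean_speed, s2$mean_speed, tolerance = 1e-10)
})

test_that("MSD exponent separates ballistic from diffusive motion", {
  t <- seq(0, 400, 0.1)
  k_ball <- msd_exponent(data.frame(t = t, x = 0.05 * t, y = 0))
  expect_equal(as.numeric(k_ball), 2, tolerance = 1e-6)

  set.seed(7)
  rw <- data.frame(t = t, x = cumsum(rnorm(length(t), 0, 0.05)),
                   y = cumsum(rnorm(length(t), 0, 0.05)))
  k_diff <- msd_exponent(rw)
  expect_equal(as.numeric(k_diff), 1, tolerance = 0.05)
  expect_error(msd_exponent(data.frame(t = seq(0, 3, 0.1), x = 1:31, y = 0)),
               "span")
})

test_that("aspect-ratio classification follows the projection formula", {
  # horizontal spherocylinder: b = (3 + 1) / 1 = 4 -> crawling
  n <- 300
  horiz <- data.frame(bx = rep(1, n), by = 0, bz = 0)
  ch <- classify_trajectory(horiz, window = 200)
  expect_equal(ch$b_min, 4)
  expect_equal(ch$label, "crawling")

  # vertical body projects to a circle: b = 1 -> walking
  vert <- data.frame(bx = rep(0, n), by = 0, bz = 1)
  cv <- classify_trajectory(vert, window = 200)
  expect_equal(cv$b_min, 1)
  expect_equal(cv$label, "walking")

  # the boundary value itself is walking (strict >)
  cb <- classify_trajectory(rep(1.6, n), window = 200)
  expect_equal(cb$label, "walking")

  # short series fall back to a single window and are flagged
  cs <- classify_trajectory(rep(4, 50), window = 200)
  expect_true(cs$flagged)
  expect_equal(cs$label, "crawling")
})

test_that("transition times read the trailing-pole contact", {
  # a quiescent deep-well crawler never transitions: tau_w = t_max
  p <- update_params(validation_params(), k_spawn = 0)
  s <- simulate_twitching(p, duration = 20, seed = 1)
  tw <- transition_time(s, "crawling_to_walking")
  expect_false(attr(tw, "transitioned"))
  expect_equal(as.numeric(tw), 20)
})
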