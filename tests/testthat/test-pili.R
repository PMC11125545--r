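test_that("anchor directions follow the von Mises-Fisher law", {
  set.seed(1)
  n <- 1e5
  ct <- twitchsim:::.cpp_vmf_costheta(n, 2.5)
  # closed-form mean resultant length: coth(kappa) - 1/kappa
  expect_equal(mean(ct), 1 / tanh(2.5) - 1 / 2.5, tolerance = 0.005)
  # Kolmogorov-Smirnov against the analytic cos-theta CDF
  k <- 2.5
  Fvmf <- function(t) (exp(k * t) - exp(-k)) / (exp(k) - exp(-k))
  ks <- suppressWarnings(stats::ks.test(ct, Fvmf))
  expect_gt(ks$p.value, 0.01)
})

test_that("anchor mapping concentrates on the pole as kappa grows", {
  set.seed(2)
  # near-degenerate concentration: all anchors at the leading cap tip
  a_inf <- sample_anchor(500, kappa = 500)
  expect_true(all(a_inf$on_cap))
  expect_true(all(a_inf$da_x > 1.95))
  # broader distributions put more anchors on the cylindrical wall
  frac_wall <- function(kp) mean(!sample_anchor(2e4, kp)$on_cap)
  expect_gt(frac_wall(1.0), frac_wall(7.0))
  # all anchors on the leading half, on the body surface
  a <- sample_anchor(2000, 2.5)
  expect_true(all(a$da_x >= -1e-9))
  radial <- sqrt(a$da_y^2 + a$da_z^2)
  on_cyl <- !a$on_cap
  expect_equal(radial[on_cyl], rep(0.5, sum(on_cyl)), tolerance = 1e-9)
  cap_r <- sqrt((a$da_x[a$on_cap] - 1.5)^2 + radial[a$on_cap]^2)
  expect_equal(cap_r, rep(0.5, sum(a$on_cap)), tolerance = 1e-9)
  expect_error(sample_anchor(10, kappa = -1), "kappa")
})

test_that("worm-like chains reproduce the tangent correlation", {
  set.seed(3)
  delta <- 0.004
  nseg <- 250 # 1 um contour
  nchain <- 1500
  corr <- numeric(nchain)
  for (i in seq_len(nchain)) {
    ch <- sample_chain(nseg, persistence_length = 5, normal = c(0, 0, 1),
                       delta_step = delta)
    t0 <- ch[1, ] / delta
    ts <- (ch[126, ] - ch[125, ]) / delta # tangent at s = 0.5 um
    corr[i] <- sum(t0 * ts)
  }
  expect_equal(mean(corr), exp(-0.5 / 5), tolerance = 0.02)
})

test_that("the rigid limit gives straight chains", {
  set.seed(4)
  ch <- sample_chain(200, persistence_length = 1e7, normal = c(0, 1, 0),
                     delta_step = 0.004)
  ee <- sqrt(sum(ch[200, ]^2))
  expect_equal(ee, 200 * 0.004, tolerance = 1e-5)
  expect_gt(ch[200, 2], 0.999 * 0.8)
})

test_that("direct WLC sampling matches a Metropolis oracle on short chains", {
  set.seed(5)
  # stiff regime (delta/Lp = 0.02) where the harmonic bending weight and
  # the exact sin(theta)-measure chain coincide to O(theta^2)
  nseg <- 20; delta <- 0.05; Lp <- 2.5
  nd <- 400
  ee_direct <- replicate(nd, {
    ch <- sample_chain(nseg, Lp, normal = c(0, 0, 1), delta_step = delta)
    sqrt(sum(ch[nseg, ]^2))
  })
  ee_mh <- replicate(nd, {
    pos <- wlc_metropolis_chain(nseg, Lp, delta)
    sqrt(sum(pos[nseg, ]^2))
  })
  expect_equal(mean(ee_direct), mean(ee_mh), tolerance = 0.01)
  ks <- suppressWarnings(stats::ks.test(ee_direct, ee_mh))
  expect_gt(ks$p.value, 0.01)
})

test_that("elastic energy and tension follow the stretched-spring law", {
  expect_equal(elastic_energy(1.0, 1.0), 0)
  expect_equal(pilus_tension(1.0, 1.0), 0)
  expect_equal(elastic_energy(1.1, 1.0, E = 2000), 10)
  expect_equal(pilus_tension(1.1, 1.0, E = 2000), 200)
  # slack pili store nothing and cannot push
  expect_equal(elastic_energy(0.7, 1.0), 0)
  expect_equal(pilus_tension(0.7, 1.0), 0)
  expect_error(elastic_energy(1, 0), "dissolved")

  # continuity and convexity around the rest length: zero value and zero
  # slope at r_ab = l_eq, increasing slope beyond
  x <- seq(0.9, 1.3, by = 1e-3)
  u <- elastic_energy(x, 1.0)
  expect_true(all(diff(u) >= 0))
  slope_at_leq <- (elastic_energy(1 + 1e-6, 1) - elastic_energy(1 - 1e-6, 1)) / 2e-6
  expect_lt(abs(slope_at_leq), 1e-2)
  d2 <- diff(diff(u[x > 1.001]))
  expect_true(all(d2 > -1e-12))
})

test_that("the stall rule blocks retraction above the stall force", {
  # unbound pili always may retract
  expect_true(retraction_allowed(2, 1, bound = FALSE))
  # tension 120 pN > 100 pN stall: blocked
  expect_false(retraction_allowed(1.06, 1.0, E = 2000, f_stall = 100))
  # tension 40 pN: allowed
  expect_true(retraction_allowed(1.02, 1.0, E = 2000, f_stall = 100))
  # slack pilus: always allowed
  expect_true(retraction_allowed(0.5, 1.0))
})
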