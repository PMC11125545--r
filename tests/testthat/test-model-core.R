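test_that("pole sites sit at center +/- (l/2) axis", {
  b <- body_configuration(c(0, 0, 0.5), c(1, 0, 0), length = 3)
  s <- pole_sites(b)
  expect_equal(unname(s["leading", ]), c(1.5, 0, 0.5))
  expect_equal(unname(s["trailing", ]), c(-1.5, 0, 0.5))

  b2 <- body_configuration(c(0, 0, 2), c(0, 0, 1), length = 3)
  s2 <- pole_sites(b2)
  expect_equal(unname(s2["leading", ]), c(0, 0, 3.5))
  expect_equal(unname(s2["trailing", ]), c(0, 0, 0.5))

  # midpoint of the sites is always the centre
  set.seed(7)
  for (i in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ct <- rnorm(3)
    b3 <- body_configuration(ct, ax)
    expect_equal(unname(colMeans(pole_sites(b3))), ct)
  }
  expect_error(body_configuration(c(0, 0, 0), c(1, 1, 0)), "unit")
})

test_that("surface energy reproduces the site potential", {
  well <- surface_potential("attractive_well", epsilon = 50, range = 0.05)
  rep_ <- surface_potential("repulsive", wall_stiffness = 1e5)

  # far above the surface: zero
  high <- body_configuration(c(0, 0, 5), c(1, 0, 0))
  expect_equal(surface_energy(high, well), 0)

  # crawling pose with both gaps zero: two pole sites at the well minimum
  crawl <- body_configuration(c(0, 0, 0.5), c(1, 0, 0))
  expect_equal(surface_energy(crawl, well), -100)

  # penetration of 0.01 um: (k/2) gap^2 per site
  pen <- body_configuration(c(0, 0, 0.49), c(1, 0, 0))
  expect_equal(surface_energy(pen, rep_), 2 * 0.5 * 1e5 * 0.01^2)
})

test_that("total energy is additive over surface and pilus terms", {
  pot <- surface_potential("repulsive")
  b <- body_configuration(c(0, 0, 1.0), c(1, 0, 0))
  expect_equal(total_energy(b, NULL, pot)$total, 0)

  # one taut pilus exactly at its rest length stores nothing
  ra <- c(1.5, 0, 1.0)
  rb <- c(3, 0, 0)
  leq <- sqrt(sum((ra - rb)^2))
  p1 <- data.frame(da_x = 1.5, da_y = 0, da_z = 0, rb_x = 3, rb_y = 0,
                   l_eq = leq)
  expect_equal(total_energy(b, p1, pot)$pili, 0)

  # two identical stretched pili double the elastic term
  p1$l_eq <- leq - 0.1
  e1 <- total_energy(b, p1, pot)
  e2 <- total_energy(b, rbind(p1, p1), pot)
  expect_equal(e2$pili, 2 * e1$pili)
  expect_equal(e1$total, e1$surface + e1$pili)
  # matches the independent plain-R energy
  expect_equal(e1$total,
               energy_R(c(0, 0, 1), rot_from_axis(c(1, 0, 0)), p1, pot),
               tolerance = 1e-12)
})

test_that("relaxation settles a free body into the well", {
  well <- surface_potential("attractive_well", epsilon = 50)
  b <- body_configuration(c(0, 0, 0.53), c(1, 0, 0))
  r <- relax_body(b, NULL, well)
  s <- pole_sites(r)
  expect_equal(unname(s[, "z"]) - 0.5, c(0, 0), tolerance = 1e-6)
  expect_equal(attr(r, "energy"), -100, tolerance = 1e-9)
  expect_true(attr(r, "converged"))
})

test_that("a single stretched pilus is relaxed to its rest length", {
  pot <- surface_potential("repulsive")
  # pilus pulling the leading pole horizontally, r_ab > l_eq
  pil <- data.frame(da_x = 2.0, da_y = 0, da_z = 0, rb_x = 4, rb_y = 0,
                    l_eq = 1.5)
  b <- body_configuration(c(0, 0, 0.5), c(1, 0, 0))
  r <- relax_body(b, pil, pot)
  ra <- r$center + attr(r, "rotation") %*% c(2, 0, 0)
  rab <- sqrt(sum((ra - c(4, 0, 0))^2))
  expect_equal(rab, 1.5, tolerance = 1e-5) # tension fully relieved
  # agrees with the brute-force minimiser on the plain-R energy
  o <- brute_force_relax(c(0, 0, 0.5), c(1, 0, 0), pil, pot)
  expect_lt(abs(attr(r, "energy") - o$value), 1e-6)
})

test_that("opposed co-linear pili leave the body in place", {
  pot <- surface_potential("repulsive")
  pil <- data.frame(da_x = c(2, -2), da_y = 0, da_z = 0,
                    rb_x = c(4, -4), rb_y = 0, l_eq = c(1.4, 1.4))
  b <- body_configuration(c(0, 0, 0.5), c(1, 0, 0))
  r <- relax_body(b, pil, pot)
  expect_equal(r$center[1], 0, tolerance = 1e-8)
})

test_that("relaxation is monotone and matches brute force on random instances", {
  set.seed(11)
  pot <- surface_potential("attractive_well", epsilon = 50)
  for (rep in 1:8) {
    npil <- sample(0:3, 1)
    pil <- if (npil > 0) {
      da <- cbind(runif(npil, 0.8, 2), runif(npil, -0.3, 0.3),
                  runif(npil, -0.3, 0.3))
      # attachments placed outward of the anchors with mild stretch so the
      # landscape has a single relevant basin
      rb <- da[, 1:2, drop = FALSE] + cbind(runif(npil, 0.3, 1),
                                            runif(npil, -0.5, 0.5))
      leq <- sqrt(rowSums(cbind(rb - da[, 1:2, drop = FALSE],
                                0.5 + da[, 3])^2)) * runif(npil, 0.92, 1.0)
      data.frame(da_x = da[, 1], da_y = da[, 2], da_z = da[, 3],
                 rb_x = rb[, 1], rb_y = rb[, 2], l_eq = leq)
    } else NULL
    ctr <- c(0, 0, 0.5 + runif(1, -0.005, 0.02))
    b <- body_configuration(ctr, c(1, 0, 0))
    e0 <- total_energy(b, pil, pot)$total
    r <- relax_body(b, pil, pot)
    expect_lte(attr(r, "energy"), e0 + 1e-12) # never uphill
    o <- brute_force_relax(ctr, c(1, 0, 0), pil, pot)
    expect_lt(abs(attr(r, "energy") - o$value), 1e-6)
  }
})

test_that("energy is gauge invariant without pili", {
  pot <- surface_potential("attractive_well", epsilon = 50)
  b1 <- body_configuration(c(0, 0, 0.51), c(1, 0, 0))
  b2 <- body_configuration(c(3.7, -2.2, 0.51), c(0, 1, 0)) # translated + yawed
  expect_equal(surface_energy(b1, pot), surface_energy(b2, pot))
})
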