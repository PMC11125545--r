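test_that("the Saltelli design has the A/B/AB block structure", {
  box <- parameter_box(c("kappa", "v_ret"), c(1, 0.01), c(15, 1))
  d <- saltelli_design(box, n_base = 4, seed = 1)
  expect_equal(nrow(d$design), 4 * (2 + 2))
  expect_true(all(d$design[, 1] >= 1 & d$design[, 1] <= 15))
  expect_true(all(d$design[, 2] >= 0.01 & d$design[, 2] <= 1))
  # AB_kappa block: kappa column from B, v_ret column from A
  A <- d$design[1:4, ]; B <- d$design[5:8, ]; ABk <- d$design[9:12, ]
  expect_equal(ABk[, "kappa"], B[, "kappa"])
  expect_equal(ABk[, "v_ret"], A[, "v_ret"])

  d11 <- saltelli_design(sensitivity_box(), n_base = 2048, seed = 1)
  expect_equal(nrow(d11$design), 26624) # 2048 * (11 + 2)
})

test_that("the sensitivity box brackets the reference parameter values", {
  box <- sensitivity_box()
  p <- sim_params()
  for (i in seq_len(nrow(box))) {
    v <- p[[box$name[i]]]
    expect_true(v >= box$min[i] && v <= box$max[i], label = box$name[i])
  }
})

test_that("total-effect indices isolate the active variable", {
  set.seed(2)
  n <- 512
  A <- matrix(runif(2 * n), n); B <- matrix(runif(2 * n), n)
  fA <- A[, 1]; fB <- B[, 1]
  f_AB <- cbind(B[, 1], A[, 1]) # swap x1 / keep x1
  te <- total_effect(fA, fB, f_AB)
  expect_gt(te$S_T[1], 0.9)
  expect_lt(te$S_T[2], 0.05)

  # constant output is flagged degenerate
  expect_warning(te0 <- total_effect(rep(1, n), rep(1, n),
                                     matrix(1, n, 2)), "degenerate")
  expect_true(all(is.na(te0$S_T)))
})

test_that("the Jansen estimator matches the Ishigami closed form", {
  truth <- ishigami_truth()
  est_at <- function(n_base, seed) {
    box <- parameter_box(c("kappa", "v_ret", "L_p"),
                         rep(-pi, 3), rep(pi, 3)) # names are placeholders
    d <- saltelli_design(box, n_base, seed = seed)
    y <- ishigami_f(d$design)
    iA <- seq_len(n_base); iB <- n_base + iA
    f_AB <- vapply(1:3, function(k) y[(k + 1) * n_base + iA],
                   numeric(n_base))
    total_effect(y[iA], y[iB], f_AB, n_boot = 50)$S_T
  }
  st_hi <- est_at(4096, 3)
  expect_equal(unname(st_hi), unname(truth), tolerance = 0.04)
  # consistency: the error shrinks as the design grows
  st_lo <- est_at(256, 3)
  expect_lt(max(abs(st_hi - truth)), 0.05)
  expect_lt(max(abs(st_lo - truth)), 0.3)
})

test_that("run_sensitivity wires simulations to indices", {
  # tiny smoke run on the two dominant parameters
  box <- parameter_box(c("kappa", "v_ret"), c(1, 0.0025), c(15, 0.25))
  res <- suppressWarnings(
    run_sensitivity(box, n_base = 8, duration = 60, seed = 1, n_boot = 20))
  expect_equal(dim(res$indices), c(2, 4))
  expect_true(all(res$indices >= 0 & res$indices <= 1, na.rm = TRUE))
  expect_equal(res$max_S_T, apply(res$indices, 1, max))
})
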