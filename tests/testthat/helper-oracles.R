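# Independent reference implementations used as oracles.  Everything here
# is deliberately written without touching the package's compiled code
# paths: plain-R energies, optim-based minimisation, Monte Carlo chains.

rot_from_axis <- function(axis) {
  e1 <- c(1, 0, 0)
  v <- c(e1[2] * axis[3] - e1[3] * axis[2],
         e1[3] * axis[1] - e1[1] * axis[3],
         e1[1] * axis[2] - e1[2] * axis[1])
  s <- sqrt(sum(v^2)); c_ <- sum(e1 * axis)
  if (s < 1e-12) return(if (c_ > 0) diag(3) else diag(c(-1, -1, 1)))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

rodrigues_R <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Plain-R total energy of a pose: surface wells at the two pole sites plus
# elastic bound-pilus terms.  pili: data.frame(da_x..z, rb_x..z, l_eq).
energy_R <- function(center, R, pili, pot, r = 0.5, l = 3, E = 2000) {
  axis <- R[, 1]
  site <- function(gap) {
    u <- 0
    if (gap < 0) {
      u <- u + 0.5 * pot$wall_stiffness * gap^2
      if (pot$kind == "attractive_well") u <- u - pot$epsilon
    } else if (pot$kind == "attractive_well" && gap < pot$range) {
      u <- u - pot$epsilon * (1 - (gap / pot$range)^2)
    }
    u
  }
  e <- site(center[3] + (l / 2) * axis[3] - r) +
       site(center[3] - (l / 2) * axis[3] - r)
  if (!is.null(pili) && nrow(pili) > 0) {
    for (i in seq_len(nrow(pili))) {
      ra <- center + R %*% c(pili$da_x[i], pili$da_y[i], pili$da_z[i])
      rb <- c(pili$rb_x[i], pili$rb_y[i],
              if ("rb_z" %in% names(pili)) pili$rb_z[i] else 0)
      d <- sqrt(sum((ra - rb)^2))
      ext <- d - pili$l_eq[i]
      if (ext > 0) e <- e + 0.5 * E * ext^2 / pili$l_eq[i]
    }
  }
  e
}

# Brute-force 6-D rigid-body minimiser on the plain-R energy (translation
# plus axis-angle about the centre), refined in two stages.
brute_force_relax <- function(center, axis, pili, pot, r = 0.5, l = 3,
                              E = 2000, start = rep(0, 6)) {
  R0 <- rot_from_axis(axis)
  f <- function(x) {
    energy_R(center + x[1:3], rodrigues_R(x[4:6]) %*% R0, pili, pot,
             r = r, l = l, E = E)
  }
  o <- stats::optim(start, f, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  o <- stats::optim(o$par, f, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-15))
  list(value = o$value, par = o$par)
}

# Monte Carlo oracle for the expected lifetime of a single never-binding
# pilus under the four-state motor chain with stepped extension/retraction.
pilus_lifetime_oracle <- function(params, n = 2000) {
  rates <- c(ext_off = params$k_ext_off, ret_on = params$k_ret_on,
             ret_off = params$k_ret_off, ext_on = params$k_ext_on)
  step_ext <- params$v_ext / params$delta_step
  step_ret <- params$v_ret / params$delta_step
  one <- function() {
    len <- 1L; state <- "ext"; t <- 0
    repeat {
      rs <- switch(state,
        ext = c(step = step_ext, move = rates["ext_off"]),
        pe = c(move = rates["ret_on"]),
        ret = c(step = step_ret, move = rates["ret_off"]),
        pr = c(move = rates["ext_on"]))
      tot <- sum(rs)
      t <- t + rexp(1, tot)
      if (runif(1) * tot < rs[1] && names(rs)[1] == "step") {
        len <- len + if (state == "ext") 1L else -1L
        if (len == 0L) return(t)
      } else {
        state <- switch(state, ext = "pe", pe = "ret", ret = "pr", pr = "ext")
      }
    }
  }
  mean(replicate(n, one()))
}

# Metropolis sampler for the discrete WLC bend angles (target density
# proportional to sin(theta) * exp(-(Lp/(2 delta)) theta^2) per joint),
# independent of the package's direct sampler.
wlc_metropolis_chain <- function(n_seg, Lp, delta, n_sweep = 60) {
  c_ <- Lp / (2 * delta)
  logw <- function(th) {
    w <- rep(-Inf, length(th))
    ok <- th > 0 & th < pi
    w[ok] <- log(sin(th[ok])) - c_ * th[ok]^2
    w
  }
  th <- rep(0.1, n_seg - 1)
  ps <- runif(n_seg - 1, 0, 2 * pi)
  for (s in seq_len(n_sweep)) {
    prop <- th + rnorm(n_seg - 1, 0, 0.5 / sqrt(c_ + 1))
    acc <- log(runif(n_seg - 1)) < logw(prop) - logw(th)
    th[acc] <- prop[acc]
    ps <- ifelse(runif(n_seg - 1) < 0.5, runif(n_seg - 1, 0, 2 * pi), ps)
  }
  # build the chain from the angles
  t <- c(0, 0, 1)
  pos <- matrix(0, n_seg, 3)
  p <- c(0, 0, 0)
  for (i in seq_len(n_seg)) {
    if (i > 1) {
      ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- c(t[2] * ref[3] - t[3] * ref[2], t[3] * ref[1] - t[1] * ref[3],
             t[1] * ref[2] - t[2] * ref[1])
      u <- u / sqrt(sum(u^2))
      v <- c(t[2] * u[3] - t[3] * u[2], t[3] * u[1] - t[1] * u[3],
             t[1] * u[2] - t[2] * u[1])
      a <- th[i - 1]; b <- ps[i - 1]
      t <- cos(a) * t + sin(a) * (cos(b) * u + sin(b) * v)
      t <- t / sqrt(sum(t^2))
    }
    p <- p + delta * t
    pos[i, ] <- p
  }
  pos
}

# Closed-form Ishigami total-effect indices (a = 7, b = 0.1).
ishigami_truth <- function(a = 7, b = 0.1) {
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V13 <- 8 * b^2 * pi^8 / 225
  c(ST1 = (V1 + V13) / V, ST2 = (a^2 / 8) / V, ST3 = V13 / V)
}

ishigami_f <- function(X) {
  sin(X[, 1]) + 7 * sin(X[, 2])^2 + 0.1 * X[, 3]^4 * sin(X[, 1])
}

# Build a linearised-trajectory data frame directly from step velocities
# (unit step duration), bypassing track rendering; axis defaults to +x.
lin_from_velocities <- function(vx, vy, bx = 1, by = 0) {
  n <- length(vx)
  d <- data.frame(idx = seq_len(n), t0 = seq_len(n) - 1, t1 = seq_len(n),
                  x0 = 0, y0 = 0, x1 = vx, y1 = vy, dt = 1,
                  vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2),
                  bx = rep_len(bx, n), by = rep_len(by, n))
  class(d) <- c("linearised_trajectory", "data.frame")
  attr(d, "flagged") <- FALSE
  attr(d, "delta_step") <- NA_real_
  d
}

# Planar persistent-random-walk step velocities v_i = q v_{i-1} + a n_i.
prw_velocities <- function(n, q, a) {
  v <- matrix(0, n, 2)
  sd0 <- a / sqrt(1 - q^2)
  v[1, ] <- rnorm(2, 0, sd0)
  for (i in 2:n) v[i, ] <- q * v[i - 1, ] + a * rnorm(2)
  v
}

validation_params <- function() {
  sim_params(mode = "crawling", tau_dwell = 2.0, kappa = 2.5,
             v_ret = 0.09, k_spawn = 5.0)
}
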