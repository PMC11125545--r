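#' Generate synthetic tracking fixtures
#'
#' Produces noisy experimental-style pole tracks at 10 frames per second
#' for testing the analysis pipeline without real tracking data:
#' \describe{
#'   \item{straight}{uniform straight motion at a known speed.}
#'   \item{prw}{a persistent random walk generated at the linearised-step
#'     level (`v_i = q v_(i-1) + a n_i`, steps of 0.12 um contour) and
#'     rendered back onto the 0.1 s frame grid, so the summary-statistic
#'     estimators can be checked against known `q`, `a`.}
#'   \item{crawler, walker}{simulator-backed tracks in the corresponding
#'     mode.}
#' }
#' Isotropic Gaussian localisation noise of `noise_sd` is added to both
#' pole positions.  The generating truth is attached as attribute
#' `truth`.
#'
#' @param kind Fixture family.
#' @param n Number of tracks.
#' @param duration Track duration (s).
#' @param noise_sd Localisation noise (um).
#' @param speed Speed of the straight fixture (um/s).
#' @param q,a Persistence and activity of the PRW fixture.
#' @param params Simulation parameters for the simulator-backed kinds.
#' @param seed Integer seed.
#' @return A list of `twitch_trajectory` data frames (columns `t, x_lead,
#'   y_lead, x_trail, y_trail`), each with attribute `truth`.
#' @examples
#' fx <- make_fixtures("straight", n = 1, duration = 10, seed = 1)
#' nrow(linearise(fx[[1]])) # 0.06 um/s for 10 s: 5 steps of 0.12 um
#' @export
make_fixtures <- function(kind = c("straight", "prw", "crawler", "walker"),
                          n = 1, duration = 100, noise_sd = 0,
                          speed = 0.06, q = 0.42, a = 0.10,
                          params = NULL, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(noise_sd >= 0, n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  frame_dt <- 0.1
  body_l <- 3.0
  one <- function() {
    if (kind == "straight") {
      t <- seq(0, duration, frame_dt)
      ang <- runif(1, 0, 2 * pi)
      dir <- c(cos(ang), sin(ang))
      x <- speed * t * dir[1]; y <- speed * t * dir[2]
      tr <- data.frame(t = t, x_lead = x, y_lead = y,
                       x_trail = x - body_l * dir[1],
                       y_trail = y - body_l * dir[2])
      truth <- list(kind = kind, speed = speed, direction = dir)
    } else if (kind == "prw") {
      # step-level PRW; each 0.12 um step traversed at its own speed
      step_len <- 0.12
      sdv <- a / sqrt(1 - q^2)
      v <- matrix(0, 2, 1)
      v[, 1] <- rnorm(2, 0, sdv)
      pos <- matrix(0, nrow = 1, ncol = 2)
      times <- 0
      while (times[length(times)] < duration) {
        vn <- q * v[, ncol(v)] + a * rnorm(2)
        v <- cbind(v, vn)
        sp <- sqrt(sum(vn^2))
        if (sp < 1e-6) next
        dt <- step_len / sp
        pos <- rbind(pos, pos[nrow(pos), ] + vn * dt)
        times <- c(times, times[length(times)] + dt)
      }
      t <- seq(0, times[length(times)], frame_dt)
      x <- stats::approx(times, pos[, 1], xout = t)$y
      y <- stats::approx(times, pos[, 2], xout = t)$y
      # body axis follows the smoothed heading
      hx <- stats::filter(c(diff(x), 0), rep(1 / 20, 20), sides = 1)
      hy <- stats::filter(c(diff(y), 0), rep(1 / 20, 20), sides = 1)
      hn <- sqrt(hx^2 + hy^2)
      hx <- ifelse(is.na(hx) | hn < 1e-12, 1, hx / pmax(hn, 1e-12))
      hy <- ifelse(is.na(hy) | hn < 1e-12, 0, hy / pmax(hn, 1e-12))
      tr <- data.frame(t = t, x_lead = x, y_lead = y,
                       x_trail = x - body_l * hx,
                       y_trail = y - body_l * hy)
      truth <- list(kind = kind, q = q, a = a)
    } else {
      p <- params
      if (is.null(p))
        p <- sim_params(mode = if (kind == "crawler") "crawling" else "walking")
      sim <- simulate_twitching(p, duration = duration)
      tr <- sim$trajectory[, c("t", "x_lead", "y_lead", "x_trail", "y_trail")]
      truth <- list(kind = kind, params = p)
    }
    if (noise_sd > 0) {
      nf <- nrow(tr)
      tr$x_lead <- tr$x_lead + rnorm(nf, 0, noise_sd)
      tr$y_lead <- tr$y_lead + rnorm(nf, 0, noise_sd)
      tr$x_trail <- tr$x_trail + rnorm(nf, 0, noise_sd)
      tr$y_trail <- tr$y_trail + rnorm(nf, 0, noise_sd)
    }
    truth$noise_sd <- noise_sd
    class(tr) <- c("twitch_trajectory", "data.frame")
    attr(tr, "truth") <- truth
    tr
  }
  lapply(seq_len(n), function(i) one())
}
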