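#' Linearise a pole trajectory at a fixed step length
#'
#' Coarse-grains a tracked pole trajectory into steps of at least
#' `delta_step` by a greedy scan: starting from the first frame, the first
#' subsequent frame whose planar displacement from the previous accepted
#' point reaches `delta_step` is accepted, and the segment between
#' accepted points is treated as a straight step traversed in the elapsed
#' wall time.  Sub-threshold tracking noise is thereby removed.  The
#' leading and trailing poles are linearised independently.
#'
#' @param track A `twitch_sim`, a trajectory data frame with columns
#'   `t, x_lead, y_lead` (and optionally `x_trail, y_trail` for the body
#'   axis), or a plain data frame with columns `t, x, y`.
#' @param delta_step Step length (um).
#' @param pole `"leading"` or `"trailing"`.
#' @return A data frame of class `linearised_trajectory` with one row per
#'   step: accepted frame index `idx`, endpoints and times, step duration
#'   `dt`, velocity `vx, vy`, `speed`, and the surface-projected body axis
#'   `bx, by` at the step start (NA when the track has a single pole).
#'   Zero rows (with attribute `flagged`) when the path never reaches
#'   `delta_step`.
#' @examples
#' tr <- data.frame(t = seq(0, 10, 0.1), x = 0.06 * seq(0, 10, 0.1), y = 0)
#' nrow(linearise(tr)) # 5 steps of 0.12 um at 0.06 um/s
#' @export
linearise <- function(track, delta_step = 0.12,
                      pole = c("leading", "trailing")) {
  pole <- match.arg(pole)
  if (inherits(track, "twitch_sim")) track <- track$trajectory
  track <- as.data.frame(track)
  if (all(c("x_lead", "y_lead") %in% names(track))) {
    if (pole == "leading") { x <- track$x_lead; y <- track$y_lead }
    else { x <- track$x_trail; y <- track$y_trail }
    haxis <- all(c("x_trail", "y_trail") %in% names(track))
    if (haxis) {
      bx <- track$x_lead - track$x_trail
      by <- track$y_lead - track$y_trail
    }
  } else if (all(c("x", "y") %in% names(track))) {
    x <- track$x; y <- track$y
    haxis <- FALSE
  } else stop("track needs columns x_lead/y_lead or x/y")
  t <- track$t
  n <- length(t)
  if (n < 2) stop("track needs at least 2 frames")
  acc <- integer(n)
  na <- 1L
  acc[1L] <- 1L
  last <- 1L
  for (i in 2L:n) {
    dx <- x[i] - x[last]; dy <- y[i] - y[last]
    if (dx * dx + dy * dy >= delta_step^2) {
      na <- na + 1L
      acc[na] <- i
      last <- i
    }
  }
  acc <- acc[seq_len(na)]
  if (na < 2L) {
    out <- data.frame(idx = integer(0), t0 = numeric(0), t1 = numeric(0),
                      x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), dt = numeric(0), vx = numeric(0),
                      vy = numeric(0), speed = numeric(0), bx = numeric(0),
                      by = numeric(0))
    class(out) <- c("linearised_trajectory", "data.frame")
    attr(out, "flagged") <- TRUE
    attr(out, "delta_step") <- delta_step
    return(out)
  }
  i0 <- acc[-na]; i1 <- acc[-1L]
  dt <- t[i1] - t[i0]
  out <- data.frame(idx = i1, t0 = t[i0], t1 = t[i1],
                    x0 = x[i0], y0 = y[i0], x1 = x[i1], y1 = y[i1],
                    dt = dt, vx = (x[i1] - x[i0]) / dt,
                    vy = (y[i1] - y[i0]) / dt)
  out$speed <- sqrt(out$vx^2 + out$vy^2)
  if (haxis) { out$bx <- bx[i0]; out$by <- by[i0] }
  else { out$bx <- NA_real_; out$by <- NA_real_ }
  class(out) <- c("linearised_trajectory", "data.frame")
  attr(out, "flagged") <- FALSE
  attr(out, "delta_step") <- delta_step
  out
}

#' Persistent-random-walk summary statistics of linearised steps
#'
#' Computes the four trajectory statistics used to compare simulations
#' with tracking data, pooling steps over a set of trajectories:
#' \describe{
#'   \item{mean_speed}{mean linearised step speed, `<|v|>` (um/s).}
#'   \item{var_dev}{variance of the deviation angle between the
#'     surface-projected body axis (trailing to leading) and the step
#'     velocity, taken as the signed planar bearing in (-pi, pi\] (its
#'     mean vanishes by symmetry, so the variance is the mean-square
#'     deviation; rad^2).}
#'   \item{q_hat}{persistence of the fitted persistent random walk
#'     `v_i = q v_(i-1) + a n_i`:
#'     `sum(v_i . v_(i-1)) / sum(v_(i-1) . v_(i-1))` over consecutive
#'     within-trajectory step pairs.}
#'   \item{a_hat}{activity: `sqrt(sum |v_i - q_hat v_(i-1)|^2 / (2 n_pairs))`,
#'     the planar maximum-likelihood noise scale (um/s).}
#' }
#' Steps whose speed falls in the top `trim` fraction are discarded from
#' the persistence and activity estimates only (robustness to rare
#' tracking glitches); the mean speed and deviation-angle variance use all
#' steps.
#'
#' @param lin A `linearised_trajectory` or a list of them (pooled as one
#'   trajectory set; step pairs never straddle two trajectories).
#' @param trim Fraction of fastest steps excluded from `q_hat`/`a_hat`.
#' @return A list of class `twitch_summary_stats` with `mean_speed`,
#'   `var_dev`, `q_hat`, `a_hat`, `n_steps`, `n_pairs` and `flagged`
#'   (TRUE when fewer than 3 steps are available and the statistics are
#'   undefined).
#' @export
summary_stats <- function(lin, trim = 0.01) {
  if (inherits(lin, "linearised_trajectory")) lin <- list(lin)
  stopifnot(is.list(lin), trim >= 0, trim < 1)
  lin <- Filter(function(d) nrow(d) > 0, lin)
  steps <- if (length(lin)) do.call(rbind, lapply(seq_along(lin), function(i) {
    d <- as.data.frame(lin[[i]]); d$.traj <- i; d
  })) else NULL
  n <- if (is.null(steps)) 0L else nrow(steps)
  if (n < 3L) {
    return(structure(list(mean_speed = NA_real_, var_dev = NA_real_,
                          q_hat = NA_real_, a_hat = NA_real_,
                          n_steps = n, n_pairs = 0L, flagged = TRUE),
                     class = "twitch_summary_stats"))
  }
  mean_speed <- mean(steps$speed)
  bn <- sqrt(steps$bx^2 + steps$by^2)
  ok <- is.finite(bn) & bn > 0 & steps$speed > 0
  var_dev <- if (any(ok)) {
    # signed planar bearing of the step velocity relative to the body
    # axis; zero-mean by left-right symmetry, so the variance reads the
    # mean-square deviation from straight-ahead motion
    theta <- atan2(steps$bx[ok] * steps$vy[ok] - steps$by[ok] * steps$vx[ok],
                   steps$bx[ok] * steps$vx[ok] + steps$by[ok] * steps$vy[ok])
    stats::var(theta)
  } else NA_real_
  # trim the fastest steps for the PRW estimators only; at least one
  # step is discarded so that small pooled samples are protected too
  keep <- if (trim > 0) {
    k_drop <- max(1L, ceiling(trim * n))
    rank(-steps$speed, ties.method = "first") > k_drop
  } else rep(TRUE, n)
  pair_i <- 2:n
  valid <- steps$.traj[pair_i] == steps$.traj[pair_i - 1L] &
    keep[pair_i] & keep[pair_i - 1L]
  pi1 <- pair_i[valid]; pi0 <- pi1 - 1L
  n_pairs <- length(pi1)
  if (n_pairs < 2L) {
    return(structure(list(mean_speed = mean_speed, var_dev = var_dev,
                          q_hat = NA_real_, a_hat = NA_real_,
                          n_steps = n, n_pairs = n_pairs, flagged = TRUE),
                     class = "twitch_summary_stats"))
  }
  num <- sum(steps$vx[pi1] * steps$vx[pi0] + steps$vy[pi1] * steps$vy[pi0])
  den <- sum(steps$vx[pi0]^2 + steps$vy[pi0]^2)
  q_hat <- num / den
  res2 <- (steps$vx[pi1] - q_hat * steps$vx[pi0])^2 +
    (steps$vy[pi1] - q_hat * steps$vy[pi0])^2
  a_hat <- sqrt(sum(res2) / (2 * n_pairs))
  structure(list(mean_speed = mean_speed, var_dev = var_dev,
                 q_hat = q_hat, a_hat = a_hat,
                 n_steps = n, n_pairs = n_pairs, flagged = FALSE),
            class = "twitch_summary_stats")
}

#' @export
print.twitch_summary_stats <- function(x, ...) {
  cat(sprintf(
    "<twitch_summary_stats> n=%d steps (%d pairs)%s\n", x$n_steps, x$n_pairs,
    if (isTRUE(x$flagged)) " [flagged: undefined]" else ""))
  cat(sprintf("  <u> = %.4g um/s   Var(theta_d) = %.4g rad^2\n",
              x$mean_speed, x$var_dev))
  cat(sprintf("  q^  = %.4g         a^ = %.4g um/s\n", x$q_hat, x$a_hat))
  invisible(x)
}

#' @export
as.double.twitch_summary_stats <- function(x, ...) {
  c(mean_speed = x$mean_speed, var_dev = x$var_dev,
    q_hat = x$q_hat, a_hat = x$a_hat)
}

#' Extract the four summary statistics as a named vector
#'
#' @param x A `twitch_summary_stats` object.
#' @return Named numeric of length 4: `mean_speed`, `var_dev`, `q_hat`,
#'   `a_hat`.
#' @export
stats_vector <- function(x) {
  stopifnot(inherits(x, "twitch_summary_stats"))
  c(mean_speed = x$mean_speed, var_dev = x$var_dev,
    q_hat = x$q_hat, a_hat = x$a_hat)
}

#' Mean-squared-displacement scaling exponent
#'
#' Fits `<delta(tau)^2> ~ tau^k` by least squares on log--log axes, with
#' the MSD averaged over all start frames, over lag times between
#' `tau_min` and a quarter of the track duration (short-time stochastic
#' structure is excluded by `tau_min`).  k = 1 is diffusive, k = 2
#' ballistic.
#'
#' @param track As in [linearise()].
#' @param tau_min Smallest lag time (s).
#' @param n_tau Number of log-spaced lag times.
#' @param pole Which pole to use.
#' @return The exponent `k`, with the fitted MSD curve in attribute
#'   `msd` (data frame `tau`, `msd`).
#' @export
msd_exponent <- function(track, tau_min = 2, n_tau = 25,
                         pole = c("leading", "trailing")) {
  pole <- match.arg(pole)
  if (inherits(track, "twitch_sim")) track <- track$trajectory
  track <- as.data.frame(track)
  if (all(c("x_lead", "y_lead") %in% names(track))) {
    if (pole == "leading") { x <- track$x_lead; y <- track$y_lead }
    else { x <- track$x_trail; y <- track$y_trail }
  } else { x <- track$x; y <- track$y }
  t <- track$t
  dt <- stats::median(diff(t))
  Tdur <- t[length(t)] - t[1]
  if (Tdur <= 2 * tau_min)
    stop("track duration must exceed 2 * tau_min; insufficient span")
  tau_max <- Tdur / 4
  if (tau_max <= tau_min) stop("insufficient span: duration/4 <= tau_min")
  lags <- unique(round(exp(seq(log(tau_min / dt), log(tau_max / dt),
                               length.out = n_tau))))
  lags <- lags[lags >= 1 & lags < length(t)]
  msd <- vapply(lags, function(L) {
    i <- seq_len(length(t) - L)
    mean((x[i + L] - x[i])^2 + (y[i + L] - y[i])^2)
  }, numeric(1))
  okm <- msd > 0
  fit <- stats::lm(log(msd[okm]) ~ log(lags[okm] * dt))
  k <- unname(coef(fit)[2])
  attr(k, "msd") <- data.frame(tau = lags * dt, msd = msd)
  k
}

#' Classify a trajectory as walking or crawling
#'
#' Uses the projected aspect ratio b_t (body length over width of the
#' surface projection).  For a simulated spherocylinder,
#' b_t = (l |cos phi| + 2 r) / (2 r) with phi the axis tilt out of the
#' surface plane.  The series is smoothed with a sliding-window mean of
#' `window` frames and its minimum b_min taken; trajectories with
#' b_min > `threshold` are crawling, the rest walking (an upright body
#' projects to a circle, b_t = 1).
#'
#' @param x A `twitch_sim`, a trajectory data frame with axis columns
#'   `bx, by, bz`, or a numeric aspect-ratio series.
#' @param window Sliding window length in frames.
#' @param threshold Classification threshold on b_min (strict >).
#' @param r,l Body dimensions used for the projection formula.
#' @return A list with `label` (`"walking"`/`"crawling"`), `b_min`,
#'   the aspect series `aspect`, and `flagged` (TRUE when the series is
#'   shorter than `window` and a single mean was used).
#' @export
classify_trajectory <- function(x, window = 200, threshold = 1.6,
                                r = 0.5, l = 3.0) {
  if (inherits(x, "twitch_sim")) {
    r <- x$params$r; l <- x$params$l
    x <- x$trajectory
  }
  if (is.data.frame(x)) {
    if (!all(c("bx", "by", "bz") %in% names(x)))
      stop("trajectory lacks body-axis columns bx, by, bz")
    nrm <- sqrt(x$bx^2 + x$by^2 + x$bz^2)
    inplane <- sqrt(x$bx^2 + x$by^2) / nrm
    aspect <- (l * inplane + 2 * r) / (2 * r)
  } else {
    aspect <- as.numeric(x)
  }
  n <- length(aspect)
  flagged <- n < window
  if (flagged) {
    b_min <- mean(aspect)
  } else {
    cs <- cumsum(c(0, aspect))
    means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
    b_min <- min(means)
  }
  list(label = if (b_min > threshold) "crawling" else "walking",
       b_min = b_min, aspect = aspect, flagged = flagged)
}

#' Time of a walking/crawling transition
#'
#' For a simulated trajectory with pose information, finds the first frame
#' at which the trailing-pole surface contact changes: a crawling start
#' transitions to walking when the trailing-pole gap exceeds the contact
#' cutoff (the surface-well range), and a walking start transitions to
#' crawling when the trailing pole comes within the cutoff.  When no
#' transition occurs the maximum time is returned.
#'
#' @param sim A `twitch_sim` (or trajectory data frame with `z_trail`).
#' @param direction `"crawling_to_walking"` or `"walking_to_crawling"`.
#' @param cutoff Contact cutoff on the trailing-pole gap (um); defaults to
#'   the surface-well range of the simulation parameters (0.05 um
#'   otherwise).
#' @param r Body radius, taken from the simulation when available.
#' @param t_max Value returned when no transition occurs; defaults to the
#'   last frame time.
#' @return The transition time tau_w (s), with attribute `transitioned`.
#' @export
transition_time <- function(sim,
                            direction = c("crawling_to_walking",
                                          "walking_to_crawling"),
                            cutoff = NULL, r = 0.5, t_max = NULL) {
  direction <- match.arg(direction)
  if (inherits(sim, "twitch_sim")) {
    if (is.null(cutoff)) cutoff <- sim$params$surface$range
    r <- sim$params$r
    tr <- sim$trajectory
  } else tr <- as.data.frame(sim)
  if (is.null(cutoff)) cutoff <- 0.05
  if (!"z_trail" %in% names(tr))
    stop("transition_time needs the trailing-pole z coordinate")
  gap <- tr$z_trail - r
  if (is.null(t_max)) t_max <- tr$t[nrow(tr)]
  hit <- if (direction == "crawling_to_walking") which(gap > cutoff)
         else which(gap <= cutoff)
  if (length(hit) == 0) {
    out <- t_max
    attr(out, "transitioned") <- FALSE
  } else {
    out <- tr$t[hit[1]]
    attr(out, "transitioned") <- TRUE
  }
  out
}
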