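#' Prior box for parameter inference
#'
#' The minimal twitching model keeps four free parameters; their uniform
#' prior bounds span the physically plausible ranges seen across twitching
#' experiments: dwell time tau_dwell in \[0.05, 3\] s, anchor concentration
#' kappa in \[1, 15\], retraction speed v_ret in \[0.01, 1\] um/s and spawn
#' rate k_spawn in \[0.1, 8\] per s.
#'
#' @return A [parameter_box()] over the four inferred parameters.
#' @export
abc_prior <- function() {
  parameter_box(name = c("tau_dwell", "kappa", "v_ret", "k_spawn"),
                min = c(0.05, 1.0, 0.01, 0.1),
                max = c(3.0, 15.0, 1.0, 8.0),
                unit = c("s", "", "um/s", "1/s"))
}

#' Evaluate the summary statistics of one parameter sample
#'
#' Simulates trajectories at the given parameter values and pools their
#' linearised steps until either `max_traj` trajectories have been run or
#' the accumulated trajectory data reaches `target_steps` linearised
#' steps (i.e. a total contour length of `target_steps * delta_step`),
#' then computes the four summary statistics plus simulation-only
#' diagnostics.
#'
#' @param theta Named numeric: values for (a subset of) [sim_params()]
#'   fields, typically `tau_dwell, kappa, v_ret, k_spawn`.
#' @param base_params Baseline [sim_params()] overwritten by `theta`.
#' @param duration Seconds per trajectory.
#' @param max_traj Maximum trajectories per sample.
#' @param target_steps Stop once this many pooled linearised steps have
#'   accumulated.
#' @param delta_step Linearisation step (um).
#' @param trim Velocity trim fraction for the persistence estimators.
#' @param seed Integer seed.
#' @return A list with `stats` (named length-4 vector), `n_steps`,
#'   `n_traj`, and `diagnostics` (`n_taut`, `n_bound`, `n_total` frame
#'   means, `mean_dx`, `contact_fraction`).  Statistics are NA (and
#'   `n_steps` 0) when no linearised steps exist; such samples can never
#'   be accepted.
#' @export
evaluate_sample <- function(theta, base_params = sim_params(mode = "crawling"),
                            duration = 2000, max_traj = 10,
                            target_steps = 1000, delta_step = 0.12,
                            trim = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- do.call(update_params, c(list(base_params), as.list(theta)))
  lins <- list()
  n_steps <- 0L
  diag_acc <- c(n_taut = 0, n_bound = 0, n_total = 0)
  dx <- contact <- numeric(0)
  n_traj <- 0L
  while (n_traj < max_traj && n_steps < target_steps) {
    sim <- suppressWarnings(simulate_twitching(p, duration = duration))
    n_traj <- n_traj + 1L
    l <- linearise(sim, delta_step = delta_step)
    lins[[n_traj]] <- l
    n_steps <- n_steps + nrow(l)
    d <- tfp_diagnostics(sim)
    diag_acc <- diag_acc + c(d$mean_taut, d$mean_bound, d$mean_total)
    done <- sim$pili[!is.na(sim$pili$t_end), , drop = FALSE]
    dx <- c(dx, done$dx)
    contact <- c(contact, done$ever_bound)
  }
  s <- summary_stats(lins, trim = trim)
  list(stats = stats_vector(s), n_steps = s$n_steps, n_traj = n_traj,
       diagnostics = c(diag_acc / n_traj,
                       mean_dx = if (length(dx)) mean(dx) else NA_real_,
                       contact_fraction = if (length(contact))
                         mean(contact) else NA_real_))
}

#' Rejection approximate Bayesian computation
#'
#' Draws `n` parameter samples from the uniform prior, simulates each and
#' reduces it to the four summary statistics, standardises every
#' statistic by its standard deviation across all samples (the reference
#' is standardised identically), and accepts the `m` samples closest to
#' the reference in Euclidean distance.  Accepted samples are weighted
#' with an Epanechnikov kernel of width epsilon = the m-th smallest
#' distance: w = 1 - (rho / epsilon)^2.
#'
#' @param reference Named numeric length-4 reference statistics
#'   (`mean_speed`, `var_dev`, `q_hat`, `a_hat`), e.g. from a simulated
#'   validation data set or published values.
#' @param prior A [parameter_box()]; defaults to [abc_prior()].
#' @param n Number of prior samples.
#' @param m Number accepted (`2 <= m <= n`).
#' @param base_params,mode Baseline simulation setup; `mode` selects
#'   crawling or walking simulations.
#' @param duration,max_traj,target_steps,delta_step,trim Per-sample
#'   simulation budget, passed to [evaluate_sample()].
#' @param seed Master seed; per-sample streams are derived from it so the
#'   run is reproducible.
#' @param progress Print a dot every 25 samples.
#' @return An object of class `abc_result`: list with `samples` (data
#'   frame of parameters, raw statistics, diagnostics, distance `rho`,
#'   `accepted`, `weight`), `reference`, `epsilon`, `scale` (the
#'   standardising SDs), `prior` and bookkeeping fields.
#' @export
rejection_abc <- function(reference, prior = abc_prior(), n = 10000, m = 50,
                          base_params = sim_params(mode = "crawling"),
                          mode = c("crawling", "walking"),
                          duration = 2000, max_traj = 10,
                          target_steps = 1000, delta_step = 0.12,
                          trim = 0.01, seed = 1, progress = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(prior, "parameter_box"), n >= m, m >= 2)
  stat_names <- c("mean_speed", "var_dev", "q_hat", "a_hat")
  reference <- reference[stat_names]
  if (any(!is.finite(reference))) stop("reference statistics must be finite")
  base_params$mode <- mode
  if (mode == "walking" && base_params$surface$kind != "repulsive")
    base_params$surface <- surface_potential("repulsive")
  set.seed(as.integer(seed))
  d <- nrow(prior)
  theta <- vapply(seq_len(d),
                  function(j) runif(n, prior$min[j], prior$max[j]),
                  numeric(n))
  colnames(theta) <- prior$name
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
  S <- matrix(NA_real_, n, 4, dimnames = list(NULL, stat_names))
  diag_names <- c("n_taut", "n_bound", "n_total", "mean_dx",
                  "contact_fraction")
  DG <- matrix(NA_real_, n, 5, dimnames = list(NULL, diag_names))
  n_steps <- integer(n)
  for (i in seq_len(n)) {
    ev <- evaluate_sample(theta[i, ], base_params = base_params,
                          duration = duration, max_traj = max_traj,
                          target_steps = target_steps,
                          delta_step = delta_step, trim = trim,
                          seed = sample_seeds[i])
    S[i, ] <- ev$stats
    DG[i, ] <- ev$diagnostics
    n_steps[i] <- ev$n_steps
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  rej <- abc_reject(S, reference, m)
  samples <- data.frame(theta, S, DG, n_steps = n_steps, rho = rej$rho,
                        accepted = rej$accepted, weight = rej$weight)
  structure(list(samples = samples, reference = reference,
                 epsilon = rej$epsilon, scale = rej$scale,
                 used_stats = rej$used_stats, prior = prior,
                 n = n, m = m, mode = mode, seed = seed),
            class = "abc_result")
}

#' Rejection step of approximate Bayesian computation
#'
#' The model-agnostic core of [rejection_abc()]: given a matrix of summary
#' statistics (one row per parameter sample) and the reference statistics,
#' standardises every column by its standard deviation across samples,
#' computes Euclidean distances, accepts the `m` closest samples and
#' weights them with an Epanechnikov kernel of width equal to the m-th
#' smallest distance.  Degenerate columns (zero spread) are dropped from
#' the distance with a warning; rows with undefined statistics get
#' infinite distance and are never accepted.
#'
#' @param S Numeric matrix of summary statistics (samples x statistics).
#' @param reference Numeric vector of reference statistics (recycled to
#'   the columns of `S` by name when both are named).
#' @param m Number of samples to accept.
#' @return A list with `rho`, `accepted`, `weight`, `epsilon`, `scale`
#'   and `used_stats`.
#' @export
abc_reject <- function(S, reference, m) {
  S <- as.matrix(S)
  stopifnot(m >= 1, m <= nrow(S))
  if (!is.null(colnames(S)) && !is.null(names(reference)))
    reference <- reference[colnames(S)]
  stopifnot(length(reference) == ncol(S))
  scale <- apply(S, 2, stats::sd, na.rm = TRUE)
  use <- is.finite(scale) & scale > 0
  if (!all(use))
    warning("dropping degenerate statistic(s) from the distance: ",
            paste(colnames(S)[!use], collapse = ", "))
  Z <- sweep(S[, use, drop = FALSE], 2, scale[use], "/")
  zref <- reference[use] / scale[use]
  rho <- sqrt(rowSums(sweep(Z, 2, zref, "-")^2))
  rho[!is.finite(rho)] <- Inf # undefined statistics are never accepted
  eps <- sort(rho)[m]
  accepted <- rank(rho, ties.method = "first") <= m
  weight <- ifelse(accepted, pmax(0, 1 - (rho / eps)^2), 0)
  list(rho = rho, accepted = accepted, weight = weight, epsilon = eps,
       scale = scale, used_stats = colnames(S)[use])
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("<abc_result> %s: accepted %d / %d samples (epsilon = %.3g)\n",
              x$mode, x$m, x$n, x$epsilon))
  acc <- x$samples[x$samples$accepted, x$prior$name, drop = FALSE]
  print(round(vapply(acc, stats::median, numeric(1)), 3))
  invisible(x)
}

# Weighted Gaussian KDE evaluated on a grid.
.wkde <- function(x, w, grid, h) {
  w <- w / sum(w)
  f <- vapply(grid, function(g) sum(w * stats::dnorm(g, x, h)), numeric(1))
  f
}

# Weighted least-squares cross-validation score for the bandwidth of a
# 1-D weighted Gaussian KDE (exact Gaussian convolutions).
.wlscv <- function(x, w, h) {
  w <- w / sum(w)
  n <- length(x)
  dx <- outer(x, x, "-")
  term1 <- sum(outer(w, w) * stats::dnorm(dx, sd = sqrt(2) * h))
  phi <- stats::dnorm(dx, sd = h)
  diag(phi) <- 0
  loo <- colSums(w * phi) / (1 - w) # f_{-i}(x_i), weights renormalised
  term1 - 2 * sum(w * loo)
}

# Weighted Silverman rule-of-thumb bandwidth.
.silverman_w <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sdw <- sqrt(sum(w * (x - mu)^2))
  n_eff <- 1 / sum(w^2)
  max(1.06 * sdw * n_eff^(-1 / 5), 1e-8)
}

#' Posterior summaries from accepted ABC samples
#'
#' Smooths the weighted accepted samples of every parameter with a
#' weighted Gaussian kernel density estimate whose bandwidth is chosen by
#' weighted least-squares cross-validation (Silverman's rule as a
#' fallback when the CV criterion has no interior minimum).  Reports the
#' density mode as the maximum-likelihood estimate and the central 5%
#' to 95% mass of the smoothed density as the 90% interval, plus the
#' Pearson correlation matrix of the accepted parameters and diagnostics.
#'
#' @param abc An [rejection_abc()] result.
#' @param n_grid Evaluation grid size per parameter.
#' @param conf Interval mass (0.9 = central 90%).
#' @return An object of class `abc_posterior`: list with `summary` (data
#'   frame: parameter, `mle`, `ci_lo`, `ci_hi`, `bandwidth`,
#'   `bw_method`), `densities` (per-parameter data frames `x`, `density`),
#'   and `correlations`.
#' @export
posterior_summaries <- function(abc, n_grid = 512, conf = 0.90) {
  stopifnot(inherits(abc, "abc_result"))
  acc <- abc$samples[abc$samples$accepted, , drop = FALSE]
  if (nrow(acc) < 2) stop("need at least 2 accepted samples")
  if (nrow(acc) < 10)
    warning("fewer than 10 accepted samples; posterior summaries are crude")
  w <- acc$weight
  if (all(w <= 0)) w <- rep(1, nrow(acc))
  if (sum(w > 0) == 1)
    warning("all posterior weight on a single sample; degenerate KDE")
  prior <- abc$prior
  alpha <- (1 - conf) / 2
  dens <- list()
  rows <- lapply(seq_len(nrow(prior)), function(j) {
    x <- acc[[prior$name[j]]]
    lo <- prior$min[j]; hi <- prior$max[j]
    h0 <- .silverman_w(x, w)
    method <- "lscv"
    h <- tryCatch({
      hs <- exp(seq(log(h0 / 8), log(h0 * 4), length.out = 30))
      sc <- vapply(hs, function(hh) .wlscv(x, w, hh), numeric(1))
      best <- which.min(sc)
      if (best == 1L || best == length(hs) || !is.finite(sc[best])) {
        method <<- "silverman"
        h0
      } else hs[best]
    }, error = function(e) { method <<- "silverman"; h0 })
    grid <- seq(lo, hi, length.out = n_grid)
    # a bandwidth below the grid resolution would put all the density
    # between grid points; floor it at one grid spacing
    h <- max(h, grid[2] - grid[1])
    f <- .wkde(x, w, grid, h)
    # normalise on the prior box (trapezoid) and take central quantiles
    dxg <- grid[2] - grid[1]
    cw <- cumsum((c(0, f[-1] + f[-n_grid]) / 2) * dxg)
    tot <- cw[n_grid]
    mle <- grid[which.max(f)]
    qs <- stats::approx(cw / tot, grid, xout = c(alpha, 1 - alpha),
                        ties = "ordered")$y
    dens[[prior$name[j]]] <<- data.frame(x = grid, density = f / tot)
    data.frame(parameter = prior$name[j], mle = mle,
               ci_lo = max(qs[1], lo), ci_hi = min(qs[2], hi),
               bandwidth = h, bw_method = method,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  corr_cols <- c(prior$name, "n_taut", "n_bound", "mean_dx",
                 "contact_fraction")
  corr_cols <- corr_cols[corr_cols %in% names(acc)]
  cc <- acc[, corr_cols, drop = FALSE]
  cc <- cc[, vapply(cc, function(v) stats::sd(v, na.rm = TRUE) > 0,
                    logical(1)), drop = FALSE]
  correlations <- if (ncol(cc) >= 2)
    stats::cor(cc, use = "pairwise.complete.obs") else NULL
  structure(list(summary = summary, densities = dens,
                 correlations = correlations, conf = conf),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("<abc_posterior> MLE and central %d%% intervals\n",
              round(100 * x$conf)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %.3g  [%.3g, %.3g]  (h=%.3g, %s)\n",
                s$parameter[i], s$mle[i], s$ci_lo[i], s$ci_hi[i],
                s$bandwidth[i], s$bw_method[i]))
  invisible(x)
}

#' Dispersion of a statistic among accepted samples
#'
#' The ratio of the standard deviation of a recorded quantity over the
#' accepted samples to that over all samples.  Ratios well below one mark
#' quantities that the summary statistics pin down (invariants of the
#' matched trajectories); ratios near one mark quantities the data leave
#' unconstrained.
#'
#' @param abc An [rejection_abc()] result.
#' @param statistic Column name of `abc$samples` (e.g. `"n_taut"`,
#'   `"mean_dx"`).
#' @return `sd(accepted) / sd(all)` (unweighted).
#' @export
accepted_dispersion <- function(abc, statistic) {
  stopifnot(inherits(abc, "abc_result"))
  v <- abc$samples[[statistic]]
  if (is.null(v)) stop("no such recorded statistic: ", statistic)
  s_all <- stats::sd(v, na.rm = TRUE)
  if (!is.finite(s_all) || s_all == 0)
    stop("statistic has zero dispersion across all samples")
  stats::sd(v[abc$samples$accepted], na.rm = TRUE) / s_all
}
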