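#' Simulate a twitching trajectory
#'
#' Runs the event-driven (kinetic Monte Carlo) simulation: waiting times
#' are exponential in the total event rate and single-TFP events (spawn,
#' chain resampling, motor transitions, extension/retraction steps of size
#' `delta_step`, surface binding and detachment) are selected with
#' probability proportional to their rates.  After every event that
#' changes the geometry of the bound-pilus set the rigid body is relaxed
#' to mechanical equilibrium; free pili do not influence the body.  Pole
#' positions, the body axis and pilus counts are recorded on a uniform
#' `frame_dt` grid (the state is piecewise constant between events).
#'
#' Crawling simulations start horizontal with both poles in surface
#' contact; walking simulations start upright with the piliated pole down.
#' Given the same `params` and `seed` the trajectory is reproducible
#' bit for bit.
#'
#' @param params A [sim_params()] object.
#' @param duration Simulated time (s).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param init_pili Optional data frame of pre-existing pili with columns
#'   `da_x, da_y, da_z` (body-frame anchor offset), `na_x, na_y, na_z`
#'   (anchor normal), `n_seg`, `bound` (logical), `rb_x, rb_y, rb_z`
#'   (attachment, used when bound) and `motor` (0 extending, 1 passive,
#'   2 retracting, 3 passive, 5 bound-retracting).  Mainly for controlled
#'   experiments and tests.
#' @param binding Set `FALSE` to disable surface binding entirely (used
#'   for pilus life-cycle diagnostics such as the birth--death balance of
#'   the free-pilus population).
#' @return An object of class `twitch_sim`: a list with `trajectory`
#'   (data frame: `t`, leading/trailing pole xyz, body axis, pilus counts
#'   including bound, taut and visibility-thresholded counts), `pili`
#'   (per-pilus lifetime table), `params`, and event/relaxation counters.
#' @examples
#' sim <- simulate_twitching(sim_params(), duration = 5, seed = 1)
#' head(sim$trajectory)
#' @export
simulate_twitching <- function(params, duration = 2000, seed = NULL,
                               init_pili = NULL, binding = TRUE) {
  stopifnot(inherits(params, "sim_params"), duration > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  par <- unclass(params)
  par$surface <- .pot_cpp(params$surface)
  par$duration <- duration
  par$enable_binding <- isTRUE(binding)
  if (!is.null(init_pili)) {
    need <- c("da_x", "da_y", "da_z", "na_x", "na_y", "na_z",
              "n_seg", "bound", "rb_x", "rb_y", "rb_z", "motor")
    miss <- setdiff(need, names(init_pili))
    if (length(miss)) stop("init_pili lacks columns: ", paste(miss, collapse = ", "))
    par$init_pili <- as.matrix(as.data.frame(init_pili)[, need])
  }
  res <- .cpp_simulate(par)
  traj <- as.data.frame(res$frames)
  class(traj) <- c("twitch_trajectory", "data.frame")
  pili <- as.data.frame(res$pili)
  pili$ever_bound <- pili$ever_bound > 0
  if (res$n_relax_fail > 0)
    warning(res$n_relax_fail, " of ", res$n_relax,
            " relaxations did not reach tolerance; simulation continued")
  structure(list(trajectory = traj, pili = pili, params = params,
                 duration = duration, seed = seed,
                 n_events = res$n_events, n_relax = res$n_relax,
                 n_relax_fail = res$n_relax_fail,
                 disp_ret = res$disp_ret, disp_other = res$disp_other),
            class = "twitch_sim")
}

#' @export
print.twitch_sim <- function(x, ...) {
  cat(sprintf("<twitch_sim> %s, %g s, %d frames, %s events\n",
              x$params$mode, x$duration, nrow(x$trajectory),
              format(x$n_events, big.mark = ",")))
  cat(sprintf("  pili spawned: %d  mean counts: total %.2f bound %.2f taut %.2f\n",
              nrow(x$pili), mean(x$trajectory$n_tfp),
              mean(x$trajectory$n_bound), mean(x$trajectory$n_taut)))
  invisible(x)
}

#' Assemble the event-rate table for a simulation state
#'
#' Returns the per-event rates the kinetic Monte Carlo step draws from, as
#' a data frame.  `state` describes the pilus population: a data frame
#' with columns `bound` (logical), `motor` (`"extending"`,
#' `"passive_ext"`, `"retracting"`, `"passive_ret"` for free pili) and
#' `stalled` (logical, bound pili only).  Free pili carry a resampling
#' event and the motor state machine (extending pili also step out at
#' `v_ext / delta_step`, free retracting pili step in at
#' `v_ret / delta_step`); bound pili detach at `1 / tau_dwell` and, unless
#' stalled, take retraction steps.  In the surface-sensing limit
#' (`tau_delay = 0`) bound pili are always retracting.
#'
#' @param state A data frame as above; use `NULL` or an empty frame for a
#'   pilus-free state.
#' @param params A [sim_params()] object.
#' @return A data frame with columns `pilus` (0 = global spawn event),
#'   `event` and `rate` (1/s); attribute `total` holds the summed rate.
#' @examples
#' event_rates(NULL, sim_params())            # only the spawn channel
#' @export
event_rates <- function(state, params) {
  stopifnot(inherits(params, "sim_params"))
  rows <- list(data.frame(pilus = 0L, event = "spawn",
                          rate = params$k_spawn))
  if (!is.null(state) && nrow(state) > 0) {
    k_det <- if (is.finite(params$tau_dwell) && params$tau_dwell > 0)
      1 / params$tau_dwell else 0
    for (i in seq_len(nrow(state))) {
      b <- isTRUE(state$bound[i])
      if (b) {
        rows[[length(rows) + 1L]] <-
          data.frame(pilus = i, event = "detach", rate = k_det)
        if (!isTRUE(state$stalled[i]))
          rows[[length(rows) + 1L]] <-
            data.frame(pilus = i, event = "retract_step",
                       rate = params$v_ret / params$delta_step)
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(pilus = i, event = "resample", rate = params$k_resample)
        motor <- as.character(state$motor[i])
        tr <- switch(motor,
          extending = data.frame(pilus = i,
                                 event = c("ext_motor_off", "extend_step"),
                                 rate = c(params$k_ext_off,
                                          params$v_ext / params$delta_step)),
          passive_ext = data.frame(pilus = i, event = "ret_motor_on",
                                   rate = params$k_ret_on),
          retracting = data.frame(pilus = i,
                                  event = c("ret_motor_off", "retract_step"),
                                  rate = c(params$k_ret_off,
                                           params$v_ret / params$delta_step)),
          passive_ret = data.frame(pilus = i, event = "ext_motor_on",
                                   rate = params$k_ext_on),
          stop("unknown motor state: ", motor))
        rows[[length(rows) + 1L]] <- tr
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$rate > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- sum(out$rate)
  out
}

#' Pilus-level diagnostics of a simulation
#'
#' Summarises quantities that tracking experiments cannot observe: mean
#' numbers of total, bound and taut pili per frame, counts of pili long
#' enough to be visible at the optical thresholds 0.3 um and 1.0 um, the
#' mean per-pilus displacement (leading-pole displacement summed over each
#' pilus' own retraction events across its lifetime) and the fraction of
#' pili that touched the surface before dissolving.
#'
#' @param sim A [simulate_twitching()] result.
#' @return A list with `mean_total`, `mean_bound`, `mean_taut`,
#'   `mean_visible` (named numeric for thresholds 0, 0.3 and 1.0 um),
#'   `mean_dx` (um), `contact_fraction`, and `n_completed` (pili with
#'   complete lifetimes; survivors at the end of the run are censored and
#'   excluded from `mean_dx` and `contact_fraction`).
#' @export
tfp_diagnostics <- function(sim) {
  stopifnot(inherits(sim, "twitch_sim"))
  tr <- sim$trajectory
  done <- sim$pili[!is.na(sim$pili$t_end), , drop = FALSE]
  list(mean_total = mean(tr$n_tfp),
       mean_bound = mean(tr$n_bound),
       mean_taut = mean(tr$n_taut),
       mean_visible = c(`0` = mean(tr$n_tfp), `0.3` = mean(tr$n_vis03),
                        `1` = mean(tr$n_vis10)),
       mean_dx = if (nrow(done)) mean(done$dx) else NA_real_,
       contact_fraction = if (nrow(done)) mean(done$ever_bound) else NA_real_,
       n_completed = nrow(done))
}
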