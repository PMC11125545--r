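#' Read and write trajectory tables
#'
#' Trajectories are exchanged as comma-separated text with a header row
#' and `#` provenance comments (ignored on reading): one row per 0.1 s
#' frame with columns `t, x_lead, y_lead, z_lead, x_trail, y_trail,
#' z_trail, bx, by, bz, n_tfp, n_bound, n_taut` (simulated tables carry
#' all columns; experimental-style tables may omit the z/axis/count
#' columns).  Positions are in um, times in s.
#'
#' @param x A `twitch_sim`, `twitch_trajectory` or plain data frame.
#' @param path File path.
#' @param comments Extra provenance comment lines (without the leading
#'   `#`).
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `twitch_trajectory` data frame.
#' @export
write_trajectory <- function(x, path, comments = character()) {
  if (inherits(x, "twitch_sim")) {
    comments <- c(comments,
                  sprintf("mode: %s", x$params$mode),
                  sprintf("seed: %s", format(x$seed)),
                  sprintf("duration_s: %g", x$duration))
    x <- x$trajectory
  }
  x <- as.data.frame(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# twitchsim trajectory (twitchsim %s)",
                       as.character(utils::packageVersion("twitchsim"))),
               "# units: um, s; surface plane z = 0",
               paste0("# ", comments)), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!"t" %in% names(d)) stop("not a trajectory table: no 't' column")
  class(d) <- c("twitch_trajectory", "data.frame")
  d
}

#' Read and write reference summary statistics
#'
#' A reference-statistics file holds the four summary statistics a
#' parameter inference is matched against (for instance values computed
#' from tracking data published elsewhere), as `name,value` rows.
#'
#' @param stats Named numeric with entries `mean_speed`, `var_dev`,
#'   `q_hat`, `a_hat` (a `twitch_summary_stats` works too).
#' @param path File path.
#' @return The named numeric vector (reading); `path` invisibly (writing).
#' @export
write_reference_stats <- function(stats, path) {
  if (inherits(stats, "twitch_summary_stats")) stats <- as.numeric(stats)
  need <- c("mean_speed", "var_dev", "q_hat", "a_hat")
  if (!all(need %in% names(stats)))
    stop("stats must be named: ", paste(need, collapse = ", "))
  d <- data.frame(name = need, value = as.numeric(stats[need]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# twitchsim reference statistics (um/s, rad^2, -, um/s)", con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reference_stats
#' @export
read_reference_stats <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  stats::setNames(d$value, d$name)
}

#' Write a per-trajectory statistics table
#'
#' One row per trajectory plus a pooled row, as produced by analysing a
#' set of tracks together.
#'
#' @param stats_list A list of `twitch_summary_stats` (one per
#'   trajectory).
#' @param pooled The pooled `twitch_summary_stats` for the set.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_stats_table <- function(stats_list, pooled, path) {
  row <- function(s, id) {
    data.frame(trajectory = id, mean_speed = s$mean_speed,
               var_dev = s$var_dev, q_hat = s$q_hat, a_hat = s$a_hat,
               n_steps = s$n_steps)
  }
  tab <- do.call(rbind, c(lapply(seq_along(stats_list), function(i)
    row(stats_list[[i]], as.character(i))),
    list(row(pooled, "pooled"))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# twitchsim summary statistics (<u> um/s, Var(theta_d) rad^2, q^, a^ um/s)",
             con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.config_keys <- function() {
  c(setdiff(names(sim_params()), "surface"),
    "surface_kind", "epsilon", "range", "wall_stiffness",
    "duration", "seed", "n_trajectories",
    "lin_delta_step", "window", "threshold", "trim",
    "abc_n", "abc_m", "target_steps", "max_traj",
    "n_base", "sobol_duration", "out_dir")
}

#' Read and write run configuration files
#'
#' Plain-text YAML key--value configuration mirroring the simulation
#' parameters and the analysis/inference settings.  Unknown keys are
#' rejected; a round trip through write/read is lossless.
#'
#' @param config A named list of configuration values.
#' @param path File path.
#' @return The configuration list (reading); `path` invisibly (writing).
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), .config_keys())
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  unknown <- setdiff(names(config), .config_keys())
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  config
}

#' Build simulation parameters from a configuration list
#'
#' @param config A configuration list as returned by [read_run_config()].
#' @return A [sim_params()] object.
#' @export
params_from_config <- function(config) {
  fields <- intersect(names(config), setdiff(names(sim_params()), "surface"))
  p <- do.call(sim_params, c(config[fields], list(
    surface = if (!is.null(config$surface_kind))
      surface_potential(config$surface_kind,
                        epsilon = config$epsilon %||% 50,
                        range = config$range %||% 0.05,
                        wall_stiffness = config$wall_stiffness %||% 1e5)
    else NULL)))
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
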