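#' Pole--surface interaction potential
#'
#' Each pole of the spherocylinder carries one surface interaction site at
#' the centre of its spherical cap.  The site interacts with the plane
#' z = 0 through the gap g = z_site - r (the cap--surface clearance):
#' a stiff harmonic wall penalises penetration (g < 0), and the
#' `attractive_well` kind additionally applies a bounded quadratic well
#' U(g) = -epsilon (1 - (g/range)^2) for 0 <= g < range, held at its floor
#' -epsilon under the wall.  The purely `repulsive` kind is used for
#' walking simulations; the well maintains the crawling orientation
#' against the vertical component of pilus tension.
#'
#' @param kind `"attractive_well"` or `"repulsive"`.
#' @param epsilon Well depth (pN um); ignored for the repulsive kind.
#' @param range Well width (um).
#' @param wall_stiffness Harmonic wall stiffness (pN/um).
#' @return An object of class `surface_potential`.
#' @examples
#' surface_potential("attractive_well", epsilon = 50)
#' @export
surface_potential <- function(kind = c("attractive_well", "repulsive"),
                              epsilon = 50, range = 0.05,
                              wall_stiffness = 1e5) {
  kind <- match.arg(kind)
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (range <= 0) stop("range must be > 0")
  if (wall_stiffness <= 0) stop("wall_stiffness must be > 0")
  structure(list(kind = kind,
                 epsilon = if (kind == "repulsive") 0 else epsilon,
                 range = range, wall_stiffness = wall_stiffness),
            class = "surface_potential")
}

.pot_cpp <- function(p) {
  list(kind = if (p$kind == "repulsive") 0L else 1L,
       epsilon = p$epsilon, range = p$range,
       wall_stiffness = p$wall_stiffness)
}

#' @export
print.surface_potential <- function(x, ...) {
  cat("<surface_potential> ", x$kind, "\n", sep = "")
  if (x$kind == "attractive_well")
    cat("  depth ", x$epsilon, " pN um, range ", x$range, " um\n", sep = "")
  cat("  wall stiffness ", format(x$wall_stiffness), " pN/um\n", sep = "")
  invisible(x)
}

#' Simulation parameters
#'
#' Collects the full parameter set of the twitching model.  Rate and
#' mechanical defaults follow the experimental estimates compiled for the
#' model (motor binding/unbinding times 1/k_ext,off = 1.6 s,
#' 1/k_ret,off = 9.1 s, 1/k_ext,on = 2.4 s, 1/k_ret,on = 0.40 s;
#' v_ret = 0.09 um/s, v_ext = 0.28 um/s; L_p = 5 um; E = 2000 pN/um;
#' f_stall = 100 pN; tau_dwell = 1 s).  No experimental estimate exists
#' for `kappa` (anchor-distribution concentration) or `k_spawn`; their
#' defaults (2.5 and 5 / s) are the values used throughout the simulated
#' validation studies.
#'
#' @param tau_dwell Mean surface dwell time of a bound pilus tip (s).
#' @param kappa von Mises--Fisher concentration of the anchor distribution
#'   (dimensionless, > 0); smaller values spread pili further from the
#'   leading pole.
#' @param k_spawn Rate of new pilus creation (1/s).
#' @param k_resample Thermal re-sampling rate of free worm-like chains (1/s).
#' @param v_ret,v_ext Retraction / extension speeds (um/s); converted to
#'   Poisson step events of size `delta_step` at rate v/delta.
#' @param k_ext_off,k_ret_on,k_ret_off,k_ext_on Motor transition rates of
#'   unbound pili (1/s), cycling extending -> passive -> retracting ->
#'   passive -> extending.
#' @param tau_delay Delay between surface binding and retraction (s).  The
#'   default 0 is the surface-sensing limit: on binding the extension motor
#'   detaches and the retraction motor attaches instantaneously.
#' @param L_p Persistence length of free pili (um).
#' @param E Elastic modulus of the TFP machine (pN/um).
#' @param f_stall Stall force of the retraction motor (pN).
#' @param r,l Body radius and cylinder length (um).
#' @param delta_step Pilus discretisation length (um).
#' @param surface A [surface_potential()].  Defaults to the attractive well
#'   for crawling mode and the repulsive wall for walking mode.  Note that
#'   a crawling start on a purely repulsive surface is a legitimate
#'   configuration (it is how crawling-to-walking transitions are studied);
#'   only sustained crawling requires the well.
#' @param mode `"crawling"` (horizontal start, both poles in contact) or
#'   `"walking"` (upright start, piliated pole down).
#' @param frame_dt Trajectory recording interval (s).
#' @param relax_tol Gradient infinity-norm tolerance of the rigid-body
#'   relaxation (pN).
#' @param relax_maxit Maximum relaxation iterations per event.
#' @return An object of class `sim_params` (a named list).
#' @examples
#' p <- sim_params(mode = "crawling", tau_dwell = 2, kappa = 2.5)
#' p$v_ret
#' @export
sim_params <- function(tau_dwell = 1.0, kappa = 2.5, k_spawn = 5.0,
                       k_resample = 1.0,
                       v_ret = 0.09, v_ext = 0.28,
                       k_ext_off = 1 / 1.6, k_ret_on = 1 / 0.40,
                       k_ret_off = 1 / 9.1, k_ext_on = 1 / 2.4,
                       tau_delay = 0, L_p = 5.0, E = 2000, f_stall = 100,
                       r = 0.5, l = 3.0, delta_step = 0.004,
                       surface = NULL,
                       mode = c("crawling", "walking"),
                       frame_dt = 0.1,
                       relax_tol = 1e-5, relax_maxit = 400) {
  mode <- match.arg(mode)
  if (is.null(surface)) {
    surface <- if (mode == "crawling") surface_potential("attractive_well")
               else surface_potential("repulsive")
  }
  stopifnot(inherits(surface, "surface_potential"))
  num <- c(tau_dwell = tau_dwell, kappa = kappa, k_spawn = k_spawn,
           k_resample = k_resample, v_ret = v_ret, v_ext = v_ext,
           k_ext_off = k_ext_off, k_ret_on = k_ret_on,
           k_ret_off = k_ret_off, k_ext_on = k_ext_on,
           tau_delay = tau_delay, L_p = L_p, E = E, f_stall = f_stall,
           r = r, l = l, delta_step = delta_step, frame_dt = frame_dt)
  if (any(!is.finite(num) & names(num) != "tau_dwell"))
    stop("non-finite parameter value")
  if (any(num[c("v_ret", "v_ext", "k_spawn", "k_resample", "k_ext_off",
                "k_ret_on", "k_ret_off", "k_ext_on", "tau_delay")] < 0))
    stop("rates and speeds must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if (any(num[c("L_p", "E", "f_stall", "r", "l", "delta_step",
                "frame_dt")] <= 0))
    stop("mechanical parameters must be > 0")
  structure(c(as.list(num),
              list(surface = surface, mode = mode,
                   relax_tol = relax_tol, relax_maxit = as.integer(relax_maxit))),
            class = "sim_params")
}

#' Update simulation parameters
#'
#' Returns a copy of `params` with the named fields replaced; used to move
#' through parameter space in the sensitivity and ABC modules.
#'
#' @param params A [sim_params()] object.
#' @param ... Named scalar replacements (e.g. `v_ret = 0.05`).
#' @return The modified `sim_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "sim_params"))
  repl <- list(...)
  if (length(repl) == 0) return(params)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  for (nm in names(repl)) params[[nm]] <- repl[[nm]]
  params
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> mode =", x$mode, "\n")
  cat(sprintf("  tau_dwell=%g s  kappa=%g  k_spawn=%g /s  v_ret=%g um/s  v_ext=%g um/s\n",
              x$tau_dwell, x$kappa, x$k_spawn, x$v_ret, x$v_ext))
  cat(sprintf("  motors: k_ext_off=%.3g k_ret_on=%.3g k_ret_off=%.3g k_ext_on=%.3g /s\n",
              x$k_ext_off, x$k_ret_on, x$k_ret_off, x$k_ext_on))
  cat(sprintf("  L_p=%g um  E=%g pN/um  f_stall=%g pN  body r=%g l=%g um\n",
              x$L_p, x$E, x$f_stall, x$r, x$l))
  cat("  surface:", x$surface$kind,
      if (x$surface$kind == "attractive_well")
        sprintf("(epsilon=%g, range=%g)", x$surface$epsilon, x$surface$range)
      else "", "\n")
  invisible(x)
}
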