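#' Rigid spherocylinder body configuration
#'
#' The cell body is a rigid spherocylinder of radius `radius` and cylinder
#' length `length`; `axis` is the unit vector from the trailing to the
#' leading (piliated) pole.  The two pole interaction sites sit at the
#' centres of the spherical caps, `center +/- (length/2) axis`.
#'
#' @param center Numeric length-3 centre position (um).
#' @param axis Numeric length-3 body axis; must have unit norm to within
#'   1e-9 (pass `normalize = TRUE` to rescale an un-normalised direction).
#' @param radius Body radius (um).
#' @param length Cylinder length (um).
#' @param normalize Rescale `axis` to unit length instead of insisting on it.
#' @return An object of class `body_configuration`.
#' @examples
#' b <- body_configuration(c(0, 0, 0.5), c(1, 0, 0))
#' pole_sites(b)
#' @export
body_configuration <- function(center, axis, radius = 0.5, length = 3.0,
                               normalize = FALSE) {
  center <- as.numeric(center); axis <- as.numeric(axis)
  if (length(center) != 3 || length(axis) != 3)
    stop("center and axis must be length-3 numeric vectors")
  if (any(!is.finite(center)) || any(!is.finite(axis)))
    stop("non-finite body pose")
  nrm <- sqrt(sum(axis^2))
  if (normalize) {
    if (nrm == 0) stop("axis has zero length")
    axis <- axis / nrm
  } else if (abs(nrm - 1) > 1e-9) {
    stop("axis must be a unit vector (|axis| = 1 within 1e-9)")
  }
  if (radius <= 0 || length <= 0) stop("radius and length must be > 0")
  structure(list(center = center, axis = axis, radius = radius,
                 length = length),
            class = "body_configuration")
}

#' Pole interaction sites of a body
#'
#' @param body A [body_configuration()].
#' @return A 2 x 3 matrix with rows `leading` and `trailing`:
#'   `center +/- (length/2) axis`.
#' @export
pole_sites <- function(body) {
  stopifnot(inherits(body, "body_configuration"))
  h <- body$length / 2
  m <- rbind(leading = body$center + h * body$axis,
             trailing = body$center - h * body$axis)
  colnames(m) <- c("x", "y", "z")
  m
}

#' @export
print.body_configuration <- function(x, ...) {
  cat(sprintf("<body_configuration> r=%g l=%g um\n", x$radius, x$length))
  cat("  center:", paste(signif(x$center, 6), collapse = ", "), "\n")
  cat("  axis:  ", paste(signif(x$axis, 6), collapse = ", "), "\n")
  invisible(x)
}

# Minimal rotation taking e1 = (1,0,0) onto `axis`; fixes the body roll
# gauge for poses specified by an axis alone.
.rotation_from_axis <- function(axis) {
  e1 <- c(1, 0, 0)
  v <- c(e1[2] * axis[3] - e1[3] * axis[2],
         e1[3] * axis[1] - e1[1] * axis[3],
         e1[1] * axis[2] - e1[2] * axis[1])
  s <- sqrt(sum(v^2)); c_ <- sum(e1 * axis)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about z
    return(diag(c(-1, -1, 1)))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

.pili_matrix <- function(pili) {
  if (is.null(pili) || (is.data.frame(pili) && nrow(pili) == 0)) return(NULL)
  if (is.matrix(pili)) pili <- as.data.frame(pili)
  need <- c("da_x", "da_y", "da_z", "rb_x", "rb_y", "l_eq")
  if (!all(need %in% names(pili)))
    stop("pili need columns ", paste(need, collapse = ", "))
  rb_z <- if ("rb_z" %in% names(pili)) pili$rb_z else rep(0, nrow(pili))
  as.matrix(cbind(pili$da_x, pili$da_y, pili$da_z,
                  pili$rb_x, pili$rb_y, rb_z, pili$l_eq))
}

#' Body--surface interaction energy
#'
#' Sum over the two pole sites of the site potential of
#' [surface_potential()], evaluated at the cap--surface gaps.
#'
#' @param body A [body_configuration()].
#' @param potential A [surface_potential()].
#' @return Energy in pN um.
#' @examples
#' b <- body_configuration(c(0, 0, 0.5), c(1, 0, 0))
#' surface_energy(b, surface_potential("attractive_well", epsilon = 50))
#' @export
surface_energy <- function(body, potential) {
  stopifnot(inherits(body, "body_configuration"),
            inherits(potential, "surface_potential"))
  e <- .cpp_energy(body$center, .rotation_from_axis(body$axis), NULL,
                   .pot_cpp(potential), body$radius, body$length, 1)
  e$surface
}

#' Total mechanical energy of a body with bound pili
#'
#' Adds the elastic energy of each bound pilus (see [elastic_energy()]) to
#' the body--surface term.  Pilus anchors are given in the body frame as
#' offsets `da_*` from the centre; attachment points `rb_*` are world
#' coordinates on the surface plane.
#'
#' @param body A [body_configuration()].
#' @param pili A data frame with columns `da_x, da_y, da_z, rb_x, rb_y`
#'   (optionally `rb_z`) and `l_eq`; may be `NULL` or empty.
#' @param potential A [surface_potential()].
#' @param E Elastic modulus (pN/um).
#' @return A list of class `energy_breakdown` with components `surface`,
#'   `pili` and `total` (pN um).
#' @export
total_energy <- function(body, pili = NULL, potential, E = 2000) {
  stopifnot(inherits(body, "body_configuration"),
            inherits(potential, "surface_potential"))
  e <- .cpp_energy(body$center, .rotation_from_axis(body$axis),
                   .pili_matrix(pili), .pot_cpp(potential),
                   body$radius, body$length, E)
  structure(list(surface = e$surface, pili = e$pili, total = e$total),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> surface %.6g + pili %.6g = %.6g pN um\n",
              x$surface, x$pili, x$total))
  invisible(x)
}

#' Relax a body to mechanical equilibrium
#'
#' Minimises [total_energy()] over the six rigid-body degrees of freedom
#' (translation plus axis--angle rotation about the centre) by monotone
#' preconditioned gradient descent with backtracking.  Anchored pilus
#' attachment points on the surface stay fixed; anchors move rigidly with
#' the body.
#'
#' @inheritParams total_energy
#' @param tol Gradient infinity-norm convergence tolerance (pN).
#' @param max_iter Iteration cap; non-convergence returns the last iterate
#'   with a warning.
#' @return The relaxed `body_configuration`, with attributes `energy`,
#'   `iterations`, `converged` and `grad_norm`.
#' @examples
#' b <- body_configuration(c(0, 0, 0.53), c(1, 0, 0))
#' relaxed <- relax_body(b, NULL, surface_potential("attractive_well"))
#' attr(relaxed, "energy")
#' @export
relax_body <- function(body, pili = NULL, potential, E = 2000,
                       tol = 1e-8, max_iter = 2000) {
  stopifnot(inherits(body, "body_configuration"),
            inherits(potential, "surface_potential"))
  res <- .cpp_relax(body$center, .rotation_from_axis(body$axis),
                    .pili_matrix(pili), .pot_cpp(potential),
                    body$radius, body$length, E, tol, as.integer(max_iter))
  if (!res$converged)
    warning("relax_body did not converge (grad norm ",
            format(res$grad_norm), " after ", res$iterations,
            " iterations); returning last iterate")
  out <- body_configuration(res$center, res$rotation[, 1],
                            body$radius, body$length, normalize = TRUE)
  attr(out, "rotation") <- res$rotation
  attr(out, "energy") <- res$energy
  attr(out, "iterations") <- res$iterations
  attr(out, "converged") <- res$converged
  attr(out, "grad_norm") <- res$grad_norm
  out
}
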