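#' Sample pilus anchor sites on the cell surface
#'
#' Anchor directions are drawn from a von Mises--Fisher distribution about
#' the body axis, f(x; kappa) = kappa / (4 pi sinh kappa) exp(kappa b.x),
#' then mapped onto the spherocylinder: polar angles up to pi/4 stay on the
#' leading spherical cap, angles in \[pi/4, pi/2\] are transported by the
#' linear map g(theta): \[pi/4, pi/2\] -> \[pi/4, pi/4 + l/2\] onto the near
#' half of the cylindrical wall, and the back hemisphere is mirrored onto
#' the same construction, so all pili originate on the leading half of the
#' body.
#'
#' @param n Number of anchors to draw.
#' @param kappa Concentration parameter (> 0); smaller values give broader
#'   anchor fields.
#' @param body_length,body_radius Spherocylinder dimensions (um).
#' @return A data frame with body-frame anchor offsets `da_x, da_y, da_z`
#'   (from the body centre), outward normals `na_x, na_y, na_z`, and a
#'   logical `on_cap`.
#' @examples
#' set.seed(1)
#' a <- sample_anchor(5, kappa = 2.5)
#' mean(a$on_cap)
#' @export
sample_anchor <- function(n, kappa, body_length = 3.0, body_radius = 0.5) {
  if (kappa <= 0) stop("kappa must be > 0")
  m <- .cpp_sample_anchor(as.integer(n), kappa, body_length, body_radius)
  d <- as.data.frame(m)
  d$on_cap <- d$on_cap > 0
  d
}

#' Sample a free pilus worm-like chain
#'
#' Generates a discrete worm-like chain of `n_seg` segments of length
#' `delta_step` starting along `normal` (the outward anchor normal).
#' Successive bend angles follow the harmonic bending Boltzmann weight
#' exp(-(L_p / (2 delta)) theta^2) under the spherical sin(theta) measure,
#' with uniform azimuth, so the tangent correlation decays as
#' exp(-s / L_p).
#'
#' @param n_seg Number of segments; the contour length is
#'   `n_seg * delta_step`.
#' @param persistence_length Persistence length L_p (um).
#' @param normal Initial tangent direction (normalised internally).
#' @param delta_step Segment length (um).
#' @param free_pivot Draw the first tangent uniformly over the outward
#'   hemisphere about `normal` (the filament pivots freely at its
#'   anchor, as in the simulator) instead of clamping it along `normal`.
#' @return An `n_seg` x 3 matrix of node positions relative to the anchor.
#' @examples
#' set.seed(1)
#' ch <- sample_chain(250, persistence_length = 5)
#' sqrt(sum(ch[250, ]^2)) # end-to-end distance of a 1 um pilus
#' @export
sample_chain <- function(n_seg, persistence_length = 5.0,
                         normal = c(0, 0, 1), delta_step = 0.004,
                         free_pivot = FALSE) {
  stopifnot(n_seg >= 1, persistence_length > 0, delta_step > 0)
  .cpp_sample_chain(as.integer(n_seg), as.numeric(normal),
                    persistence_length, delta_step, isTRUE(free_pivot))
}

#' Elastic energy and tension of a bound pilus
#'
#' A bound pilus is modelled as an elastic filament between its anchor and
#' its surface attachment point.  Stretching beyond the rest contour length
#' l_eq costs u = (E/2) (r_ab - l_eq)^2 / l_eq and produces tension
#' E (r_ab - l_eq) / l_eq along the filament; a slack pilus
#' (r_ab <= l_eq) stores no energy and cannot push.
#'
#' @param r_ab Anchor-to-attachment distance (um); vectorised.
#' @param l_eq Rest contour length (um, > 0).
#' @param E Elastic modulus (pN/um).
#' @return Energy in pN um ([elastic_energy()]) or force in pN
#'   ([pilus_tension()]).
#' @examples
#' elastic_energy(1.1, 1, E = 2000) # 10 pN um
#' pilus_tension(1.1, 1, E = 2000)  # 200 pN
#' @export
elastic_energy <- function(r_ab, l_eq, E = 2000) {
  if (any(l_eq <= 0)) stop("l_eq must be > 0 (a zero-length pilus is dissolved)")
  if (any(r_ab < 0)) stop("r_ab must be >= 0")
  ext <- pmax(r_ab - l_eq, 0)
  0.5 * E * ext^2 / l_eq
}

#' @rdname elastic_energy
#' @export
pilus_tension <- function(r_ab, l_eq, E = 2000) {
  if (any(l_eq <= 0)) stop("l_eq must be > 0 (a zero-length pilus is dissolved)")
  if (any(r_ab < 0)) stop("r_ab must be >= 0")
  E * pmax(r_ab - l_eq, 0) / l_eq
}

#' Stall rule for bound retracting pili
#'
#' Tension builds up in a restrained bound pilus as it retracts; once the
#' tension exceeds the stall force the retraction motor can no longer
#' shorten the filament, and retraction resumes only after the body
#' relaxes (or another pilus detaches) and the tension drops back to the
#' stall force or below.  An unrestrained pilus keeps near-zero tension
#' while dragging the body and retracts all the way to zero length, at
#' which point it dissolves.  Unbound pili carry no tension and always
#' may retract.
#'
#' @param r_ab Current anchor-to-attachment distance (um).
#' @param l_eq Current rest contour length (um).
#' @param E Elastic modulus (pN/um).
#' @param f_stall Stall force (pN).
#' @param bound Is the pilus surface-bound?  Vectorised with the rest.
#' @return Logical: `TRUE` where a retraction step is allowed.
#' @examples
#' retraction_allowed(1.06, 1.0, E = 2000, f_stall = 100) # 120 pN: stalled
#' @export
retraction_allowed <- function(r_ab, l_eq, E = 2000, f_stall = 100,
                               bound = TRUE) {
  n <- max(length(r_ab), length(l_eq), length(bound))
  r_ab <- rep_len(r_ab, n); l_eq <- rep_len(l_eq, n)
  bound <- rep_len(bound, n)
  ifelse(!bound, TRUE, pilus_tension(r_ab, l_eq, E) <= f_stall)
}
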