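## Kinematics of forced penetration into a locally quadrilateral chain
## lattice: the sink <-> stretch mapping, trapezoid/rhombus angles, and
## regime boundaries.
##
## Geometry in brief: a rigid particle (sphere or ellipsoid pushed through
## its short axis) pressed into the network plane stretches the four chains
## it touches. At sink depth y the in-plane cross-section of the particle
## has grown so that the cell of side lambda*R stays tangent to it; that
## tangency is the sink relation y/rho = 1 - sqrt(1 - lambda^2 eta^2),
## where eta = R / (rho * sqrt(2 (xi^2 + 1))) compares the mesh to the
## particle. Full penetration (y = rho) occurs at lambda = 1/eta.
## Neighbouring chains rotate into trapezoids of base angle
## alpha = arccos((lambda - 1)/2); at lambda = 3 the trapezoid collapses
## (alpha = 0) and further sinking must stretch the neighbours too, which
## stiffens the response.

## Collapse stretch of the trapezoid: alpha = arccos((lambda-1)/2) = 0.
.lambda_collapse <- 3

#' Mesh-to-particle size ratio
#'
#' \eqn{\eta = R / (\rho \sqrt{2(\xi^2+1)})} compares the chain end-to-end
#' distance with the pertinent particle dimension. For a sphere
#' (\eqn{\xi = 1}) it reduces to \eqn{R/2\rho}. \eqn{\eta \ge 1} means the
#' particle fits the mesh and penetrates spontaneously; otherwise the chains
#' must stretch to \eqn{\lambda = 1/\eta} for full penetration.
#'
#' @param R Chain end-to-end distance (nm).
#' @param rho Particle short semi-axis (nm).
#' @param xi Aspect ratio (>= 1; semi-axes are \eqn{\rho, \rho, \xi\rho}).
#' @return Dimensionless ratio.
#' @examples
#' eta_ratio(R = 100, rho = 150)          # 1/3
#' eta_ratio(R = 100, rho = 50, xi = 3)   # R / (rho * sqrt(20))
#' @family lattice geometry
#' @export
eta_ratio <- function(R, rho, xi = 1) {
  if (any(R <= 0) || any(rho <= 0)) stop_domain("`R` and `rho` must be positive.")
  if (any(xi < 1)) stop_domain("Aspect ratio `xi` must be >= 1 (penetration through the short axis).")
  R / (rho * sqrt(2 * (xi^2 + 1)))
}

#' Particle sink from chain stretch
#'
#' \eqn{y/\rho = 1 - \sqrt{1 - \lambda^2\eta^2}}. At \eqn{\lambda = 1} this
#' is the initial, force-free sink; at \eqn{\lambda = 1/\eta} the particle
#' equator reaches the network plane (\eqn{y = \rho}, full penetration).
#' For \eqn{\lambda\eta > 1} the sink saturates at 1 (already penetrated).
#'
#' @param lambda Chain stretch (>= 1). Vectorised.
#' @param eta Mesh-to-particle ratio from [eta_ratio()].
#' @return Normalized sink \eqn{y/\rho \in [0, 1]}.
#' @examples
#' sink_from_stretch(1, eta = 1/3)  # initial sink ~ 0.0572
#' sink_from_stretch(3, eta = 1/3)  # 1: full penetration
#' @family lattice geometry
#' @export
sink_from_stretch <- function(lambda, eta) {
  if (any(lambda < 1)) stop_domain("Stretch `lambda` must be >= 1 (no compressive states).")
  if (any(eta <= 0)) stop_domain("`eta` must be positive.")
  arg <- pmax(1 - lambda^2 * eta^2, 0)
  1 - sqrt(arg)
}

#' Chain stretch from particle sink
#'
#' Exact algebraic inverse of [sink_from_stretch()]:
#' \eqn{\lambda = \sqrt{1 - (1 - y/\rho)^2} / \eta}.
#'
#' @param y_over_rho Normalized sink in `[y0/rho, 1]`, where `y0/rho` is
#'   the initial sink at \eqn{\lambda = 1}. Vectorised.
#' @param eta Mesh-to-particle ratio.
#' @return Stretch \eqn{\lambda \ge 1}.
#' @family lattice geometry
#' @export
stretch_from_sink <- function(y_over_rho, eta) {
  if (any(eta <= 0)) stop_domain("`eta` must be positive.")
  if (any(y_over_rho < 0) || any(y_over_rho > 1)) {
    stop_domain("`y_over_rho` must lie in [0, 1].")
  }
  y0 <- sink_from_stretch(1, eta)
  if (any(y_over_rho < y0 - 1e-12)) {
    stop_domain("`y_over_rho` below the initial sink: compressive states are not modelled.")
  }
  sqrt(1 - (1 - y_over_rho)^2) / eta
}

#' Trapezoid base angle of the rotated neighbour chains
#'
#' As the contact chains stretch to \eqn{\lambda}, each neighbouring chain
#' rotates (without stretching) into a trapezoid of base angle
#' \eqn{\alpha = \arccos((\lambda-1)/2)}: 90 degrees in the reference state
#' and 0 at the collapse stretch \eqn{\lambda = 3}, beyond which the angle
#' is clamped at 0 (the trapezoid has collapsed and neighbours stretch
#' instead of rotating).
#'
#' @param lambda Chain stretch (>= 1). Vectorised.
#' @return Base angle in degrees, in `[0, 90]`.
#' @examples
#' trapezoid_angle(c(1, 2, 3))  # 90, 60, 0
#' @family lattice geometry
#' @export
trapezoid_angle <- function(lambda) {
  if (any(lambda < 1)) stop_domain("Stretch `lambda` must be >= 1.")
  arg <- pmin((lambda - 1) / 2, 1)
  acos(arg) * 180 / pi
}

#' Stretch at which the trapezoid reaches a given base angle
#'
#' Algebraic inverse of [trapezoid_angle()] on `[1, 3]`:
#' \eqn{\lambda = 1 + 2\cos\alpha}. At \eqn{\alpha = 0} this is the
#' collapse (stiffening-onset) stretch.
#'
#' @param alpha_deg Base angle in degrees, in `[0, 90]`. Vectorised.
#' @return Stretch \eqn{\lambda \in [1, 3]}.
#' @family lattice geometry
#' @export
stretch_from_angle <- function(alpha_deg) {
  if (any(alpha_deg < 0) || any(alpha_deg > 90)) {
    stop_domain("`alpha_deg` must lie in [0, 90].")
  }
  1 + 2 * cos(alpha_deg * pi / 180)
}

#' Rhombus vertex angle under an ellipsoidal particle
#'
#' An ellipsoid with long axis along the cell diagonal distorts the square
#' cell into a rhombus of vertex angle \eqn{\gamma = 2\arctan(1/\xi)}:
#' 90 degrees for a sphere, shrinking towards 0 as the particle elongates.
#'
#' @param xi Aspect ratio (>= 1). Vectorised.
#' @return Vertex angle in degrees, in `(0, 90]`.
#' @examples
#' rhombus_vertex_angle(c(1, 3))  # 90, 36.87
#' @family lattice geometry
#' @export
rhombus_vertex_angle <- function(xi) {
  if (any(xi < 1)) stop_domain("Aspect ratio `xi` must be >= 1.")
  2 * atan(1 / xi) * 180 / pi
}

#' Classify the penetration regime at a given stretch
#'
#' Partition of the stretch axis for a given mesh-to-particle ratio:
#' * `spontaneous` — \eqn{\eta \ge 1}: the particle fits the mesh, no
#'   forced states exist;
#' * `fully_penetrated` — \eqn{\lambda \ge 1/\eta}: the equator has passed
#'   the network plane;
#' * `post_collapse` — \eqn{\lambda > 3}: trapezoids collapsed, the 12
#'   neighbour chains stretch (stiffened response);
#' * `pre_collapse` — otherwise.
#'
#' Stiffened states occur before penetration iff \eqn{1/\eta > 3}, i.e.
#' \eqn{\eta < 1/3}; at \eqn{\eta = 1/3} penetration completes exactly at
#' the collapse stretch.
#'
#' @param lambda Chain stretch (>= 1). Vectorised.
#' @param eta Mesh-to-particle ratio.
#' @return Character vector of regime flags.
#' @examples
#' classify_regime(c(1, 2.9, 3), eta = 1/3)
#' classify_regime(c(3.5, 5), eta = 1/5)
#' @family lattice geometry
#' @export
classify_regime <- function(lambda, eta) {
  if (any(lambda < 1)) stop_domain("Stretch `lambda` must be >= 1.")
  if (any(eta <= 0)) stop_domain("`eta` must be positive.")
  dplyr::case_when(
    eta >= 1 ~ "spontaneous",
    lambda >= 1 / eta ~ "fully_penetrated",
    lambda > .lambda_collapse ~ "post_collapse",
    TRUE ~ "pre_collapse"
  )
}
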