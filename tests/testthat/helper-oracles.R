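# Independent oracles, kept deliberately separate from the implementation:
# the package uses closed forms; these recover the same quantities by
# numeric inversion, explicit vector sums, or constrained tangency solves.

# Exact inverse Langevin by root-finding on L(b) = coth(b) - 1/b = x.
langevin_fn <- function(b) ifelse(abs(b) < 1e-8, b / 3, 1 / tanh(b) - 1 / b)

exact_inverse_langevin <- function(x) {
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    uniroot(function(b) langevin_fn(b) - xi,
            lower = 1e-12, upper = 1e6, tol = 1e-12)$root
  }, numeric(1))
}

# Explicit 2-D vector sum of the four chain forces at a cross-link vertex
# with opening angle `vertex_deg`: two stretched chains (tension f) along
# the vertex edges, plus each edge's adjacent trapezoid leg (tension
# f_leg) pulling cos(alpha) along its own edge and -sin(alpha) along the
# other edge's direction.
crosslink_vector_sum <- function(lambda, kappa, vertex_deg) {
  f <- kappa * lambda * (3 - (kappa * lambda)^2) / (1 - (kappa * lambda)^2)
  lam_nb <- if (lambda > 3) lambda / 3 else 1
  x <- kappa * lam_nb
  f_leg <- x * (3 - x^2) / (1 - x^2)
  alpha <- acos(min((lambda - 1) / 2, 1))
  half <- vertex_deg * pi / 180 / 2
  A <- c(cos(half), sin(half))
  B <- c(cos(half), -sin(half))
  total <- f * A + f * B +
    f_leg * (cos(alpha) * A - sin(alpha) * B) +
    f_leg * (cos(alpha) * B - sin(alpha) * A)
  sqrt(sum(total^2))
}

# Tangency construction for the sink relation, sphere case: the square
# cell of side lambda*R must be tangent to the particle's circular
# cross-section at the network plane. Returns the cell side implied by a
# given sink depth; matching lambda*R validates the closed form.
tangent_square_side <- function(y_over_rho, rho) {
  2 * rho * sqrt(1 - (1 - y_over_rho)^2)
}

# Ellipsoid case: side length of the rhombus with vertex angle
# 2*atan(1/xi) tangent to the in-plane ellipse with semi-axes
# (xi*rho*s, rho*s), found by a numeric solve of the tangent-line
# condition a^2 u^2 + b^2 v^2 = 1 for the side x/p + y/q = 1.
tangent_rhombus_side <- function(y_over_rho, rho, xi) {
  s <- sqrt(1 - (1 - y_over_rho)^2)
  a <- xi * rho * s
  b <- rho * s
  t <- 1 / xi  # q/p fixed by the vertex angle
  p <- uniroot(function(p) a^2 / p^2 + b^2 / (t * p)^2 - 1,
               lower = max(a, b / t) * (1 + 1e-12),
               upper = max(a, b / t) * 10, tol = 1e-14)$root
  sqrt(p^2 + (t * p)^2)
}

table1_mucus <- tibble::tribble(
  ~name, ~d_avg, ~m, ~R_expected, ~n_expected,
  "Respiratory mucus",    140, 3, 240, 24,
  "Respiratory mucus",    140, 4, 140, 8,
  "Intestinal mucus",     210, 3, 360, 54,
  "Intestinal mucus",     210, 4, 210, 18,
  "Cervicovaginal mucus", 340, 3, 590, 146,
  "Cervicovaginal mucus", 340, 4, 340, 48
)

bundled_gel_table <- function() {
  read_gel_table(system.file("extdata", "table1_gels.csv", package = "gelpen"))
}
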