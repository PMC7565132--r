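## Forces during quasi-static forced penetration: average chain force,
## cross-link resultants, damage classification, and the sweep driver that
## produces force-sink trajectories.

## Guard: the sweep stops this fraction below the extensibility limit.
.lambda_max_guard <- 1e-6

#' Stretches of the chains contributing to the local response
#'
#' Before trapezoid collapse (\eqn{\lambda \le 3}) only the 4 chains in
#' direct contact with the particle stretch; the 12 neighbours (three per
#' side) rotate at their reference length. Beyond collapse the neighbours
#' stretch too; series compatibility of the collapsed trapezoid (near side
#' \eqn{\lambda R} equals far side plus two legs, all stretching equally)
#' gives them stretch \eqn{\lambda/3}, continuous at \eqn{\lambda = 3}.
#'
#' @param lambda Chain stretch of the contact chains (>= 1, scalar).
#' @return A tibble with columns `chain_class` (`contact`/`neighbor`),
#'   `stretch`, `count`.
#' @examples
#' contributing_chain_stretches(2)    # neighbours at 1
#' contributing_chain_stretches(4.5)  # neighbours at 1.5
#' @family forced penetration
#' @export
contributing_chain_stretches <- function(lambda) {
  if (length(lambda) != 1 || lambda < 1) stop_domain("`lambda` must be a scalar >= 1.")
  tibble(
    chain_class = c("contact", "neighbor"),
    stretch = c(lambda, if (lambda > .lambda_collapse) lambda / 3 else 1),
    count = c(4L, 12L)
  )
}

neighbor_stretch <- function(lambda) {
  ifelse(lambda > .lambda_collapse, lambda / 3, 1)
}

#' Average dimensionless force on a local chain
#'
#' Count-weighted mean of the entropic tensions of the 16 local chains
#' (4 contact + 12 neighbours): \eqn{\langle f l/k_b T\rangle =
#' [4\beta(\kappa\lambda) + 12\beta(\kappa\lambda_{nb})]/16} with
#' \eqn{\lambda_{nb}} from [contributing_chain_stretches()]. Pre-collapse
#' the neighbours sit at their constant reference tension
#' \eqn{\beta(\kappa)}, so only the contact chains add \eqn{\lambda}
#' dependence; post-collapse the neighbours stretch as \eqn{\lambda/3} and
#' the slope jumps up — the stiffening seen in force-sink curves.
#'
#' @param lambda Chain stretch (>= 1). Vectorised.
#' @param chain A [chain_spec()] or bare `kappa` scalar.
#' @param subtract_reference Subtract the reference-state value
#'   \eqn{\beta(\kappa)} so the curve starts at zero? Default `FALSE`.
#' @return Dimensionless average force \eqn{\langle f l/(k_b T)\rangle}.
#' @examples
#' average_chain_force(2, chain = 0.1)  # (4*beta(0.2) + 12*beta(0.1))/16
#' @family forced penetration
#' @export
average_chain_force <- function(lambda, chain, subtract_reference = FALSE) {
  kappa <- as_kappa(chain)
  if (any(lambda < 1)) stop_domain("`lambda` must be >= 1.")
  check_extensible(lambda, kappa)
  f <- (4 * inverse_langevin(kappa * lambda) +
          12 * inverse_langevin(kappa * neighbor_stretch(lambda))) / 16
  if (subtract_reference) f - inverse_langevin(kappa) else f
}

check_extensible <- function(lambda, kappa) {
  if (any(lambda * kappa >= 1 - .extensibility_guard)) {
    stop_extensibility(sprintf(
      "Contact chains fully extended: lambda reaches the extensibility limit 1/kappa = %.6g.",
      1 / kappa
    ))
  }
  if (any(neighbor_stretch(lambda) * kappa >= 1 - .extensibility_guard)) {
    stop_extensibility("Neighbor chains fully extended (lambda/3 at the extensibility limit).")
  }
  invisible(TRUE)
}

#' Resultant forces on the two cross-link types
#'
#' At each cell vertex the two stretched contact chains (tension
#' \eqn{f = \beta(\kappa\lambda)}) meet the two adjacent trapezoid legs
#' (tension \eqn{f_{leg}}: the reference tension \eqn{\beta(\kappa)} while
#' the legs merely rotate, \eqn{\beta(\kappa\lambda/3)} after collapse).
#' Each leg pulls along \eqn{\cos\alpha} of its own chain axis and
#' \eqn{-\sin\alpha} of the other, so the four forces sum along the vertex
#' bisector and
#' \deqn{f_{CL,1} = 2\cos(\gamma/2)\,|f + f_{leg}(\cos\alpha - \sin\alpha)|,
#'       \quad f_{CL,2} = 2\sin(\gamma/2)\,|\cdot|,}
#' with \eqn{\gamma = 2\arctan(1/\xi)} the rhombus vertex angle (cross-link
#' 1 sits at the acute vertex near the long axis and always bears the
#' larger load; the ratio is exactly \eqn{\cot(\gamma/2) = \xi}). For a
#' sphere both reduce to \eqn{\sqrt 2\,|f + f_{leg}(\cos\alpha-\sin\alpha)|}.
#' In the reference state the four tensions balance and both resultants
#' vanish.
#'
#' @inheritParams average_chain_force
#' @param xi Particle aspect ratio (>= 1).
#' @return A tibble with columns `f_cl_1`, `f_cl_2` (dimensionless
#'   \eqn{f^{CL} l/(k_b T)}).
#' @examples
#' crosslink_resultant(1, chain = 0.1)          # both zero
#' crosslink_resultant(2, chain = 0.1, xi = 3)  # ratio = 3
#' @family forced penetration
#' @export
crosslink_resultant <- function(lambda, chain, xi = 1) {
  kappa <- as_kappa(chain)
  if (any(lambda < 1)) stop_domain("`lambda` must be >= 1.")
  if (any(xi < 1)) stop_domain("Aspect ratio `xi` must be >= 1.")
  check_extensible(lambda, kappa)
  alpha <- trapezoid_angle(lambda) * pi / 180
  gamma_half <- atan(1 / xi)
  f <- inverse_langevin(kappa * lambda)
  f_leg <- inverse_langevin(kappa * neighbor_stretch(lambda))
  common <- abs(f + f_leg * (cos(alpha) - sin(alpha)))
  tibble(f_cl_1 = 2 * cos(gamma_half) * common,
         f_cl_2 = 2 * sin(gamma_half) * common)
}

#' Damage thresholds for the network
#'
#' Critical forces (dimensionless, \eqn{f l/(k_b T)}) at which a chain
#' ruptures or a cross-link dissociates. `Inf` disables a mechanism. In
#' physically cross-linked gels such as mucin the cross-links are the weak
#' element, which motivates the tie-break default in [check_damage()].
#'
#' @param f_rup Critical chain-rupture force (> 0, may be `Inf`).
#' @param f_dis Critical cross-link dissociation force (> 0, may be `Inf`).
#' @param k Chains per cross-link (integer >= 2; default 4 for the
#'   quadrilateral lattice).
#' @return An object of class `damage_thresholds`.
#' @family forced penetration
#' @export
damage_thresholds <- function(f_rup = Inf, f_dis = Inf, k = 4L) {
  if (!is.numeric(f_rup) || f_rup <= 0 || !is.numeric(f_dis) || f_dis <= 0) {
    stop_domain("Damage thresholds must be strictly positive (Inf disables damage).")
  }
  if (k < 2 || k != round(k)) stop_domain("`k` must be an integer >= 2.")
  structure(list(f_rup = f_rup, f_dis = f_dis, k = as.integer(k)),
            class = "damage_thresholds")
}

#' Classify a damage event
#'
#' A chain ruptures when its tension exceeds `f_rup`; a cross-link
#' dissociates when the resultant on the critical site (cross-link 1)
#' exceeds `f_dis`. If both thresholds are exceeded in the same state the
#' mechanism with the larger relative exceedance is reported; on an exact
#' tie, cross-link dissociation (the more probable mechanism in physically
#' cross-linked gels) by default.
#'
#' @param f_chain Tension on the most-loaded chain (dimensionless).
#' @param f_cl_1 Resultant on cross-link 1 (dimensionless).
#' @param thresholds A [damage_thresholds()].
#' @param tie Mechanism reported on an exact tie; default
#'   `"crosslink_dissociation"`.
#' @return `"none"`, `"chain_rupture"`, or `"crosslink_dissociation"`.
#' @family forced penetration
#' @export
check_damage <- function(f_chain, f_cl_1, thresholds,
                         tie = c("crosslink_dissociation", "chain_rupture")) {
  tie <- match.arg(tie)
  if (!inherits(thresholds, "damage_thresholds")) {
    stop_domain("`thresholds` must be a damage_thresholds object.")
  }
  if (f_chain < 0 || f_cl_1 < 0) stop_domain("Forces must be non-negative.")
  exc_chain <- f_chain / thresholds$f_rup
  exc_cl <- f_cl_1 / thresholds$f_dis
  if (exc_chain <= 1 && exc_cl <= 1) return("none")
  if (exc_chain > exc_cl) return("chain_rupture")
  if (exc_cl > exc_chain) return("crosslink_dissociation")
  tie
}

#' Simulate quasi-static forced penetration
#'
#' Sweeps the contact-chain stretch uniformly from \eqn{\lambda = 1} up to
#' full penetration (\eqn{\lambda = 1/\eta}) or the chain extensibility
#' limit, whichever comes first, recording at each state the sink, the
#' trapezoid angle, the regime, the average chain force and the cross-link
#' resultants, and stopping at the first damage event. The process is
#' deterministic.
#'
#' The geometry can be given directly (`eta`, `kappa`) as in the
#' force-sink figures, or physically (`R`, `rho`, `chain`), from which
#' \eqn{\eta} and \eqn{\kappa} are derived.
#'
#' @param eta Mesh-to-particle ratio; computed from `R` and `rho` if
#'   omitted.
#' @param chain A [chain_spec()] or bare `kappa` scalar.
#' @param xi Particle aspect ratio (>= 1).
#' @param R Chain end-to-end distance (nm), used with `rho` when `eta` is
#'   not given directly.
#' @param rho Particle short semi-axis (nm).
#' @param thresholds A [damage_thresholds()]; default disables damage.
#' @param steps Number of sweep states (>= 2; default 400).
#' @param subtract_reference Report forces relative to the reference
#'   state? See [average_chain_force()].
#' @return An object of class `gel_penetration`: a list with `trajectory`
#'   (tibble of states: `lambda`, `y_over_rho`, `alpha_deg`, `regime`,
#'   `avg_chain_force`, `f_cl_1`, `f_cl_2`, `damage`), `outcome` (one of
#'   `spontaneous`, `elastic_penetration`, `chain_rupture`,
#'   `crosslink_dissociation`, `jammed`), and `params`. Use [tidy()] for
#'   the trajectory, [glance()] for a one-row summary, [autoplot()] to
#'   plot.
#' @examples
#' sim <- simulate_penetration(eta = 1/4, chain = 0.1, steps = 100)
#' glance(sim)
#' @family forced penetration
#' @export
simulate_penetration <- function(eta = NULL, chain, xi = 1, R = NULL, rho = NULL,
                                 thresholds = damage_thresholds(), steps = 400,
                                 subtract_reference = FALSE) {
  kappa <- as_kappa(chain)
  if (is.null(eta)) {
    if (is.null(R) || is.null(rho)) {
      stop_config("Give either `eta` directly or both `R` and `rho`.")
    }
    eta <- eta_ratio(R, rho, xi)
  }
  if (length(eta) != 1 || eta <= 0) stop_domain("`eta` must be a positive scalar.")
  if (length(xi) != 1 || xi < 1) stop_domain("`xi` must be a scalar >= 1.")
  if (!inherits(thresholds, "damage_thresholds")) {
    stop_domain("`thresholds` must be a damage_thresholds object.")
  }
  if (length(steps) != 1 || steps < 2 || steps != round(steps)) {
    stop_domain("`steps` must be an integer >= 2.")
  }
  params <- list(eta = eta, kappa = kappa, xi = xi, steps = as.integer(steps),
                 f_rup = thresholds$f_rup, f_dis = thresholds$f_dis,
                 subtract_reference = subtract_reference)

  empty_traj <- tibble(
    lambda = double(), y_over_rho = double(), alpha_deg = double(),
    regime = character(), avg_chain_force = double(),
    f_cl_1 = double(), f_cl_2 = double(), damage = character()
  )
  if (eta >= 1) {
    return(new_gel_penetration(empty_traj, "spontaneous", params))
  }

  lambda_pen <- 1 / eta
  lambda_ext <- (1 / kappa) * (1 - .lambda_max_guard)
  lambda_end <- min(lambda_pen, lambda_ext)
  grid <- seq(1, lambda_end, length.out = steps)

  f_contact <- inverse_langevin(kappa * grid)
  cl <- crosslink_resultant(grid, kappa, xi)
  traj <- tibble(
    lambda = grid,
    y_over_rho = sink_from_stretch(grid, eta),
    alpha_deg = trapezoid_angle(grid),
    regime = classify_regime(grid, eta),
    avg_chain_force = average_chain_force(grid, kappa,
                                          subtract_reference = subtract_reference),
    f_cl_1 = cl$f_cl_1,
    f_cl_2 = cl$f_cl_2,
    damage = "none"
  )

  dmg <- purrr::map2_chr(f_contact, cl$f_cl_1, check_damage, thresholds = thresholds)
  hit <- which(dmg != "none")
  if (length(hit)) {
    first <- hit[1]
    traj <- traj[seq_len(first), , drop = FALSE]
    traj$damage[first] <- dmg[first]
    return(new_gel_penetration(traj, dmg[first], params))
  }
  outcome <- if (lambda_end >= lambda_pen) "elastic_penetration" else "jammed"
  new_gel_penetration(traj, outcome, params)
}

new_gel_penetration <- function(trajectory, outcome, params) {
  structure(list(trajectory = trajectory, outcome = outcome, params = params),
            class = "gel_penetration")
}
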