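test_that("contributing chain stretches switch at trapezoid collapse", {
  ref <- contributing_chain_stretches(1)
  expect_equal(ref$stretch, c(1, 1))
  expect_equal(ref$count, c(4L, 12L))
  expect_equal(contributing_chain_stretches(2)$stretch, c(2, 1))
  # continuity at collapse: neighbours take over at exactly stretch 1
  expect_equal(contributing_chain_stretches(3)$stretch[2], 1)
  expect_equal(contributing_chain_stretches(3 + 1e-12)$stretch[2], 1, tolerance = 1e-9)
  expect_equal(contributing_chain_stretches(4.5)$stretch, c(4.5, 1.5))
  expect_error(contributing_chain_stretches(0.9), class = "gelpen_domain_error")
})

test_that("average chain force matches the 16-chain closed form", {
  kappa <- 0.1
  b <- function(x) x * (3 - x^2) / (1 - x^2)
  expect_equal(average_chain_force(1, kappa), b(kappa))
  expect_equal(average_chain_force(2, kappa), (4 * b(0.2) + 12 * b(0.1)) / 16)
  expect_equal(average_chain_force(6, kappa), (4 * b(0.6) + 12 * b(0.2)) / 16)
  expect_equal(average_chain_force(1, kappa, subtract_reference = TRUE), 0)
  expect_error(average_chain_force(10, kappa), class = "gelpen_extensibility_error")
  expect_error(average_chain_force(6.9, 0.45), class = "gelpen_extensibility_error")
})

test_that("average chain force is continuous with an upward slope jump at collapse", {
  kappa <- 0.1
  eps <- 1e-8
  left <- average_chain_force(3 - eps, kappa)
  right <- average_chain_force(3 + eps, kappa)
  expect_equal(left, right, tolerance = 1e-6)
  h <- 1e-6
  slope_left <- (average_chain_force(3 - h, kappa) - average_chain_force(3 - 2 * h, kappa)) / h
  slope_right <- (average_chain_force(3 + 2 * h, kappa) - average_chain_force(3 + h, kappa)) / h
  jump <- slope_right - slope_left
  expect_gt(jump, 0)
  expect_equal(jump, (12 / 16) * (kappa / 3) * inverse_langevin_prime(kappa),
               tolerance = 1e-4)
  # monotone non-decreasing along a sweep
  lam <- seq(1, 8, by = 0.01)
  expect_true(all(diff(average_chain_force(lam, kappa)) >= 0))
})

test_that("cross-link resultants match the explicit vector sum", {
  for (kappa in c(0.05, 0.1, 0.3)) {
    for (xi in c(1, 2, 3)) {
      gamma <- rhombus_vertex_angle(xi)
      for (lam in seq(1, min(6, 0.95 / kappa), length.out = 13)) {
        got <- crosslink_resultant(lam, kappa, xi)
        expect_equal(got$f_cl_1, crosslink_vector_sum(lam, kappa, gamma),
                     tolerance = 1e-10)
        expect_equal(got$f_cl_2, crosslink_vector_sum(lam, kappa, 180 - gamma),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("cross-link forces vanish in the reference state and split as xi", {
  for (xi in c(1, 1.5, 3, 10)) {
    ref <- crosslink_resultant(1, 0.1, xi)
    expect_equal(ref$f_cl_1, 0, tolerance = 1e-14)
    expect_equal(ref$f_cl_2, 0, tolerance = 1e-14)
    loaded <- crosslink_resultant(seq(1.1, 5, by = 0.3), 0.1, xi)
    expect_equal(loaded$f_cl_1 / loaded$f_cl_2, rep(xi, nrow(loaded)),
                 tolerance = 1e-12)
  }
  # sphere: f_cl_1 = f_cl_2 = sqrt(2) * |f + f_leg (cos a - sin a)|
  sph <- crosslink_resultant(2, 0.1, 1)
  a <- pi / 3
  expect_equal(sph$f_cl_1,
               sqrt(2) * abs(inverse_langevin(0.2) +
                               inverse_langevin(0.1) * (cos(a) - sin(a))))
  expect_equal(sph$f_cl_1, sph$f_cl_2)
})

test_that("an elongated particle loads cross-link 1 harder than a sphere", {
  lam <- seq(1.05, 6, by = 0.05)
  for (kappa in c(0.05, 0.1)) {
    sphere <- crosslink_resultant(lam, kappa, 1)$f_cl_1
    ellip <- crosslink_resultant(lam, kappa, 3)$f_cl_1
    expect_true(all(ellip > sphere))
    # the two share |f + f_leg(...)|, so the ratio is the pure geometry factor
    expect_equal(ellip / sphere,
                 rep(2 * cos(atan(1 / 3)) / sqrt(2), length(lam)),
                 tolerance = 1e-12)
    expect_equal(ellip[1] / sphere[1], 1.342, tolerance = 1e-3)
  }
})

test_that("cross-link force is continuous and non-decreasing with a kink only at collapse", {
  kappa <- 0.1
  lam <- seq(1, 8, by = 0.005)
  f1 <- crosslink_resultant(lam, kappa, 1)$f_cl_1
  expect_true(all(diff(f1) >= -1e-12))
  # the curvature spike (slope jump) sits at the collapse stretch
  curv <- abs(diff(f1, differences = 2))
  expect_equal(lam[which.max(curv) + 1], 3, tolerance = 0.01)
})

test_that("damage classification honours thresholds, exceedance, and the tie rule", {
  off <- damage_thresholds()
  expect_equal(check_damage(10, 10, off), "none")
  th <- damage_thresholds(f_rup = 1.5, f_dis = 10)
  expect_equal(check_damage(2, 1, th), "chain_rupture")
  th2 <- damage_thresholds(f_rup = 10, f_dis = 0.5)
  expect_equal(check_damage(2, 1, th2), "crosslink_dissociation")
  # both exceeded: larger relative exceedance wins
  th3 <- damage_thresholds(f_rup = 1, f_dis = 4)
  expect_equal(check_damage(3, 5, th3), "chain_rupture")       # 3x vs 1.25x
  expect_equal(check_damage(1.1, 5, th3), "crosslink_dissociation")
  # exact tie -> cross-link dissociation by default, configurable
  th4 <- damage_thresholds(f_rup = 1, f_dis = 2)
  expect_equal(check_damage(2, 4, th4), "crosslink_dissociation")
  expect_equal(check_damage(2, 4, th4, tie = "chain_rupture"), "chain_rupture")
  expect_error(damage_thresholds(f_rup = -1), class = "gelpen_domain_error")
})

test_that("quasi-static sweep outcomes match the regime analysis", {
  # eta = 1/3: penetration exactly at collapse onset, no stiffened states
  s1 <- simulate_penetration(eta = 1 / 3, chain = 0.1, steps = 200)
  expect_equal(s1$outcome, "elastic_penetration")
  expect_equal(max(s1$trajectory$lambda), 3)
  expect_equal(sum(s1$trajectory$regime == "post_collapse"), 0L)
  expect_equal(dplyr::last(s1$trajectory$y_over_rho), 1)

  # eta = 1/5: stiffened states before penetration at lambda = 5
  s2 <- simulate_penetration(eta = 1 / 5, chain = 0.1, steps = 200)
  expect_equal(s2$outcome, "elastic_penetration")
  expect_equal(max(s2$trajectory$lambda), 5)
  expect_gt(sum(s2$trajectory$regime == "post_collapse"), 0L)

  # a finite dissociation threshold below the force maximum triggers damage
  s3 <- simulate_penetration(eta = 1 / 4, chain = 0.1,
                             thresholds = damage_thresholds(f_dis = 0.5),
                             steps = 300)
  expect_equal(s3$outcome, "crosslink_dissociation")
  expect_lt(dplyr::last(s3$trajectory$y_over_rho), 1)
  expect_equal(sum(s3$trajectory$damage != "none"), 1L)
  expect_equal(dplyr::last(s3$trajectory$damage), "crosslink_dissociation")

  # extensibility limit reached before penetration, no damage: jammed
  s4 <- simulate_penetration(eta = 0.1, chain = 0.45, steps = 200)
  expect_equal(s4$outcome, "jammed")
  expect_lt(max(s4$trajectory$lambda), 1 / 0.45)

  # mesh wider than the particle: spontaneous, empty trajectory
  s5 <- simulate_penetration(eta = 1.5, chain = 0.1)
  expect_equal(s5$outcome, "spontaneous")
  expect_equal(nrow(s5$trajectory), 0L)
})

test_that("trajectories are strictly monotone and record consistent states", {
  sim <- simulate_penetration(eta = 1 / 5, chain = 0.1, xi = 3, steps = 150)
  tr <- tidy(sim)
  expect_true(all(diff(tr$lambda) > 0))
  expect_true(all(diff(tr$y_over_rho) > 0))
  expect_equal(tr$y_over_rho, sink_from_stretch(tr$lambda, 1 / 5))
  expect_equal(tr$alpha_deg, trapezoid_angle(tr$lambda))
  expect_equal(tr$regime, classify_regime(tr$lambda, 1 / 5))
  expect_equal(tr$f_cl_1 / tr$f_cl_2, rep(3, nrow(tr)), tolerance = 1e-10)
  g <- glance(sim)
  expect_equal(g$outcome, "elastic_penetration")
  expect_equal(g$n_states, nrow(tr))
  expect_equal(g$lambda_final, 5)
})

test_that("ellipsoid outputs collapse to sphere outputs at xi = 1", {
  a <- simulate_penetration(eta = 0.3, chain = 0.1, xi = 1, steps = 80)
  b <- simulate_penetration(R = 60, rho = 100, chain = 0.1, xi = 1, steps = 80)
  expect_equal(eta_ratio(60, 100, 1), 0.3)
  expect_equal(a$trajectory, b$trajectory)
  expect_equal(crosslink_resultant(2, 0.1, 1),
               crosslink_resultant(2, 0.1, 1 + 1e-12), tolerance = 1e-10)
})

test_that("lowering a damage threshold never delays the damage event", {
  lam_at_damage <- function(f_dis) {
    s <- simulate_penetration(eta = 1 / 5, chain = 0.1,
                              thresholds = damage_thresholds(f_dis = f_dis),
                              steps = 400)
    if (s$outcome == "crosslink_dissociation") dplyr::last(s$trajectory$lambda) else Inf
  }
  lams <- vapply(c(0.2, 0.5, 1, 2, 5), lam_at_damage, 0)
  expect_true(all(diff(lams) >= 0))
})

test_that("simulation validates its inputs", {
  expect_error(simulate_penetration(chain = 0.1), class = "gelpen_config_error")
  expect_error(simulate_penetration(eta = 0.5, chain = 0.1, steps = 1),
               class = "gelpen_domain_error")
  expect_error(simulate_penetration(eta = 0.5, chain = 0.1, xi = 0.5),
               class = "gelpen_domain_error")
  expect_error(simulate_penetration(eta = -1, chain = 0.1),
               class = "gelpen_domain_error")
})
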