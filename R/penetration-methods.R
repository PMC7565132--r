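#' @export
print.gel_penetration <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<gel_penetration> eta = %.4g, kappa = %.4g, xi = %g\n  outcome: %s (%d states recorded)\n",
    p$eta, p$kappa, p$xi, x$outcome, nrow(x$trajectory)
  ))
  if (nrow(x$trajectory)) {
    last <- x$trajectory[nrow(x$trajectory), ]
    cat(sprintf("  final state: lambda = %.4g, y/rho = %.4g, <f l/kT> = %.4g\n",
                last$lambda, last$y_over_rho, last$avg_chain_force))
  }
  invisible(x)
}

#' Tidy a forced-penetration simulation
#'
#' Returns the quasi-static trajectory as a tibble, one row per swept
#' state.
#'
#' @param x A `gel_penetration` object from [simulate_penetration()].
#' @param ... Unused.
#' @return A tibble with columns `lambda`, `y_over_rho`, `alpha_deg`,
#'   `regime`, `avg_chain_force`, `f_cl_1`, `f_cl_2`, `damage`.
#' @family forced penetration
#' @method tidy gel_penetration
#' @export
tidy.gel_penetration <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a forced-penetration simulation
#'
#' @param x A `gel_penetration` object.
#' @param ... Unused.
#' @return A one-row tibble: parameters, outcome, number of recorded
#'   states, and the final stretch/sink/forces (NA for an empty
#'   spontaneous trajectory).
#' @family forced penetration
#' @method glance gel_penetration
#' @export
glance.gel_penetration <- function(x, ...) {
  tr <- x$trajectory
  last <- if (nrow(tr)) tr[nrow(tr), ] else NULL
  tibble(
    eta = x$params$eta, kappa = x$params$kappa, xi = x$params$xi,
    f_rup = x$params$f_rup, f_dis = x$params$f_dis,
    outcome = x$outcome, n_states = nrow(tr),
    lambda_final = if (is.null(last)) NA_real_ else last$lambda,
    y_over_rho_final = if (is.null(last)) NA_real_ else last$y_over_rho,
    avg_chain_force_final = if (is.null(last)) NA_real_ else last$avg_chain_force,
    f_cl_1_final = if (is.null(last)) NA_real_ else last$f_cl_1
  )
}

#' Plot a forced-penetration trajectory
#'
#' Force-sink curves of the quasi-static sweep: the average chain force
#' and/or cross-link resultants against the normalized sink, coloured by
#' regime, with the trapezoid-collapse (stiffening) sink marked when it is
#' crossed.
#'
#' @param object A `gel_penetration` object.
#' @param quantity `"chain"` (average chain force), `"crosslink"` (both
#'   cross-link resultants), or `"stretch"` (stretch vs sink).
#' @param ... Unused.
#' @return A ggplot.
#' @family forced penetration
#' @method autoplot gel_penetration
#' @export
autoplot.gel_penetration <- function(object,
                                     quantity = c("chain", "crosslink", "stretch"),
                                     ...) {
  quantity <- match.arg(quantity)
  tr <- object$trajectory
  if (!nrow(tr)) {
    stop_validation("Nothing to plot: spontaneous penetration has an empty trajectory.")
  }
  base <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$y_over_rho)) +
    ggplot2::labs(x = expression(y / rho)) +
    ggplot2::theme_minimal()
  collapse_sink <- tr$y_over_rho[tr$lambda >= 3][1]
  if (!is.na(collapse_sink)) {
    base <- base + ggplot2::geom_vline(xintercept = collapse_sink,
                                       linetype = "dashed", colour = "grey50")
  }
  switch(quantity,
    chain = base +
      ggplot2::geom_line(ggplot2::aes(y = .data$avg_chain_force)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$avg_chain_force,
                                       colour = .data$regime), size = 0.6) +
      ggplot2::labs(y = expression("<" * f * l / (k[b] * T) * ">"),
                    title = sprintf("Average chain force (eta = %.3g, kappa = %.3g)",
                                    object$params$eta, object$params$kappa)),
    crosslink = base +
      ggplot2::geom_line(ggplot2::aes(y = .data$f_cl_1, linetype = "cross-link 1")) +
      ggplot2::geom_line(ggplot2::aes(y = .data$f_cl_2, linetype = "cross-link 2")) +
      ggplot2::labs(y = expression(f^CL * l / (k[b] * T)), linetype = NULL,
                    title = sprintf("Cross-link resultants (xi = %g)", object$params$xi)),
    stretch = base +
      ggplot2::geom_line(ggplot2::aes(y = .data$lambda)) +
      ggplot2::labs(y = expression(lambda), title = "Chain stretch vs sink")
  )
}

#' Plot a gel characterization table
#'
#' Dot plot of the estimated end-to-end distances per gel and assumed
#' coordination, annotated with the repeat-unit counts.
#'
#' @param object A `gel_characterization` tibble from
#'   [characterize_gels()].
#' @param ... Unused.
#' @return A ggplot.
#' @family spontaneous penetration
#' @method autoplot gel_characterization
#' @export
autoplot.gel_characterization <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$R_reported_nm,
                               y = factor(.data$name, levels = rev(unique(.data$name))),
                               colour = factor(.data$m))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                       vjust = -1, size = 3, show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "end-to-end distance R (nm)", y = NULL,
                  colour = "coordination m",
                  title = "Bio-gel microstructure from spontaneous penetration") +
    ggplot2::theme_minimal()
}
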