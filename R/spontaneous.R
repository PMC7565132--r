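## Spontaneous (unforced) penetration criterion and the inverse
## microstructure-characterization pipeline built on it.
##
## A particle of diameter 2*rho sitting on m chains fits through the mesh
## without force only if the chain end-to-end distance R exceeds
## 2*rho*tan(pi/m). Read forwards this predicts which particles penetrate;
## read backwards, reported penetrating-particle diameters put a lower
## bound on R, and with the liquid content and repeat-unit length this
## yields the number of repeat units per chain.

#' Can a particle penetrate a gel spontaneously?
#'
#' Geometric fit criterion: a sphere of diameter \eqn{2\rho} surrounded by
#' `m` chains penetrates without external force iff
#' \eqn{R > 2\rho \tan(\pi/m)} (strict inequality; sitting exactly at the
#' boundary does not admit entry). An ellipsoid pushed through its short
#' axis must clear the quadrilateral mesh with its long axis \eqn{2\xi\rho},
#' i.e. \eqn{R > 2\xi\rho}; since \eqn{\tan(\pi/4)=1} this is the same
#' formula with `m = 4`.
#'
#' @param diameter Particle diameter \eqn{2\rho} in nm (short-axis diameter
#'   for an ellipsoid). Vectorised.
#' @param R Chain end-to-end distance in nm.
#' @param m Local coordination: number of chains around the particle
#'   (>= 3). Must be 4 when `xi > 1`.
#' @param xi Particle aspect ratio (>= 1; 1 = sphere).
#' @return Logical.
#' @examples
#' can_penetrate_spontaneously(140, R = 140, m = 4)  # FALSE, boundary
#' can_penetrate_spontaneously(100, R = 300, m = 3)  # TRUE
#' @family spontaneous penetration
#' @export
can_penetrate_spontaneously <- function(diameter, R, m = 4, xi = 1) {
  check_coordination(m)
  if (any(xi < 1)) stop_domain("Aspect ratio `xi` must be >= 1.")
  if (any(xi > 1) && any(m != 4)) {
    stop_domain("Ellipsoidal particles (xi > 1) are modelled on the quadrilateral mesh only: use m = 4.")
  }
  if (any(diameter <= 0) || any(R <= 0)) stop_domain("Lengths must be positive.")
  thr <- xi * diameter * tan(pi / m)
  # strict inequality; the relative guard keeps exact-boundary inputs
  # (where tan(pi/m) itself carries float error) on the "no" side
  R > thr * (1 + 1e-9)
}

#' Smallest end-to-end distance admitting spontaneous penetration
#'
#' The boundary of the fit criterion: \eqn{R = 2\rho \tan(\pi/m)}. Applied
#' to the largest (or average) particle diameter observed to penetrate a
#' gel spontaneously, this estimates the gel's chain end-to-end distance
#' and hence its mesh size.
#'
#' @inheritParams can_penetrate_spontaneously
#' @return End-to-end distance in nm.
#' @examples
#' min_end_to_end(140, m = 4)  # 140 nm
#' min_end_to_end(140, m = 3)  # 242.49 nm
#' @family spontaneous penetration
#' @export
min_end_to_end <- function(diameter, m) {
  check_coordination(m)
  if (any(diameter <= 0)) stop_domain("`diameter` must be positive.")
  diameter * tan(pi / m)
}

check_coordination <- function(m) {
  if (any(!is.finite(m)) || any(m < 3) || any(m != round(m))) {
    stop_domain("Coordination `m` must be an integer >= 3.")
  }
  invisible(m)
}

#' Characterize one gel from a spontaneous-penetration observation
#'
#' For each assumed local coordination `m`, estimates the chain end-to-end
#' distance from the average penetrating-particle diameter,
#' \eqn{R = \bar d \tan(\pi/m)}, reports it to `sigfigs` significant
#' figures, and converts the reported value into a repeat-unit count
#' \eqn{n = (R_{rep}/(J^{1/3} l))^2} rounded to the nearest integer, with
#' \eqn{J} from the liquid content. `n` is computed from the *reported*
#' (rounded) `R`: estimates are only meaningful at the precision of the
#' underlying particle-diameter data, and downstream quantities follow the
#' reported value.
#'
#' @param name Gel name (character scalar).
#' @param d_avg Average spontaneously penetrating particle diameter (nm).
#' @param cl Liquid volume fraction in `[0, 1)`.
#' @param l Repeat-unit length (nm).
#' @param m_values Integer vector of coordinations to evaluate (each >= 3).
#' @param sigfigs Significant figures for the reported `R` (default 2,
#'   matching the precision of typical particle-sizing data).
#' @return A tibble with one row per `m`: `name`, `m`, `R_nm` (exact),
#'   `R_reported_nm` (rounded), `n`.
#' @examples
#' characterize_gel("intestinal mucus", d_avg = 210, cl = 0.95, l = 18,
#'                  m_values = c(3, 4))
#' @family spontaneous penetration
#' @export
characterize_gel <- function(name, d_avg, cl, l, m_values = c(3, 4), sigfigs = 2) {
  if (is.null(l) || is.null(cl) || anyNA(c(l, cl))) {
    stop_config("Both `l` and `cl` are required (no default available for this observation).")
  }
  if (d_avg <= 0) stop_domain("`d_avg` must be positive.")
  check_coordination(m_values)
  J <- swelling_from_liquid_content(cl)
  m_values <- sort(unique(as.integer(m_values)))
  R <- min_end_to_end(d_avg, m_values)
  R_rep <- signif(R, sigfigs)
  n <- monomers_from_R(R_rep, J = J, l = l, round_n = TRUE)
  sub <- n < 1
  if (any(sub)) {
    warn(sprintf(
      "%s: estimated chain shorter than one repeat unit at m = %s; n clamped to 1.",
      name, paste(m_values[sub], collapse = ", ")
    ), class = "gelpen_sub_monomer_warning")
    n <- pmax(n, 1)
  }
  tibble(name = name, m = m_values, R_nm = R, R_reported_nm = R_rep, n = n)
}

#' Characterize a table of gels
#'
#' Batch driver for [characterize_gel()]: one row of the result per
#' (gel, coordination) pair, in input order then ascending `m`. The input
#' is a data frame as returned by [read_gel_table()] (columns `name`,
#' `d_avg_nm`, `cl`, `l_nm`, `m_values`); `l_nm`/`cl` given as ranges are
#' resolved to their midpoint unless overridden.
#'
#' @param gels A data frame of gel observations; see [read_gel_table()]
#'   for the schema. `m_values` may be a list-column of integer vectors or
#'   a character column of semicolon-separated integers.
#' @param l_nm Optional repeat-unit length override (nm) applied to every
#'   row.
#' @param cl Optional liquid-content override applied to every row.
#' @param sigfigs Significant figures for reported `R`; see
#'   [characterize_gel()].
#' @return A tibble of class `gel_characterization` with columns
#'   `name`, `m`, `R_nm`, `R_reported_nm`, `n`.
#' @examples
#' gels <- read_gel_table(system.file("extdata", "table1_gels.csv",
#'                                    package = "gelpen"))
#' characterize_gels(gels)
#' @family spontaneous penetration
#' @export
characterize_gels <- function(gels, l_nm = NULL, cl = NULL, sigfigs = 2) {
  if (!is.data.frame(gels)) stop_validation("`gels` must be a data frame.")
  if (nrow(gels) == 0) {
    warn("Empty gel table: returning an empty characterization.")
    out <- tibble(name = character(), m = integer(), R_nm = double(),
                  R_reported_nm = double(), n = double())
    return(new_gel_characterization(out))
  }
  needed <- c("name", "d_avg_nm", "cl", "l_nm", "m_values")
  missing_cols <- setdiff(needed, names(gels))
  if (length(missing_cols)) {
    stop_validation(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  rows <- purrr::pmap(
    list(gels$name, gels$d_avg_nm, gels$cl, gels$l_nm, gels$m_values),
    function(name, d_avg, cl_row, l_row, m_row) {
      characterize_gel(
        name = name,
        d_avg = d_avg,
        cl = cl %||% range_midpoint(cl_row),
        l = l_nm %||% range_midpoint(l_row),
        m_values = parse_m_values(m_row),
        sigfigs = sigfigs
      )
    }
  )
  new_gel_characterization(bind_rows(rows))
}

new_gel_characterization <- function(x) {
  class(x) <- c("gel_characterization", class(x))
  x
}

## "0.87;0.99" or c(0.87, 0.99) or 0.95 -> midpoint scalar
range_midpoint <- function(x) {
  if (is.character(x)) {
    x <- suppressWarnings(as.numeric(strsplit(x, ";", fixed = TRUE)[[1]]))
  }
  if (is.list(x)) x <- unlist(x)
  if (anyNA(x) || !length(x)) stop_validation("Cannot parse numeric cell (expected a number or 'lo;hi').")
  mean(range(x))
}

parse_m_values <- function(x) {
  if (is.character(x)) {
    x <- suppressWarnings(as.integer(strsplit(x, ";", fixed = TRUE)[[1]]))
  }
  if (is.list(x)) x <- unlist(x)
  if (anyNA(x) || !length(x)) stop_validation("Cannot parse m_values (expected e.g. '3;4').")
  as.integer(x)
}
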