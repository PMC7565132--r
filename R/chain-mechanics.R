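## Freely-jointed-chain entropic elasticity and swelling/geometry relations.
## All forces are dimensionless, f*l/(kb*T); an SI layer converts on request.

## Stretches closer than this to full extension are treated as singular.
.extensibility_guard <- 1e-9

#' Rational approximant of the inverse Langevin function
#'
#' Entropic tension in a freely jointed chain follows the inverse of the
#' Langevin function \eqn{L(\beta) = \coth\beta - 1/\beta}. The exact inverse
#' has no closed form; this uses the rational (Pade-type) approximant
#' \deqn{\beta(x) = x (3 - x^2) / (1 - x^2),}
#' accurate to a few percent over the whole physical range and exact in both
#' the Gaussian limit (\eqn{\beta \to 3x} as \eqn{x \to 0}) and at the
#' finite-extensibility singularity \eqn{x \to 1}.
#'
#' @param x Fractional chain extension \eqn{r / (n l)}, in `[0, 1)`.
#'   Vectorised.
#' @return Dimensionless force \eqn{\beta = f l / (k_b T)} per chain.
#' @examples
#' inverse_langevin(c(0, 0.1, 0.5))
#' @family chain mechanics
#' @export
inverse_langevin <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_domain("`x` must be finite numeric.")
  }
  if (any(x < 0) || any(x >= 1 - .extensibility_guard)) {
    stop_domain(
      "Fractional extension must satisfy 0 <= x < 1: a chain cannot be stretched beyond its contour length."
    )
  }
  x * (3 - x^2) / (1 - x^2)
}

#' Derivative of the inverse Langevin approximant
#'
#' Closed-form derivative of [inverse_langevin()], used for the stiffening
#' slope analysis of the forced-penetration model.
#'
#' @inheritParams inverse_langevin
#' @return d\eqn{\beta}/dx at `x`.
#' @family chain mechanics
#' @export
inverse_langevin_prime <- function(x) {
  if (any(x < 0) || any(x >= 1 - .extensibility_guard)) {
    stop_domain("Fractional extension must satisfy 0 <= x < 1.")
  }
  (3 + x^4) / (1 - x^2)^2
}

#' Specify a network chain
#'
#' A chain between two cross-links is a freely jointed segment of `n` repeat
#' units of length `l` in a network swollen isotropically by a volumetric
#' factor `J`. Its referential (swollen, force-free) end-to-end length is
#' \eqn{R = J^{1/3} \sqrt{n}\, l} and the extensibility scale is
#' \eqn{\kappa = J^{1/3}/\sqrt{n}}: the argument of the inverse Langevin law
#' at stretch \eqn{\lambda} is \eqn{\lambda\kappa}, so the chain is fully
#' extended at \eqn{\lambda = 1/\kappa}.
#'
#' @param n Repeat units per chain (> 0).
#' @param l Repeat-unit length in nm (> 0).
#' @param J Volumetric swelling ratio, swollen over dry volume (>= 1).
#'   Give either `J` or `liquid_content`.
#' @param liquid_content Liquid volume fraction \eqn{c_l = (J-1)/J} in
#'   `[0, 1)`; converted to `J` via [swelling_from_liquid_content()].
#' @return An object of class `chain_spec` with fields `n`, `l`, `J`,
#'   `kappa`, `R`, `lambda_max`.
#' @examples
#' chain_spec(n = 24, l = 18, liquid_content = 0.95)
#' @family chain mechanics
#' @export
chain_spec <- function(n, l = 1, J = NULL, liquid_content = NULL) {
  if (is.null(J) && is.null(liquid_content)) {
    stop_config("Provide either `J` or `liquid_content`.")
  }
  if (is.null(J)) J <- swelling_from_liquid_content(liquid_content)
  if (!is.numeric(n) || length(n) != 1 || n <= 0) stop_domain("`n` must be a positive scalar.")
  if (!is.numeric(l) || length(l) != 1 || l <= 0) stop_domain("`l` must be a positive scalar (nm).")
  if (!is.numeric(J) || length(J) != 1 || J < 1) stop_domain("`J` must be a scalar >= 1.")
  kappa <- J^(1 / 3) / sqrt(n)
  if (kappa > 1) {
    stop_domain(
      sprintf(
        "kappa = J^(1/3)/sqrt(n) = %.3f > 1: the swollen end-to-end length exceeds the contour length.",
        kappa
      )
    )
  }
  structure(
    list(n = n, l = l, J = J, kappa = kappa,
         R = J^(1 / 3) * sqrt(n) * l, lambda_max = 1 / kappa),
    class = "chain_spec"
  )
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf(
    "<chain_spec> n = %g repeat units, l = %g nm, J = %g\n  R = %.4g nm, kappa = %.4g, lambda_max = %.4g\n",
    x$n, x$l, x$J, x$R, x$kappa, x$lambda_max
  ))
  invisible(x)
}

## Accept a chain_spec or a bare kappa scalar wherever only kappa matters.
as_kappa <- function(chain) {
  if (inherits(chain, "chain_spec")) return(chain$kappa)
  if (is.numeric(chain) && length(chain) == 1 && chain > 0 && chain < 1) return(chain)
  stop_domain("`chain` must be a chain_spec or a kappa scalar in (0, 1).")
}

#' Entropic chain force at a given stretch
#'
#' Dimensionless tension \eqn{f l/(k_b T) = \beta(\lambda\kappa)} of a
#' freely jointed chain stretched by \eqn{\lambda} relative to its swollen
#' referential end-to-end length, with
#' \eqn{\kappa = J^{1/3}/\sqrt{n}}.
#'
#' @param lambda Stretch ratio (>= 0). Vectorised.
#' @param chain A [chain_spec()] or a bare `kappa` scalar.
#' @return Dimensionless force \eqn{f l/(k_b T)}.
#' @examples
#' chain_force(1, chain = 0.1)          # beta(0.1) = 0.30202...
#' chain_force(1:3, chain_spec(24, 18, J = 20))
#' @family chain mechanics
#' @export
chain_force <- function(lambda, chain) {
  kappa <- as_kappa(chain)
  if (any(lambda < 0)) stop_domain("Stretch `lambda` must be non-negative.")
  if (any(lambda * kappa >= 1 - .extensibility_guard)) {
    stop_extensibility(
      sprintf(
        "Chain fully extended: lambda * kappa >= 1 (lambda_max = %.6g).",
        1 / kappa
      )
    )
  }
  inverse_langevin(lambda * kappa)
}

#' Convert a dimensionless chain force to newtons
#'
#' Multiplies \eqn{f l/(k_b T)} by \eqn{k_b T / l} with
#' \eqn{k_b = 1.380649\times 10^{-23}} J/K.
#'
#' @param f Dimensionless force \eqn{f l/(k_b T)}.
#' @param l_nm Repeat-unit length in nm.
#' @param temperature_K Absolute temperature; default 310 K (body
#'   temperature, the natural choice for mucosal gels).
#' @return Force in newtons.
#' @family chain mechanics
#' @export
force_si <- function(f, l_nm, temperature_K = 310) {
  if (any(l_nm <= 0) || any(temperature_K <= 0)) {
    stop_domain("`l_nm` and `temperature_K` must be positive.")
  }
  f * .kb * temperature_K / (l_nm * 1e-9)
}

#' Volumetric swelling ratio from liquid content
#'
#' A gel holding a liquid volume fraction \eqn{c_l} has swollen-to-dry
#' volume ratio \eqn{J = 1/(1 - c_l)}, i.e. \eqn{c_l = (J-1)/J}.
#'
#' @param cl Liquid volume fraction in `[0, 1)`. Vectorised.
#' @return Swelling ratio `J >= 1`.
#' @examples
#' swelling_from_liquid_content(0.95)  # 20: a typical mucus gel
#' @family chain mechanics
#' @export
swelling_from_liquid_content <- function(cl) {
  if (any(!is.finite(cl)) || any(cl < 0) || any(cl >= 1)) {
    stop_domain("Liquid content must satisfy 0 <= cl < 1.")
  }
  1 / (1 - cl)
}

#' Liquid content from swelling ratio
#'
#' Inverse of [swelling_from_liquid_content()]: \eqn{c_l = (J-1)/J}.
#'
#' @param J Volumetric swelling ratio (>= 1). Vectorised.
#' @return Liquid volume fraction in `[0, 1)`.
#' @family chain mechanics
#' @export
liquid_content <- function(J) {
  if (any(!is.finite(J)) || any(J < 1)) stop_domain("`J` must be >= 1.")
  (J - 1) / J
}

#' Referential end-to-end length of a swollen chain
#'
#' \eqn{R = J^{1/3} \sqrt{n}\, l}: the random-walk end-to-end distance
#' \eqn{\sqrt{n}\,l} of the dry chain, dilated by the isotropic swelling
#' stretch \eqn{J^{1/3}}.
#'
#' @param chain A [chain_spec()].
#' @return End-to-end length in nm.
#' @examples
#' referential_end_to_end(chain_spec(24, 18, J = 20))  # ~239 nm
#' @family chain mechanics
#' @export
referential_end_to_end <- function(chain) {
  if (!inherits(chain, "chain_spec")) stop_domain("`chain` must be a chain_spec.")
  chain$R
}

#' Repeat units per chain from the end-to-end length
#'
#' Inverts \eqn{R = J^{1/3}\sqrt{n}\,l} to \eqn{n = (R/(J^{1/3} l))^2}.
#' This is the step that turns a mesh-size estimate into a chain-length
#' estimate in gel characterization.
#'
#' @param R End-to-end length in nm (> 0). Vectorised.
#' @param J Volumetric swelling ratio (>= 1).
#' @param l Repeat-unit length in nm (> 0).
#' @param round_n Round to the nearest integer (the reporting convention
#'   used throughout the characterization pipeline)? Default `TRUE`.
#' @return Number of repeat units (possibly fractional if `round_n = FALSE`).
#' @examples
#' monomers_from_R(240, J = 20, l = 18)  # 24
#' @family chain mechanics
#' @export
monomers_from_R <- function(R, J, l, round_n = TRUE) {
  if (any(R <= 0) || any(l <= 0)) stop_domain("`R` and `l` must be positive.")
  if (any(J < 1)) stop_domain("`J` must be >= 1.")
  n <- (R / (J^(1 / 3) * l))^2
  if (round_n) round(n) else n
}
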