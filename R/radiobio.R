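#' Radiobiological model parameters
#'
#' Bundles the parameters of the scoring models: the volume-effect exponent
#' `a` of the generalized EUD and the `D50` / `gamma` pair of the logistic
#' TCP curve.  The defaults target microscopic nodal disease in lung cancer:
#' `D50 = 36.5` Gy and `gamma = 0.72`.  No published value of `a` exists for
#' this setting; the default `a = -8` is a package modelling choice (a
#' target-type exponent, pulling the EUD a few Gy below the mean dose for
#' heterogeneous distributions) and should be set explicitly when it matters.
#'
#' @param a EUD volume-effect exponent (dimensionless, nonzero). Negative
#'   values emphasise cold spots (target-type behaviour).
#' @param d50 dose yielding 50% control probability (Gy, > 0).
#' @param gamma normalized slope of the dose-response curve at `d50` (> 0).
#' @return An object of class `radiobio_params`.
#' @examples
#' radiobio_params()            # defaults for microscopic disease
#' radiobio_params(a = -10)
#' @export
radiobio_params <- function(a = -8, d50 = 36.5, gamma = 0.72) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a == 0)
    stop("`a` must be a single nonzero number", call. = FALSE)
  if (!is.numeric(d50) || length(d50) != 1L || !is.finite(d50) || d50 <= 0)
    stop("`d50` must be a single positive dose (Gy)", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("`gamma` must be a single positive number", call. = FALSE)
  structure(list(a = a, d50 = d50, gamma = gamma), class = "radiobio_params")
}

#' @export
print.radiobio_params <- function(x, ...) {
  cat(sprintf("<radiobio_params> a = %g, D50 = %g Gy, gamma = %g\n",
              x$a, x$d50, x$gamma))
  invisible(x)
}

#' Generalized equivalent uniform dose (EUD)
#'
#' The generalized EUD is the power mean of the dose distribution,
#' \deqn{EUD = \left(\frac{1}{N} \sum_i D_i^a\right)^{1/a},}
#' evaluated here on the DVH with fractional volumes as weights.  `a = 1`
#' recovers the mean dose exactly; `a -> +Inf` tends to the maximum and
#' `a -> -Inf` to the minimum occupied dose.  The EUD is positively
#' homogeneous of degree 1 in dose, which is what makes linear plan
#' rescaling commute with EUD-based scoring.
#'
#' For `a < 0` a distribution with any zero-dose volume has EUD 0 in the
#' limit; that value is returned with a warning rather than raising a
#' numerical fault.  `a = 0` (the geometric mean) is not part of the model
#' and is a domain error.
#'
#' @param dvh a `dvh` object (either form).
#' @param a volume-effect exponent; defaults to the [radiobio_params()]
#'   default.
#' @return EUD in Gy.
#' @examples
#' d <- dvh_from_points(c(20, 60), c(0.5, 0.5))
#' eud(d, a = 1)    # 40 Gy, the mean
#' eud(d, a = 2)    # 44.72 Gy
#' eud(d, a = -10)  # 21.43 Gy, cold-spot weighted
#' @export
eud <- function(dvh, a = radiobio_params()$a) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stop("`a` must be a single finite number", call. = FALSE)
  if (a == 0)
    stop("domain error: a = 0 is not defined for the generalized EUD",
         call. = FALSE)
  dd <- to_differential(dvh)
  occ <- dd$volume > 0
  d <- dd$dose[occ]
  v <- dd$volume[occ]
  v <- v / sum(v)
  if (a < 0 && any(d <= 0)) {
    warning("zero-dose volume with a < 0: EUD is the limit value 0 Gy",
            call. = FALSE)
    return(0)
  }
  if (all(d == 0)) return(0)
  # rescale so the powered ratios stay in (0, 1]: by max(d) for a > 0,
  # by min occupied dose for a < 0 (avoids overflow at large |a|)
  ref <- if (a > 0) max(d) else min(d)
  ref * sum(v * (d / ref)^a)^(1 / a)
}

#' Logistic tumour control probability (TCP)
#'
#' Evaluates the logistic dose-response model
#' \deqn{TCP(D) = \frac{1}{1 + (D_{50}/D)^{4\gamma}},}
#' where `D50` is the dose giving 50% control and `gamma` the normalized
#' slope of the sigmoid at `D50` (so `D50 * dTCP/dD` at `D50` equals
#' `gamma` exactly).  The curve is strictly increasing in `D` with limits 0
#' and 1.  Non-positive doses return the limit value 0 with a warning.
#'
#' No fractionation (EQD2) correction is applied: the model is evaluated on
#' physical dose, here usually an EUD.
#'
#' @param D total dose in Gy (vectorised).
#' @param params a [radiobio_params()] object.
#' @return Control probability in \[0, 1\], same length as `D`.
#' @examples
#' tcp(36.5)   # 0.5 at D50
#' tcp(44.2)   # ~0.634
#' @export
tcp <- function(D, params = radiobio_params()) {
  stopifnot(inherits(params, "radiobio_params"))
  if (!is.numeric(D) || length(D) == 0L || anyNA(D) || any(!is.finite(D)))
    stop("`D` must be finite dose(s) in Gy", call. = FALSE)
  out <- numeric(length(D))
  pos <- D > 0
  if (any(!pos))
    warning("non-positive dose: TCP is the limit value 0", call. = FALSE)
  out[pos] <- 1 / (1 + (params$d50 / D[pos])^(4 * params$gamma))
  out
}

#' TCP of a dose distribution via its EUD
#'
#' The composition `tcp(eud(dvh, params$a), params)`: the heterogeneous
#' distribution is first reduced to its equivalent uniform dose, which is
#' then scored by the logistic dose-response model.  Note that across a
#' cohort the mean of per-patient TCPs is not the TCP of the mean EUD
#' (Jensen's inequality); cohort reporting always averages per-patient TCPs.
#'
#' @param dvh a `dvh` object.
#' @param params a [radiobio_params()] object.
#' @return Control probability in \[0, 1\].
#' @export
tcp_from_dvh <- function(dvh, params = radiobio_params()) {
  stopifnot(inherits(params, "radiobio_params"))
  tcp(eud(dvh, params$a), params)
}
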