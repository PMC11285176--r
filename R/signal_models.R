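#' FROC model parameter set
#'
#' Validated container for the three fractional-order calculus diffusion
#' parameters: the anomalous diffusion coefficient D (um^2/ms, equal
#' numerically to 10^-3 mm^2/s), the intravoxel diffusion heterogeneity
#' beta (unitless, 0 < beta <= 1; lower values mean a more heterogeneous
#' voxel) and the spatial constant mu (um), which preserves the nominal
#' units of D for beta < 1.
#'
#' @param D anomalous diffusion coefficient (um^2/ms), > 0.
#' @param beta intravoxel diffusion heterogeneity, 0 < beta <= 1.
#' @param mu spatial constant (um), > 0.
#' @return An object of class `froc_params`.
#' @export
froc_params <- function(D, beta, mu) {
  if (!is.finite(D) || D <= 0) stop("D must be > 0")
  if (!is.finite(beta) || beta <= 0 || beta > 1)
    stop("beta must satisfy 0 < beta <= 1")
  if (!is.finite(mu) || mu <= 0) stop("mu must be > 0")
  structure(list(D = as.numeric(D), beta = as.numeric(beta),
                 mu = as.numeric(mu)), class = "froc_params")
}

#' @export
print.froc_params <- function(x, ...) {
  cat(sprintf("FROC parameters: D = %.4g um2/ms, beta = %.4g, mu = %.4g um\n",
              x$D, x$beta, x$mu))
  invisible(x)
}

#' Mono-exponential model parameter set
#'
#' @param adc apparent diffusion coefficient (um^2/ms), >= 0.
#' @return An object of class `monoexp_params`.
#' @export
monoexp_params <- function(adc) {
  if (!is.finite(adc) || adc < 0) stop("adc must be >= 0")
  structure(list(adc = as.numeric(adc)), class = "monoexp_params")
}

#' FROC diffusion signal model
#'
#' Normalised signal \eqn{S_b/S_0} of the fractional-order calculus model
#' \deqn{S_b/S_0 = \exp\left[-D\,\mu^{2(\beta-1)}\,q^{2\beta}
#'   \left(\Delta - \frac{2\beta-1}{2\beta+1}\delta\right)\right],}
#' with the gradient factor \eqn{q = \gamma G_d \delta} obtained from the
#' nominal b-value by [b_to_gradient_factor()]. At beta = 1 the expression
#' collapses exactly to \eqn{\exp(-b D)}.
#'
#' Note that for a protocol with fixed timings D and mu enter only through
#' the decay coefficient \eqn{D\,\mu^{2(\beta-1)}}; see
#' [froc_decay_coefficient()] and the package vignette for the
#' identifiability consequences.
#'
#' @param params a [froc_params()] object.
#' @param b diffusion weighting(s), s/mm^2.
#' @param protocol a [dwi_protocol()].
#' @return normalised signal value(s) in (0, 1].
#' @export
froc_signal <- function(params, b, protocol) {
  if (!inherits(params, "froc_params")) params <- do.call(froc_params, params)
  q <- b_to_gradient_factor(b, protocol)
  expo <- params$D * params$mu^(2 * (params$beta - 1)) * q^(2 * params$beta) *
    froc_time_factor(params$beta, protocol)
  exp(-expo)
}

# effective diffusion time (ms) of the fractional model exponent
froc_time_factor <- function(beta, protocol) {
  protocol$big_delta -
    (2 * beta - 1) / (2 * beta + 1) * protocol$delta
}

#' Identifiable FROC decay coefficient
#'
#' The combination \eqn{D\,\mu^{2(\beta-1)}} through which D and mu act on
#' the signal when the gradient timings are fixed across b-values. Together
#' with beta this coefficient determines the whole decay curve, which is why
#' round-trip recovery is assessed on (beta, decay coefficient) rather than
#' on D and mu separately.
#'
#' @param params a [froc_params()] (or a list with D, beta, mu).
#' @return numeric scalar, units um^(2 beta)/ms.
#' @export
froc_decay_coefficient <- function(params) {
  params$D * params$mu^(2 * (params$beta - 1))
}

#' Mono-exponential diffusion signal model
#'
#' \eqn{S_b/S_0 = \exp(-b\,\mathrm{ADC})} with b converted to ms/um^2 so
#' that ADC is in um^2/ms.
#'
#' @param params a [monoexp_params()] object (or bare ADC value).
#' @param b diffusion weighting(s), s/mm^2.
#' @return normalised signal value(s) in (0, 1].
#' @export
monoexp_signal <- function(params, b) {
  adc <- if (inherits(params, "monoexp_params")) params$adc else
    monoexp_params(params)$adc
  if (any(!is.finite(b)) || any(b < 0)) stop("b must be finite and >= 0")
  exp(-b_si_to_ms_um2(b) * adc)
}
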