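#' Default box constraints of the FROC fit
#'
#' D in [1e-4, 4] um^2/ms, beta in [0.05, 1], mu in [0.1, 20] um. The
#' model itself constrains only 0 < beta <= 1; the remaining limits bracket
#' the physiologically plausible range and keep the bounded trust-region
#' Levenberg-Marquardt steps well scaled.
#'
#' @return list with numeric vectors `lower` and `upper` (D, beta, mu).
#' @export
froc_fit_bounds <- function() {
  list(lower = c(D = 1e-4, beta = 0.05, mu = 0.1),
       upper = c(D = 4, beta = 1, mu = 20))
}

fit_result <- function(params, residual_norm, converged, n_iter) {
  structure(list(params = params, residual_norm = residual_norm,
                 converged = converged, n_iter = n_iter),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  print(x$params)
  cat(sprintf("  SSR = %.3g, converged = %s, iterations = %d\n",
              x$residual_norm, x$converged, x$n_iter))
  invisible(x)
}

# normalise a raw signal vector by its measured b=0 intensity
.normalise_signal <- function(signal, protocol) {
  if (length(signal) != length(protocol$b_values))
    stop("signal length must equal the protocol's number of b-values")
  s0 <- signal[protocol$b_values == 0][1]
  if (!is.finite(s0) || s0 <= 0)
    stop("signal at b = 0 must be positive")
  signal / s0
}

#' Mono-exponential (ADC) fit
#'
#' Nonlinear least-squares fit of \eqn{S_b/S_0 = \exp(-b\,\mathrm{ADC})}
#' over all b-values (not the log-linearised form, for symmetry with the
#' FROC fit and correct weighting of the low-signal high-b points). The
#' signal is normalised by the measured b=0 intensity.
#'
#' @param signal numeric vector of magnitudes, one per protocol b-value.
#' @param protocol a [dwi_protocol()].
#' @return a `fit_result` whose `params` is a [monoexp_params()].
#' @export
fit_monoexp <- function(signal, protocol = protocol_14b()) {
  y <- .normalise_signal(signal, protocol)
  bms <- b_si_to_ms_um2(protocol$b_values)
  # log-linear warm start on the positive part of the signal
  pos <- y > 0 & bms > 0
  init <- if (any(pos)) max(0.01, -stats::coef(
    stats::lm(log(y[pos]) ~ 0 + bms[pos]))[[1]]) else 0.01
  fit <- minpack.lm::nls.lm(
    par = c(adc = init),
    fn = function(p) y - exp(-bms * p[1]),
    lower = 0, upper = 50,
    control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-10))
  fit_result(monoexp_params(max(0, fit$par[[1]])),
             residual_norm = fit$deviance,
             converged = fit$info %in% 1:4, n_iter = fit$niter)
}

#' FROC model fit
#'
#' Bounded Levenberg-Marquardt fit of the three FROC parameters to a
#' normalised multi-b-value decay. Initialisation: D from the voxel's
#' mono-exponential ADC (clamped into bounds), beta = 0.9, mu = 5 um; if
#' the first solution sits on a box bound, one restart from
#' (D0, 0.6, 2.5) is tried and the lower-residual solution kept.
#'
#' Identifiability: with fixed gradient timings the data determine beta
#' and the decay coefficient \eqn{D\,\mu^{2(\beta-1)}} only — the Jacobian
#' columns of D and mu are exactly parallel — so the returned D and mu are
#' one point on the zero-residual ridge selected by the initialisation.
#' `froc_decay_coefficient(fit$params)` and `fit$params$beta` are the
#' estimates with a data-determined meaning; see the package vignette.
#'
#' @param signal numeric vector of magnitudes, one per protocol b-value
#'   (at least 4 distinct b-values including 0).
#' @param protocol a [dwi_protocol()].
#' @param init `"auto"` (default) or a [froc_params()] to start from.
#' @param bounds list with `lower` and `upper` length-3 vectors
#'   (default [froc_fit_bounds()]).
#' @return a `fit_result` whose `params` is a [froc_params()], with an
#'   extra element `decay_coefficient`.
#' @export
fit_froc <- function(signal, protocol = protocol_14b(), init = "auto",
                     bounds = froc_fit_bounds()) {
  if (length(unique(protocol$b_values)) < 4L)
    stop("FROC fit needs at least 4 distinct b-values including 0")
  y <- .normalise_signal(signal, protocol)
  q <- b_to_gradient_factor(protocol$b_values, protocol)
  model <- function(p)
    exp(-p[1] * p[3]^(2 * (p[2] - 1)) * q^(2 * p[2]) *
          froc_time_factor(p[2], protocol))
  resid_fn <- function(p) y - model(p)
  lo <- bounds$lower; hi <- bounds$upper
  if (identical(init, "auto")) {
    d0 <- fit_monoexp(signal, protocol)$params$adc
    start <- c(D = min(max(d0, lo[1] * 2), hi[1] * 0.9), beta = 0.9, mu = 5)
  } else {
    stopifnot(inherits(init, "froc_params"))
    start <- c(D = init$D, beta = init$beta, mu = init$mu)
  }
  run <- function(p0) minpack.lm::nls.lm(
    par = p0, fn = resid_fn, lower = unname(lo), upper = unname(hi),
    control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 5000,
                                         ptol = 1e-8, ftol = 1e-12))
  fit <- run(start)
  on_bound <- any(abs(fit$par - lo) < 1e-8 * pmax(1, abs(lo))) ||
    any(abs(fit$par - hi) < 1e-8 * pmax(1, abs(hi)))
  if (on_bound) {
    fit2 <- run(c(D = unname(start[1]), beta = 0.6, mu = 2.5))
    if (fit2$deviance < fit$deviance) fit <- fit2
  }
  p <- fit$par
  out <- fit_result(froc_params(p[[1]], p[[2]], p[[3]]),
                    residual_norm = fit$deviance,
                    converged = fit$info %in% 1:4, n_iter = fit$niter)
  out$decay_coefficient <- froc_decay_coefficient(out$params)
  out
}

#' Voxel-wise parameter maps
#'
#' Fits both the mono-exponential and the FROC model in every masked voxel
#' of a series and assembles parameter maps with a convergence QC mask.
#' Unmasked voxels are NA.
#'
#' @param series a [dwi_series()].
#' @param mask logical 3-D array matching the series grid.
#' @return list of 3-D arrays `D`, `beta`, `mu`, `adc`,
#'   `decay_coefficient`, logical `converged`, plus the `mask`.
#' @export
fit_volume <- function(series, mask) {
  stopifnot(inherits(series, "dwi_series"))
  g <- dim(series$data)[1:3]
  if (!identical(dim(mask), as.integer(g)) && !identical(dim(mask), g))
    stop("mask must match the series grid")
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")
  mk <- function() array(NA_real_, g)
  maps <- list(D = mk(), beta = mk(), mu = mk(), adc = mk(),
               decay_coefficient = mk(),
               converged = array(FALSE, g), mask = array(as.logical(mask), g))
  nb <- dim(series$data)[4]
  flat <- matrix(series$data, ncol = nb)
  for (i in idx) {
    sig <- flat[i, ]
    ok <- TRUE
    me <- tryCatch(fit_monoexp(sig, series$protocol), error = function(e) NULL)
    fr <- tryCatch(fit_froc(sig, series$protocol), error = function(e) NULL)
    if (is.null(me) || is.null(fr)) ok <- FALSE
    if (!is.null(me)) maps$adc[i] <- me$params$adc
    if (!is.null(fr)) {
      maps$D[i] <- fr$params$D
      maps$beta[i] <- fr$params$beta
      maps$mu[i] <- fr$params$mu
      maps$decay_coefficient[i] <- fr$decay_coefficient
      ok <- ok && fr$converged && me$converged
    }
    maps$converged[i] <- isTRUE(ok)
  }
  maps
}

#' VOI summary statistics
#'
#' Mean and sample SD of a parameter map over a volume of interest,
#' restricted to converged voxels.
#'
#' @param map 3-D numeric array (one entry of [fit_volume()]'s output).
#' @param voi_mask logical 3-D array, non-empty.
#' @param converged optional logical array of QC flags; default all TRUE.
#' @return list with `mean`, `sd` and `n` (voxels used).
#' @export
voi_statistics <- function(map, voi_mask, converged = NULL) {
  stopifnot(identical(dim(map), dim(voi_mask)))
  use <- as.logical(voi_mask)
  if (!any(use)) stop("VOI is empty")
  if (!is.null(converged)) use <- use & as.logical(converged)
  vals <- map[use]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("no converged voxels inside the VOI")
  list(mean = mean(vals),
       sd = if (length(vals) > 1L) stats::sd(vals) else 0,
       n = length(vals))
}
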