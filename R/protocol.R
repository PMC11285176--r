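#' Diffusion acquisition protocol
#'
#' Bundles the experimental context every multi-b-value signal is tied to:
#' the nominal b-values (s/mm\eqn{^2}), the number of signal averages
#' acquired at each b, and the diffusion gradient timings \eqn{\delta}
#' (pulse width, ms) and \eqn{\Delta} (gradient interval, ms).
#'
#' The proton gyromagnetic ratio \eqn{\gamma} is carried along as a
#' documented physical constant (42.577 MHz/T expressed in rad/ms/mT units
#' is never needed numerically: the gradient amplitude enters the FROC
#' exponent only through the gradient factor \eqn{q = \gamma G_d \delta},
#' which [b_to_gradient_factor()] recovers directly from the nominal b).
#'
#' @param b_values numeric vector of diffusion weightings (s/mm^2),
#'   non-negative, strictly increasing, containing 0.
#' @param n_averages integer vector, one entry per b-value, each >= 1.
#' @param delta diffusion gradient pulse width (ms), 0 < delta < big_delta.
#' @param big_delta diffusion gradient interval (ms).
#' @return An object of class `dwi_protocol`.
#' @seealso [protocol_14b()] for the bundled 14-b-value breast protocol.
#' @export
dwi_protocol <- function(b_values, n_averages = rep(1L, length(b_values)),
                         delta, big_delta) {
  b_values <- as.numeric(b_values)
  n_averages <- as.integer(n_averages)
  if (length(b_values) < 1L || any(!is.finite(b_values)) || any(b_values < 0))
    stop("b_values must be finite and non-negative")
  if (is.unsorted(b_values, strictly = TRUE))
    stop("b_values must be strictly increasing")
  if (b_values[1L] != 0)
    stop("b_values must contain 0 (normalisation volume)")
  if (length(n_averages) != length(b_values))
    stop("n_averages must have one entry per b-value")
  if (any(is.na(n_averages)) || any(n_averages < 1L))
    stop("every n_averages entry must be >= 1")
  if (!is.finite(delta) || !is.finite(big_delta) || delta <= 0 ||
      delta >= big_delta)
    stop("gradient timings must satisfy 0 < delta < big_delta")
  structure(
    list(b_values = b_values, n_averages = n_averages,
         delta = as.numeric(delta), big_delta = as.numeric(big_delta),
         gamma = 267.513e-3),  # rad / (ms * mT), documented constant only
    class = "dwi_protocol")
}

#' @export
print.dwi_protocol <- function(x, ...) {
  cat("DWI acquisition protocol\n")
  cat(sprintf("  %d b-values (s/mm2): %s\n", length(x$b_values),
              paste(format(x$b_values), collapse = ", ")))
  cat(sprintf("  averages per b: %s\n",
              paste(x$n_averages, collapse = ", ")))
  cat(sprintf("  delta = %.2f ms, Delta = %.2f ms\n", x$delta, x$big_delta))
  invisible(x)
}

#' Bundled 14-b-value breast DWI protocol
#'
#' The multi-b-value protocol used throughout the package examples and
#' defaults: 14 b-values from 0 to 3000 s/mm^2 with 1-3 averages each and
#' monopolar gradient timings delta = 25.66 ms, Delta = 30.13 ms.
#'
#' @return A [dwi_protocol()] object.
#' @export
protocol_14b <- function() {
  read_protocol(system.file("extdata", "protocol_14b.yaml",
                            package = "frocdwi", mustWork = TRUE))
}

#' Read / write a protocol sidecar
#'
#' Plain-text YAML sidecar listing b-values, per-b averages and the
#' gradient timings, so a series on disk is self-describing.
#'
#' @param path file path of the YAML sidecar.
#' @return `read_protocol()` returns a [dwi_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("b_values", "n_averages", "delta", "big_delta")
  if (!all(need %in% names(y)))
    stop("protocol sidecar must define: ", paste(need, collapse = ", "))
  dwi_protocol(y$b_values, y$n_averages, y$delta, y$big_delta)
}

#' @rdname read_protocol
#' @param protocol a [dwi_protocol()] object.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "dwi_protocol"))
  yaml::write_yaml(
    list(b_values = protocol$b_values,
         n_averages = as.integer(protocol$n_averages),
         delta = protocol$delta, big_delta = protocol$big_delta),
    path)
  invisible(path)
}

# b in s/mm^2 -> b in ms/um^2 (1000 s/mm^2 == 1 ms/um^2)
b_si_to_ms_um2 <- function(b) b / 1000

#' Gradient factor from a nominal b-value
#'
#' Recovers the gradient factor \eqn{q = \gamma G_d \delta} (1/um) from the
#' nominal diffusion weighting via the Stejskal-Tanner relation
#' \eqn{b = q^2 (\Delta - \delta/3)}, with b converted to ms/um^2. This is
#' the conventional practical parameterisation for fractional-order fits of
#' scanner data, where the per-b gradient amplitude is not exported; it also
#' makes the FROC model reduce exactly to the mono-exponential at beta = 1.
#'
#' @param b diffusion weighting(s), s/mm^2, non-negative.
#' @param protocol a [dwi_protocol()].
#' @return gradient factor(s) q in 1/um.
#' @export
b_to_gradient_factor <- function(b, protocol) {
  stopifnot(inherits(protocol, "dwi_protocol"))
  if (any(!is.finite(b)) || any(b < 0)) stop("b must be finite and >= 0")
  sqrt(b_si_to_ms_um2(b) / (protocol$big_delta - protocol$delta / 3))
}
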