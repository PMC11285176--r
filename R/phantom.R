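#' 4-D diffusion-weighted series
#'
#' A stack of 3-D magnitude volumes, one per b-value, tied to the protocol
#' that produced it. The fourth array dimension indexes b.
#'
#' @param data 4-D non-negative numeric array (x, y, z, b-index).
#' @param protocol a [dwi_protocol()]; its number of b-values must equal
#'   `dim(data)[4]`.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(data, protocol) {
  stopifnot(inherits(protocol, "dwi_protocol"))
  if (length(dim(data)) != 4L)
    stop("data must be a 4-D array (x, y, z, b)")
  if (dim(data)[4L] != length(protocol$b_values))
    stop("4th dimension must match the protocol's number of b-values")
  if (any(data < 0)) stop("magnitude data must be non-negative")
  structure(list(data = data, protocol = protocol), class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI series: %d x %d x %d grid, %d b-values (max %g s/mm2)\n",
              d[1], d[2], d[3], d[4], max(x$protocol$b_values)))
  invisible(x)
}

#' Digital phantom specification
#'
#' Describes a rectangular voxel grid holding ellipsoidal lesions embedded
#' in homogeneous background tissue, with a signal-free air slab along the
#' first axis for background-noise measurements. Each compartment carries
#' its own FROC ground truth and b=0 intensity.
#'
#' @param grid_shape integer vector of 3 positive voxel counts.
#' @param voxel_size physical voxel size, mm per axis (length 3).
#' @param lesions list of lesions, each a list with `center` (voxel
#'   coordinates, length 3), `semi_axes` (voxels, length 3), `params`
#'   (a [froc_params()]) and `s0` (b=0 intensity).
#' @param background list with `params` ([froc_params()]) and `s0` for
#'   normal tissue.
#' @param air_fraction proportion of the first axis set aside as
#'   signal-free air (default 0.2).
#' @param noise_sigma Gaussian channel SD of the Rician noise, in the same
#'   units as `s0` (default 0, i.e. noiseless).
#' @param seed integer seed used when the phantom is simulated.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size = c(1, 1, 4),
                         lesions = list(), background,
                         air_fraction = 0.2, noise_sigma = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            is.finite(noise_sigma), noise_sigma >= 0,
            air_fraction >= 0, air_fraction < 1)
  stopifnot(is.list(background), inherits(background$params, "froc_params"),
            background$s0 > 0)
  for (les in lesions) {
    stopifnot(length(les$center) == 3L, length(les$semi_axes) == 3L,
              all(les$semi_axes > 0), inherits(les$params, "froc_params"),
              les$s0 > 0)
    if (any(les$center - les$semi_axes < 1) ||
        any(les$center + les$semi_axes > grid_shape))
      stop("lesion extends outside the grid")
  }
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 lesions = lesions, background = background,
                 air_fraction = air_fraction, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Ground-truth parameter maps of a phantom
#'
#' Rasterises a [phantom_spec()] into per-voxel maps of D, beta, mu and S0
#' plus an integer label mask: 0 = air, 1 = background tissue, 2, 3, ... =
#' lesions in list order. Overlapping lesions are resolved in favour of the
#' later lesion, with a warning.
#'
#' @param spec a [phantom_spec()].
#' @return list with arrays `D`, `beta`, `mu`, `s0` and integer array
#'   `label`, all of `spec$grid_shape`.
#' @export
generate_parameter_maps <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape
  lab <- array(1L, g)
  n_air <- floor(spec$air_fraction * g[1])
  if (n_air > 0) lab[seq_len(n_air), , ] <- 0L
  D <- array(spec$background$params$D, g)
  beta <- array(spec$background$params$beta, g)
  mu <- array(spec$background$params$mu, g)
  s0 <- array(spec$background$s0, g)
  s0[lab == 0L] <- 0
  ax <- lapply(1:3, function(i) seq_len(g[i]))
  for (k in seq_along(spec$lesions)) {
    les <- spec$lesions[[k]]
    dx <- (ax[[1]] - les$center[1]) / les$semi_axes[1]
    dy <- (ax[[2]] - les$center[2]) / les$semi_axes[2]
    dz <- (ax[[3]] - les$center[3]) / les$semi_axes[3]
    inside <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= 1
    if (any(lab[inside] > 1L))
      warning(sprintf("lesion %d overlaps an earlier lesion; later wins", k))
    lab[inside] <- k + 1L
    D[inside] <- les$params$D
    beta[inside] <- les$params$beta
    mu[inside] <- les$params$mu
    s0[inside] <- les$s0
  }
  list(D = D, beta = beta, mu = mu, s0 = s0, label = lab)
}

#' Simulate a multi-b-value series from parameter maps
#'
#' Forward-evaluates the FROC model per voxel and b-value and applies
#' Rician noise: each of the protocol's `n_averages[b]` acquisitions is the
#' magnitude of the noiseless complex signal plus independent Gaussian
#' noise of SD `noise_sigma` in both channels, and the stored volume is the
#' mean of those magnitudes (magnitude-then-average, as scanners combine
#' repeated measurements). With `noise_sigma = 0` the forward model is
#' reproduced exactly. Air voxels (label 0) have zero true signal, so their
#' magnitudes are Rayleigh draws.
#'
#' @param maps output of [generate_parameter_maps()].
#' @param protocol a [dwi_protocol()].
#' @param noise_sigma Gaussian channel SD (S0 units).
#' @param seed integer seed (`NULL` to leave the RNG stream alone).
#' @return a [dwi_series()].
#' @export
simulate_dwi_series <- function(maps, protocol, noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(protocol, "dwi_protocol"),
            is.finite(noise_sigma), noise_sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  g <- dim(maps$s0)
  nb <- length(protocol$b_values)
  out <- array(0, c(g, nb))
  nvox <- prod(g)
  for (j in seq_len(nb)) {
    b <- protocol$b_values[j]
    q <- b_to_gradient_factor(b, protocol)
    tf <- froc_time_factor(maps$beta, protocol)
    clean <- maps$s0 *
      exp(-maps$D * maps$mu^(2 * (maps$beta - 1)) * q^(2 * maps$beta) * tf)
    if (noise_sigma == 0) {
      out[, , , j] <- clean
    } else {
      nav <- protocol$n_averages[j]
      acc <- array(0, g)
      for (a in seq_len(nav)) {
        re <- clean + stats::rnorm(nvox, sd = noise_sigma)
        im <- stats::rnorm(nvox, sd = noise_sigma)
        acc <- acc + sqrt(re^2 + im^2)
      }
      out[, , , j] <- acc / nav
    }
  }
  dwi_series(out, protocol)
}

#' Simulate a phantom end to end
#'
#' Convenience wrapper: rasterise the spec and simulate the series with the
#' spec's noise level and seed.
#'
#' @param spec a [phantom_spec()].
#' @param protocol a [dwi_protocol()] (default the bundled 14-b protocol).
#' @return list with `maps` and `series`.
#' @export
simulate_phantom <- function(spec, protocol = protocol_14b()) {
  maps <- generate_parameter_maps(spec)
  series <- simulate_dwi_series(maps, protocol, spec$noise_sigma, spec$seed)
  list(maps = maps, series = series)
}

#' Two-group lesion cohort specification
#'
#' Distributional recipe for a benign/malignant lesion cohort: per
#' parameter (D, beta, mu, adc) and per sequence (SSEPI, SMS) a truncated
#' normal with the given mean and SD in each group, the two sequences of a
#' lesion coupled through a Gaussian copula with the given between-sequence
#' correlation. Defaults are the reference breast-lesion moments bundled
#' with the package (73 benign, 105 malignant lesions).
#'
#' @param n_benign,n_malignant group sizes.
#' @param moments data frame with columns parameter, sequence, benign_mean,
#'   benign_sd, malignant_mean, malignant_sd.
#' @param seq_correlation named numeric vector, Spearman correlation
#'   between the two sequences for each parameter.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_benign = 73L, n_malignant = 105L,
                        moments = default_cohort_moments(),
                        seq_correlation = c(D = 0.956, beta = 0.732,
                                            mu = 0.640, adc = 0.983),
                        seed = 1L) {
  stopifnot(n_benign > 0, n_malignant > 0,
            all(c("parameter", "sequence", "benign_mean", "benign_sd",
                  "malignant_mean", "malignant_sd") %in% names(moments)),
            all(moments$benign_sd >= 0), all(moments$malignant_sd >= 0),
            all(seq_correlation >= -1 & seq_correlation <= 1))
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 moments = moments, seq_correlation = seq_correlation,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Bundled cohort moments table
#'
#' Reference per-group, per-sequence means and SDs of D (um^2/ms), beta,
#' mu (um) and ADC (um^2/ms) for benign and malignant breast lesions.
#'
#' @return data frame of moments.
#' @export
default_cohort_moments <- function() {
  utils::read.csv(system.file("extdata", "cohort_moments.csv",
                              package = "frocdwi", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

# parameter domains used to truncate cohort draws
.param_domain <- list(D = c(1e-6, Inf), beta = c(1e-6, 1),
                      mu = c(1e-6, Inf), adc = c(0, Inf))

# correlated truncated-normal pair: Gaussian copula correlation obtained
# from the Spearman correlation via 2*sin(pi*r/6); out-of-domain pairs are
# redrawn jointly so the within-domain moments stay close to the spec.
.draw_pair <- function(n, mean1, sd1, mean2, sd2, r_spearman, domain) {
  rho <- 2 * sin(pi * r_spearman / 6)
  out <- matrix(NA_real_, n, 2)
  todo <- seq_len(n)
  for (iter in 1:200) {
    m <- length(todo)
    if (m == 0L) break
    z1 <- stats::rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    x1 <- mean1 + sd1 * z1
    x2 <- mean2 + sd2 * z2
    ok <- x1 >= domain[1] & x1 <= domain[2] & x2 >= domain[1] & x2 <= domain[2]
    out[todo[ok], ] <- cbind(x1[ok], x2[ok])
    todo <- todo[!ok]
  }
  if (length(todo) > 0L) {  # pathological spec: clamp the stragglers
    out[todo, 1] <- pmin(pmax(mean1, domain[1]), domain[2])
    out[todo, 2] <- pmin(pmax(mean2, domain[1]), domain[2])
  }
  out
}

#' Simulate a two-group lesion cohort
#'
#' Draws per-lesion parameter values for both sequences from the spec's
#' truncated-normal marginals with copula-coupled sequences, and returns
#' the long-format lesion table consumed by the statistics stage.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional integer overriding `spec$seed`.
#' @return data frame with columns lesion_id, group, sequence, D, beta,
#'   mu, adc; class `lesion_cohort`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(if (is.null(seed)) spec$seed else seed)
  n <- c(benign = spec$n_benign, malignant = spec$n_malignant)
  seqs <- sort(unique(spec$moments$sequence))
  if (length(seqs) != 2L)
    stop("cohort moments must describe exactly two sequences")
  params <- unique(spec$moments$parameter)
  rows <- list()
  offset <- 0L
  for (grp in c("benign", "malignant")) {
    ng <- n[[grp]]
    vals <- list()  # per sequence: data.frame of parameters
    for (s in seqs) vals[[s]] <- data.frame(row.names = seq_len(ng))
    for (p in params) {
      m <- spec$moments[spec$moments$parameter == p, ]
      m1 <- m[m$sequence == seqs[1], ]
      m2 <- m[m$sequence == seqs[2], ]
      r <- if (p %in% names(spec$seq_correlation))
        spec$seq_correlation[[p]] else 0
      pair <- .draw_pair(ng,
                         m1[[paste0(grp, "_mean")]], m1[[paste0(grp, "_sd")]],
                         m2[[paste0(grp, "_mean")]], m2[[paste0(grp, "_sd")]],
                         r, .param_domain[[p]])
      vals[[seqs[1]]][[p]] <- pair[, 1]
      vals[[seqs[2]]][[p]] <- pair[, 2]
    }
    for (s in seqs) {
      df <- vals[[s]]
      df <- cbind(data.frame(lesion_id = offset + seq_len(ng),
                             group = grp, sequence = s,
                             stringsAsFactors = FALSE), df)
      rows[[paste(grp, s)]] <- df
    }
    offset <- offset + ng
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lesion_cohort", "data.frame")
  out
}

#' Read / write series, masks and cohorts
#'
#' A series is stored as a 4-D NIfTI volume plus a YAML protocol sidecar
#' (same basename, `.yaml` extension); masks as 3-D NIfTI; cohorts as CSV
#' with the schema (lesion_id, group, sequence, D, beta, mu, adc).
#'
#' @param series a [dwi_series()].
#' @param path output path (`.nii` / `.nii.gz` for images, `.csv` for
#'   cohorts).
#' @return the written path (writers, invisibly) or the reconstructed
#'   object (readers).
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dwi_series"))
  vox <- c(1, 1, 4)
  RNifti::writeNifti(RNifti::asNifti(series$data, pixdim = vox), path)
  write_protocol(series$protocol, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".yaml", path)

#' @rdname write_series
#' @export
read_series <- function(path) {
  data <- array(as.numeric(RNifti::readNifti(path)),
                dim = dim(RNifti::readNifti(path)))
  protocol <- read_protocol(sidecar_path(path))
  if (length(dim(data)) != 4L ||
      dim(data)[4L] != length(protocol$b_values))
    stop("volume count does not match the protocol sidecar's b-values")
  dwi_series(data, protocol)
}

#' @rdname write_series
#' @param mask logical or 0/1 3-D array.
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask))),
                     path)
  invisible(path)
}

#' @rdname write_series
#' @param grid_shape expected 3-D grid; a mismatch is a format error.
#' @export
read_mask <- function(path, grid_shape = NULL) {
  m <- RNifti::readNifti(path)
  m <- array(as.integer(m) != 0L, dim(m))
  if (!is.null(grid_shape) && !identical(dim(m), as.integer(grid_shape)))
    stop("mask grid does not match the expected shape")
  m
}

#' @rdname write_series
#' @param cohort a lesion cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lesion_id", "group", "sequence", "D", "beta", "mu", "adc")
  if (!all(need %in% names(out)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  class(out) <- c("lesion_cohort", "data.frame")
  out
}
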