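#' ROI sample for image-quality metrics
#'
#' Summary intensities of the three regions entering SNR and CNR: the
#' lesion ROI, a normal-tissue ROI and the signal-free air background.
#' SDs are sample SDs (n - 1 denominator).
#'
#' @param s_lesion,sigma_lesion mean and SD of the lesion ROI.
#' @param s_tissue,sigma_tissue mean and SD of the normal-tissue ROI.
#' @param sigma_background SD of the air background.
#' @return An object of class `roi_sample`.
#' @export
roi_sample <- function(s_lesion, sigma_lesion = 0, s_tissue = NA_real_,
                       sigma_tissue = 0, sigma_background = NA_real_) {
  if (any(c(sigma_lesion, sigma_tissue) < 0, na.rm = TRUE) ||
      (is.finite(sigma_background) && sigma_background < 0))
    stop("SDs must be >= 0")
  structure(list(s_lesion = s_lesion, sigma_lesion = sigma_lesion,
                 s_tissue = s_tissue, sigma_tissue = sigma_tissue,
                 sigma_background = sigma_background),
            class = "roi_sample")
}

#' Signal-to-noise ratio of a lesion ROI
#'
#' SNR = mean lesion intensity / SD of the air background.
#'
#' @param sample a [roi_sample()].
#' @return unitless SNR.
#' @export
snr <- function(sample) {
  stopifnot(inherits(sample, "roi_sample"))
  if (!is.finite(sample$sigma_background) || sample$sigma_background <= 0)
    stop("background SD must be > 0 for SNR")
  sample$s_lesion / sample$sigma_background
}

#' Contrast-to-noise ratio between lesion and tissue
#'
#' CNR = (lesion mean - tissue mean) / sqrt(lesion SD^2 + tissue SD^2).
#'
#' @param sample a [roi_sample()].
#' @return unitless CNR (sign flips if lesion and tissue are swapped).
#' @export
cnr <- function(sample) {
  stopifnot(inherits(sample, "roi_sample"))
  denom <- sqrt(sample$sigma_lesion^2 + sample$sigma_tissue^2)
  if (!is.finite(denom) || denom <= 0)
    stop("lesion and tissue SDs cannot both be zero for CNR")
  (sample$s_lesion - sample$s_tissue) / denom
}

#' Per-b-value SNR and CNR table of a series
#'
#' Measures the three ROIs on every b-value volume of a series and tabulates
#' SNR and CNR, mirroring the per-b image-quality tables of multi-b-value
#' protocols.
#'
#' @param series a [dwi_series()].
#' @param lesion_mask,tissue_mask,background_mask logical 3-D arrays.
#' @return data frame with columns b, snr, cnr and the ROI summaries.
#' @export
series_quality_table <- function(series, lesion_mask, tissue_mask,
                                 background_mask) {
  stopifnot(inherits(series, "dwi_series"))
  nb <- length(series$protocol$b_values)
  out <- vector("list", nb)
  for (j in seq_len(nb)) {
    vol <- series$data[, , , j]
    samp <- roi_sample(
      s_lesion = mean(vol[lesion_mask]),
      sigma_lesion = stats::sd(vol[lesion_mask]),
      s_tissue = mean(vol[tissue_mask]),
      sigma_tissue = stats::sd(vol[tissue_mask]),
      sigma_background = stats::sd(vol[background_mask]))
    out[[j]] <- data.frame(b = series$protocol$b_values[j],
                           snr = snr(samp), cnr = cnr(samp),
                           s_lesion = samp$s_lesion,
                           s_tissue = samp$s_tissue,
                           sigma_background = samp$sigma_background)
  }
  do.call(rbind, out)
}
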