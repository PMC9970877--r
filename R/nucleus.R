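#' Segment the mother-cell nucleus by local thresholding
#'
#' Detects the nucleus of a histone-reporter (e.g. Hta2-mRFP1) image
#' within the mother-cell mask. A pixel \eqn{i} is selected if
#' \eqn{F_i > \bar F_i(15 \times 15) + p30}, where
#' \eqn{\bar F_i(15\times15)} is the mean intensity of the surrounding
#' 15 x 15 neighborhood (nearest-border mode) and \eqn{p30} is the 30th
#' percentile of the mother-mask pixel intensities; the positive offset
#' discards cytoplasmic pixels that are only marginally brighter than
#' their neighbors. Selected objects smaller than 25 pixels under
#' orthogonal (4-)connectivity are removed; of the survivors, the object
#' containing the brightest pixel is kept as the nucleus, and unselected
#' pixels fully enclosed by it are added back. The reporter abundance is
#' the sum of member pixel intensities.
#'
#' Because the rule compares each pixel to its local mean plus a
#' percentile of the same image, adding a constant to the whole image
#' leaves the segmentation unchanged.
#'
#' @param image integer-valued intensity matrix.
#' @param mother_mask logical matrix of the same size; pixels outside the
#'   mother cell are ignored.
#' @param block_size local-mean neighborhood edge length (odd; default 15).
#' @param offset_quantile percentile of mask pixels used as offset
#'   (default 0.30).
#' @param min_pixels minimum object size kept (default 25).
#' @return A `cycleflux_nucleus` list: `mask` (logical matrix), `abundance`
#'   (sum of member intensities), `found` (logical). When no object
#'   survives, `found = FALSE` with an empty mask and zero abundance --
#'   a "no nucleus" signal, not an error.
#' @export
segment_nucleus <- function(image, mother_mask,
                            block_size = 15L, offset_quantile = 0.30,
                            min_pixels = 25L) {
  if (!all(dim(image) == dim(mother_mask)))
    cf_stop("image and mask dimensions differ")
  mother_mask <- mother_mask > 0
  if (!any(mother_mask)) cf_stop("mother mask is empty")
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  k <- matrix(1 / block_size^2, block_size, block_size)
  local_mean <- EBImage::imageData(EBImage::filter2(img, k,
                                                    boundary = "replicate"))
  p_off <- stats::quantile(img[mother_mask], offset_quantile, names = FALSE)
  sel <- (img > local_mean + p_off) & mother_mask
  none <- list(mask = matrix(FALSE, nrow(img), ncol(img)),
               abundance = 0, found = FALSE)
  class(none) <- "cycleflux_nucleus"
  if (!any(sel)) return(none)
  lab <- EBImage::imageData(EBImage::bwlabel(sel))  # orthogonal connectivity
  sizes <- tabulate(lab[lab > 0])
  keep_ids <- which(sizes >= min_pixels)
  if (length(keep_ids) == 0L) return(none)
  # object containing the brightest surviving pixel
  cand <- lab %in% keep_ids
  bright <- which(cand)[which.max(img[cand])]
  nuc_id <- lab[bright]
  mask <- matrix(lab == nuc_id, nrow(img), ncol(img))
  # add enclosed unselected pixels (dim single pixels inside the nucleus)
  mask <- matrix(EBImage::imageData(EBImage::fillHull(mask)) > 0,
                 nrow(img), ncol(img))
  out <- list(mask = mask, abundance = sum(img[mask]), found = TRUE)
  class(out) <- "cycleflux_nucleus"
  out
}

#' @export
print.cycleflux_nucleus <- function(x, ...) {
  if (x$found)
    cat("<nucleus> ", sum(x$mask), " px, abundance ", x$abundance, "\n",
        sep = "")
  else cat("<nucleus> none found\n")
  invisible(x)
}

#' Time of karyokinesis from mother-nucleus histone abundance
#'
#' Nuclear division is visible as a rapid decrease of the tagged-histone
#' abundance in the mother-cell nucleus as half the chromatin moves into
#' the bud. After smoothing, the most negative derivative of the abundance
#' series marks karyokinesis; ties are broken by the earliest time point.
#'
#' @param abundance nuclear reporter abundance series within one cycle.
#' @param time_min matching time grid (min).
#' @param smoothing_window Savitzky-Golay window (odd; default 7).
#' @return time (min) of the steepest drop, or `NA` when the abundance
#'   never decreases (no karyokinesis found).
#' @export
karyokinesis_time <- function(abundance, time_min,
                              smoothing_window = 7L) {
  sm <- savgol_smooth(abundance, window = smoothing_window)
  d <- trace_derivative(as.numeric(sm), time_min, method = "midpoint")
  if (all(d$value >= 0)) return(NA_real_)
  d$time[which.min(d$value)]
}
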