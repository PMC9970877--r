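#' Flat-field correction of uneven illumination
#'
#' Wide-field illumination is brighter at the image center than at the
#' corners, which confounds low-signal fluorescence readouts. The
#' correction learns the illumination shape from the per-pixel median over
#' a stack of frames from many stage positions (structures average out),
#' subtracts the fixed camera baseline, fits a 2-D Gaussian
#' \eqn{G(x, y) = A \exp(-(x-x_0)^2/(2\sigma_x^2) - (y-y_0)^2/(2\sigma_y^2)) + o}
#' to the median image, and rescales every baseline-subtracted frame by
#' \eqn{\max(G)/G}.
#'
#' If the Gaussian fit fails to converge the function falls back to
#' normalizing by the median image itself, with a warning.
#'
#' @param stack a 3-D array (rows x cols x frames) or a list of matrices.
#' @param target_frame the frame (matrix) to correct.
#' @param baseline camera baseline counts subtracted before fitting and
#'   from the target frame (default 500).
#' @return list with `corrected` (matrix), `field` (fitted illumination,
#'   max 1), `fit` (named parameter vector or `NULL` on fallback).
#' @export
flatfield_correct <- function(stack, target_frame, baseline = 500) {
  frames <- if (is.list(stack)) stack else
    lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  dims <- dim(frames[[1]])
  med <- apply(simplify2array(frames), c(1, 2), stats::median)
  med <- med - baseline
  nx <- dims[1]; ny <- dims[2]
  df <- data.frame(x = as.vector(row(med)), y = as.vector(col(med)),
                   z = as.vector(med))
  start <- list(A = max(df$z) - min(df$z), x0 = nx / 2, y0 = ny / 2,
                sx = nx, sy = ny, o = min(df$z))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ A * exp(-((x - x0)^2) / (2 * sx^2) - ((y - y0)^2) / (2 * sy^2)) + o,
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  target <- target_frame - baseline
  if (is.null(fit)) {
    warning("2-D Gaussian fit did not converge; ",
            "falling back to median-image normalization")
    field <- med / max(med)
    return(list(corrected = target / field, field = field, fit = NULL))
  }
  p <- stats::coef(fit)
  g <- p["A"] * exp(-((row(med) - p["x0"])^2) / (2 * p["sx"]^2) -
                      ((col(med) - p["y0"])^2) / (2 * p["sy"]^2)) + p["o"]
  field <- g / max(g)
  list(corrected = target * max(g) / g, field = field, fit = p)
}
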