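#' Prolate-spheroid volume and surface area of a segmented cell
#'
#' Bright-field segmentation of a yeast cell yields the major and minor
#' radii of a fitted ellipse; assuming the cell is a prolate spheroid with
#' those semi-axes, volume is \eqn{V = (4/3)\pi R r^2} (fl, with radii in
#' \eqn{\mu m}) and surface area is
#' \eqn{S = 2\pi r^2 (1 + (R/(r e)) \arcsin e)} with eccentricity
#' \eqn{e = \sqrt{1 - r^2/R^2}} (\eqn{\mu m^2}).
#'
#' At \eqn{R = r} the eccentricity vanishes and the analytic limit
#' \eqn{\arcsin(e)/e \to 1} gives the sphere surface \eqn{4\pi r^2}.
#' Ellipse fitters do not guarantee axis order, so inputs with \eqn{r > R}
#' are swapped with a warning.
#'
#' @param R major semi-axis (\eqn{\mu m}); vectorized.
#' @param r minor semi-axis (\eqn{\mu m}); vectorized, recycled with `R`.
#' @return A list with numeric vectors `volume` (fl) and `surface`
#'   (\eqn{\mu m^2}). `NA` inputs propagate to `NA` outputs.
#' @examples
#' spheroid_geometry(1, 1)  # sphere: V = 4*pi/3, S = 4*pi
#' spheroid_geometry(2, 1)
#' @export
spheroid_geometry <- function(R, r) {
  n <- max(length(R), length(r))
  R <- rep_len(as.numeric(R), n)
  r <- rep_len(as.numeric(r), n)
  ok <- !(is.na(R) | is.na(r))
  if (any(R[ok] <= 0 | r[ok] <= 0))
    cf_stop("radii must be positive")
  swap <- ok & r > R
  if (any(swap)) {
    warning("minor radius exceeds major radius for ", sum(swap),
            " point(s); axes swapped")
    tmp <- R[swap]; R[swap] <- r[swap]; r[swap] <- tmp
  }
  volume <- (4 / 3) * pi * R * r^2
  # arcsin(e)/e with series-free analytic limit 1 at e = 0
  e2 <- pmax(0, 1 - (r / R)^2)
  e <- sqrt(e2)
  ratio <- ifelse(e < 1e-8, 1, asin(e) / pmax(e, 1e-300))
  surface <- 2 * pi * r^2 * (1 + (R / r) * ratio)
  list(volume = volume, surface = surface)
}
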