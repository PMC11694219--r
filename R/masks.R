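#' Per-voxel density masks on rho
#'
#' Classifies every voxel of a rho synthesis into three classes controlled by
#' the threshold `t * sigma_rho`, where `sigma_rho` is ALWAYS the
#' phase-independent Parseval value over the full reflection set (also when
#' rho itself was synthesized from the strong subset):
#'
#' * `rho > 0` (COREs and slightly positive zones): `m = 1`, `s = 1`;
#' * `0 >= rho > -t sigma` (slightly negative zones, the "zero conversion"
#'   class, about half the cell at random phases): `m = 0`, `s = -1`;
#' * `rho <= -t sigma` (very negative values, well under 1 percent for
#'   `t ~ 2.5`): `m = 1`, `s = -1`.
#'
#' The combined mask `m * s` in `{-1, 0, 1}` multiplies delta_M to give the
#' modified density rho' entering the SMAR phasing formula.  Boundary ties:
#' `rho = 0` is slightly negative, `rho = -t sigma` is very negative.
#'
#' @param rho A `"density_map"`.
#' @param sigma All-reflection Parseval sigma of rho (see [map_sigma()]).
#' @param t Threshold multiplier (default 2.5; values in 2.0-2.5 phase best,
#'   `t >= 10` zeroes effectively all negative density).
#' @return Object of class `"mask_set"`: arrays `m` (0/1), `s` (+-1),
#'   `combined` (= m*s), scalar `t`, and `fractions`, the percentages of the
#'   positive / slightly-negative / very-negative classes.
#' @export
compute_masks <- function(rho, sigma, t = 2.5) {
  if (t <= 0) stop("t must be positive")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  v <- rho$values
  pos <- v > 0
  very <- v <= -t * sigma
  m <- ifelse(pos | very, 1, 0)
  s <- ifelse(pos, 1, -1)
  fr <- 100 * c(positive = mean(pos),
                slightly_negative = mean(!pos & !very),
                very_negative = mean(very))
  structure(list(m = m, s = s, combined = m * s, t = t, fractions = fr),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("Mask set (t = %.2f): +1 %.2f%%  0 %.2f%%  -1 %.2f%%\n",
              x$t, x$fractions[1], x$fractions[2], x$fractions[3]))
  invisible(x)
}

#' Binary mask on delta_M for the tangent formula
#'
#' `m = 1` where `delta_M >= t1 * sigma(delta_M)` (sigma from the grid),
#' else 0.  With `t1 ~ 2.5` the mask isolates the strong atomic (type A)
#' peaks of delta_M from the sea of weak cross-vector (type B) peaks, so the
#' masked product `delta_M * m` is proportional to rho for equal-atom
#' structures.
#'
#' @param delta A `"density_map"` holding delta_M.
#' @param t1 Threshold multiplier (default 2.5).
#' @return Binary (0/1) array with the dimensions of the map.
#' @export
compute_m_delta <- function(delta, t1 = 2.5) {
  if (stats::sd(as.vector(delta$values)) == 0)
    stop("constant map: threshold undefined")
  sg <- map_sigma(delta)
  (delta$values >= t1 * sg) * 1
}
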