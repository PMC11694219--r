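#' Triclinic unit cell
#'
#' Constructs a unit-cell object holding the direct and reciprocal metric
#' tensors, the orthogonalization matrix and the cell volume.  All phasing in
#' this package is carried out in P1, so the cell is the only piece of
#' symmetry information required.
#'
#' @param a,b,c Cell edge lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `"unit_cell"`: a list with elements `a`, `b`,
#'   `c`, `alpha`, `beta`, `gamma`, `volume` (Angstrom^3), `metric` (direct
#'   metric tensor G), `metric_star` (reciprocal metric tensor G*), and
#'   `ortho` (fractional-to-Cartesian matrix).
#' @examples
#' cl <- unit_cell(10, 12, 14, 90, 95, 90)
#' cl$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("cell angles do not define a valid triclinic cell")
  vol <- a * b * c * sqrt(disc)
  # direct metric tensor G_ij = a_i . a_j
  G <- matrix(c(a * a,       a * b * cg,  a * c * cb,
                a * b * cg,  b * b,       b * c * ca,
                a * c * cb,  b * c * ca,  c * c), 3, 3)
  # fractional -> Cartesian (standard PDB orthogonalization)
  M <- matrix(c(a, 0, 0,
                b * cg, b * sg, 0,
                c * cb, c * (ca - cb * cg) / sg, vol / (a * b * sg)),
              3, 3)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 volume = vol, metric = G, metric_star = solve(G),
                 ortho = M),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell (P1): a=%.4f b=%.4f c=%.4f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

cell_lengths <- function(cell) c(cell$a, cell$b, cell$c)

#' d-spacings of Miller indices
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer matrix with one Miller triple per row.
#' @return Numeric vector of d-spacings in Angstrom (`1/d^2 = h' G* h`).
#' @export
d_spacing <- function(cell, hkl) {
  hkl <- rbind(hkl)
  q <- rowSums((hkl %*% cell$metric_star) * hkl)
  1 / sqrt(q)
}

# minimum-image Cartesian distances between one fractional point and a matrix
# of fractional points; exact for any cell by scanning the 27 neighbor images
periodic_distances <- function(cell, x, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  d <- pts - matrix(x, nrow(pts), 3, byrow = TRUE)
  d <- d - round(d)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  best <- rep(Inf, nrow(d))
  for (i in seq_len(nrow(shifts))) {
    cart <- (d + matrix(shifts[i, ], nrow(d), 3, byrow = TRUE)) %*% t(cell$ortho)
    best <- pmin(best, sqrt(rowSums(cart^2)))
  }
  best
}
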