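#' @title Density map over the periodic unit-cell grid
#' @description Real 3D array sampled at voxel centers `(i/Nx, j/Ny, k/Nz)`
#'   with the generating cell attached.  All syntheses exclude the (0,0,0)
#'   term, so maps are mean-zero by construction.
#' @param values Real 3D array.
#' @param cell A [unit_cell()].
#' @param delta_grid Nominal voxel edge in Angstrom (bookkeeping only).
#' @return Object of class `"density_map"`.
#' @export
density_map <- function(values, cell, delta_grid = NA_real_) {
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  structure(list(values = values, dims = dim(values), cell = cell,
                 delta_grid = delta_grid),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("Density map %d x %d x %d (V = %.2f A^3), sigma = %.4g\n",
              x$dims[1], x$dims[2], x$dims[3], x$cell$volume,
              stats::sd(as.vector(x$values))))
  invisible(x)
}

# smallest 2,3,5-smooth integer >= n (FFT-friendly grid sizes)
next_smooth <- function(n) {
  n <- as.integer(ceiling(n))
  is_smooth <- function(m) {
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    m == 1L
  }
  while (!is_smooth(n)) n <- n + 1L
  n
}

#' FFT grid dimensions for a reflection set
#'
#' Per axis, the smallest 2,3,5-smooth integer at least
#' `max(cell_edge / delta_grid, 2 h_max + 2)`.  The default voxel edge
#' `d_min / 3` gives the ~0.33 Angstrom spacing at atomic resolution that the
#' inner-pixel-preservation step presumes; the `2 h_max + 2` floor guarantees
#' Nyquist-sufficient sampling with no Friedel-index collisions.
#'
#' @param refl A `"reflection_set"`.
#' @param delta_grid Target voxel edge in Angstrom (default `d_min / 3`).
#' @return Integer vector of three grid dimensions.
#' @export
grid_dims <- function(refl, delta_grid = refl$d_min / 3) {
  hmax <- apply(abs(refl$hkl), 2, max)
  lens <- cell_lengths(refl$cell)
  vapply(1:3, function(i)
    next_smooth(max(ceiling(lens[i] / delta_grid), 2L * hmax[i] + 2L)),
    integer(1))
}

# linear 1-based indices of Miller triples (or their negatives) on the grid
grid_index <- function(hkl, dims, negate = FALSE) {
  if (negate) hkl <- -hkl
  i1 <- hkl[, 1] %% dims[1]
  i2 <- hkl[, 2] %% dims[2]
  i3 <- hkl[, 3] %% dims[3]
  1 + i1 + dims[1] * (i2 + dims[2] * i3)
}

# place half-set complex coefficients and their Friedel conjugates on the grid
coefficient_grid <- function(hkl, coef, dims) {
  A <- array(0i, dims)
  A[grid_index(hkl, dims)] <- coef
  A[grid_index(hkl, dims, negate = TRUE)] <- Conj(coef)
  A
}

#' Electron-density Fourier synthesis
#'
#' Evaluates `rho(r) = (1/V) sum_{+-h} |E_h| cos(2 pi h.r - phi_h)` on the
#' grid by FFT with Friedel completion.  In fast convergence mode only the
#' strong (`|E| >= e_lim`) terms are included; the slow mode and all delta
#' syntheses use every reflection.
#'
#' @param refl A `"reflection_set"` with phases.
#' @param phi Optional phase vector overriding `refl$phi`.
#' @param subset `"all"` or `"strong"`.
#' @param dims Grid dimensions, default [grid_dims()].
#' @param delta_grid Voxel edge used when `dims` is derived.
#' @return A `"density_map"`.
#' @export
synthesize_rho <- function(refl, phi = refl$phi, subset = c("all", "strong"),
                           dims = grid_dims(refl, delta_grid),
                           delta_grid = refl$d_min / 3) {
  subset <- match.arg(subset)
  if (is.null(phi)) stop("phases required for a rho synthesis")
  if (length(phi) != nrow(refl$hkl)) stop("phi length mismatch")
  keep <- if (subset == "strong") refl$strong else rep(TRUE, nrow(refl$hkl))
  if (!any(keep)) stop("no strong reflections in the working set")
  A <- coefficient_grid(refl$hkl[keep, , drop = FALSE],
                        refl$E[keep] * exp(1i * phi[keep]), dims)
  density_map(Re(stats::fft(A)) / refl$cell$volume, refl$cell, delta_grid)
}

#' Scale constant of the delta_M synthesis
#'
#' `c = sum |E|^2 / sum (|E| - <|E|>)^2` over the full working set.  This
#' choice unit-scales the rho component of delta_M (the projection of the
#' `c (|E| - <|E|>)` coefficients onto `|E|` is exactly 1) and makes the
#' SDEL diagnostic equal c identically.  Every phase update and every ratio
#' diagnostic is invariant under rescaling of c.
#'
#' @param refl A `"reflection_set"`.
#' @return Positive scalar c.
#' @export
compute_c <- function(refl) {
  if (nrow(refl$hkl) < 2) stop("need at least 2 reflections")
  den <- sum((refl$E - refl$e_mean)^2)
  if (den == 0) stop("all |E| equal: c undefined")
  sum(refl$E^2) / den
}

#' delta_M Fourier synthesis
#'
#' `delta_M(r) = (c/V) sum_{+-h} (|E_h| - <|E|>) cos(2 pi h.r - alpha_h)`,
#' always over the full reflection set.  With phases alpha taken from the
#' transform of `|rho|`, delta_M decomposes into the atomic peaks of rho
#' (type A) plus a sea of `N(N-1)^2` weak positive peaks at the cross
#' vectors `r_j + r_l - r_m` (type B), each about `1/(N-1)` of an atom peak.
#'
#' @param refl A `"reflection_set"`.
#' @param alpha Phases (radians) for every half-set reflection.
#' @param c_scale Scale constant, default [compute_c()].
#' @param dims Grid dimensions.
#' @param delta_grid Voxel edge used when `dims` is derived.
#' @return A `"density_map"`.
#' @export
synthesize_delta_m <- function(refl, alpha, c_scale = compute_c(refl),
                               dims = grid_dims(refl, delta_grid),
                               delta_grid = refl$d_min / 3) {
  if (is.null(alpha) || length(alpha) != nrow(refl$hkl))
    stop("alpha must be given for every reflection")
  A <- coefficient_grid(refl$hkl,
                        c_scale * (refl$E - refl$e_mean) * exp(1i * alpha),
                        dims)
  density_map(Re(stats::fft(A)) / refl$cell$volume, refl$cell, delta_grid)
}

#' Forward Fourier transform of a map at the Miller indices
#'
#' Discrete transform `F(h) = (V/N_vox) sum_voxels map(r) exp(+2 pi i h.r)`
#' sampled at every reflection of `refl`.  Masked (non-band-limited) maps are
#' transformed as-is on the fixed grid; aliasing is part of the method's
#' contract.  A round trip with [synthesize_rho()] is the identity on
#' band-limited data.
#'
#' @param map A `"density_map"`.
#' @param refl A `"reflection_set"` (indices must be inside the Nyquist
#'   range of the grid).
#' @return List with `modulus` and `phase` vectors over the half-set.
#' @export
forward_transform <- function(map, refl) {
  hmax <- apply(abs(refl$hkl), 2, max)
  if (any(2L * hmax + 1L > map$dims))
    stop("Miller index outside the Nyquist range of the grid")
  C <- stats::fft(map$values, inverse = TRUE) * map$cell$volume / prod(map$dims)
  Fh <- C[grid_index(refl$hkl, map$dims)]
  list(modulus = Mod(Fh), phase = Arg(Fh))
}

#' Map standard deviation
#'
#' For an unmasked rho synthesis the variance is phase independent and is
#' computed from the amplitudes alone via Parseval's theorem over the FULL
#' reflection set (also in fast mode, where rho itself uses only the strong
#' terms); for delta_M and for masked maps the grid standard deviation is
#' used.
#'
#' @param x A `"density_map"` (grid route) or `"reflection_set"` (Parseval
#'   route).
#' @param subset For the Parseval route, which reflections to sum over.
#' @return Nonnegative scalar sigma.
#' @export
map_sigma <- function(x, subset = c("all", "strong")) {
  if (inherits(x, "reflection_set")) {
    subset <- match.arg(subset)
    keep <- if (subset == "strong") x$strong else rep(TRUE, nrow(x$hkl))
    sqrt(2 * sum(x$E[keep]^2)) / x$cell$volume
  } else {
    sqrt(mean(x$values^2))
  }
}

#' CORE radius of a series-terminated point-atom peak
#'
#' The positive central part of a point-atom peak in a synthesis truncated at
#' `d_min` ends at the first zero of the spherical termination kernel
#' `T3(u) propto (sin u - u cos u)/u^3`; the first positive root
#' `u* ~ 4.4934` gives a radius `u*/(2 pi) d_min ~ 0.72 d_min`.
#'
#' @param d_min Resolution limit in Angstrom.
#' @return CORE radius in Angstrom.
#' @export
core_radius <- function(d_min) {
  if (d_min <= 0) stop("d_min must be positive")
  u_star() / (2 * pi) * d_min
}

# first positive root of sin(u) - u cos(u) = 0 by scan + bracketed search
u_star <- function() {
  f <- function(u) sin(u) - u * cos(u)
  u <- seq(0.5, 10, by = 0.1)
  s <- f(u)
  i <- which(s[-1] * s[-length(s)] < 0)[1]
  stats::uniroot(f, c(u[i], u[i + 1]), tol = 1e-12)$root
}
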