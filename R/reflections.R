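#' Reflection set container
#'
#' Reciprocal-space state of a phasing run: the unique half-set of Miller
#' indices to a resolution limit, their (normalized) amplitudes and,
#' optionally, phases.  Friedel mates are implied: `|E(-h)| = |E(h)|` and
#' `phi(-h) = -phi(h)` (all maps are real).  The (0,0,0) term is always
#' excluded, so every synthesized map has zero mean.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer matrix of Miller triples (unique half-set).
#' @param E Nonnegative amplitudes.
#' @param phi Phases in radians, or `NULL` when unphased.
#' @param d_min Resolution limit in Angstrom.
#' @param e_lim Strong-reflection threshold on `|E|` (default 1.0).
#' @return Object of class `"reflection_set"`: list with `cell`, `hkl`, `E`,
#'   `phi`, `d`, `d_min`, `e_mean` (mean `|E|` over the full sphere),
#'   `e_lim`, `strong` (logical, `|E| >= e_lim`).
#' @export
reflection_set <- function(cell, hkl, E, phi = NULL, d_min, e_lim = 1.0) {
  hkl <- rbind(hkl)
  storage.mode(hkl) <- "integer"
  if (nrow(hkl) == 0L) stop("empty reflection set")
  if (any(rowSums(abs(hkl)) == 0L)) stop("(0,0,0) is not a valid reflection")
  if (length(E) != nrow(hkl)) stop("E length mismatch")
  if (!is.null(phi) && length(phi) != nrow(hkl)) stop("phi length mismatch")
  structure(list(cell = cell, hkl = unname(hkl), E = as.numeric(E),
                 phi = if (is.null(phi)) NULL else as.numeric(phi),
                 d = d_spacing(cell, hkl), d_min = d_min,
                 e_mean = mean(E), e_lim = e_lim,
                 strong = E >= e_lim),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("Reflection set: %d unique reflections to d_min = %.3f A\n",
              nrow(x$hkl), x$d_min))
  cat(sprintf("  <|E|> = %.4f  <|E|^2> = %.4f  strong (|E| >= %.2f): %d\n",
              x$e_mean, mean(x$E^2), x$e_lim, sum(x$strong)))
  if (!is.null(x$phi)) cat("  phases present\n")
  invisible(x)
}

# enumerate the unique half-set of Miller indices with d >= d_min;
# half-set convention: h > 0, or h = 0 & k > 0, or h = k = 0 & l > 0
hkl_sphere <- function(cell, d_min) {
  lim <- ceiling(cell_lengths(cell) / d_min) + 1L
  g <- expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2], l = 0:lim[3])
  hkl <- as.matrix(g)
  keep <- hkl[, 3] > 0 |
    (hkl[, 3] == 0 & (hkl[, 1] > 0 | (hkl[, 1] == 0 & hkl[, 2] > 0)))
  hkl <- hkl[keep, , drop = FALSE]
  d <- d_spacing(cell, hkl)
  hkl <- hkl[d >= d_min, , drop = FALSE]
  if (nrow(hkl) == 0L)
    stop("no reflections: d_min exceeds every lattice spacing")
  hkl[order(-d_spacing(cell, hkl)), , drop = FALSE]
}

#' Exact structure factors by direct summation
#'
#' Evaluates `F(h) = sum_j f_j exp(2 pi i h.r_j)` over all atoms for every
#' unique reflection with `d >= d_min`.  For the default point atoms
#' (`f_j = 1`, no thermal motion) this is the exact transform of the model
#' and serves as the oracle for every FFT-based synthesis in the package.
#'
#' @param st A `"crystal_structure"`.
#' @param d_min Resolution limit in Angstrom.
#' @param b_iso Optional isotropic Debye-Waller parameter (Angstrom^2); the
#'   default 0 keeps atoms point-like.  A positive value produces
#'   Gaussian-broadened amplitudes for map-visualisation realism only.
#' @return A `"reflection_set"` with unnormalized amplitudes `E = |F|` and
#'   phases `phi = arg F`.
#' @export
structure_factors <- function(st, d_min, b_iso = 0) {
  if (st$n_atoms < 1) stop("empty structure")
  hkl <- hkl_sphere(st$cell, d_min)
  ph <- 2 * pi * (hkl %*% t(st$xyz))          # nrefl x natoms
  Fc <- rowSums(exp(1i * ph))
  if (b_iso > 0) {
    s2 <- 1 / d_spacing(st$cell, hkl)^2       # (2 sin(theta)/lambda)^2 = 1/d^2
    Fc <- Fc * exp(-b_iso * s2 / 4)
  }
  reflection_set(st$cell, hkl, Mod(Fc), Arg(Fc), d_min = d_min)
}

#' Normalize point-atom amplitudes to E-values
#'
#' For an equal-atom point structure the normalized structure factor is
#' `|E| = |F| / sqrt(N)`, which makes `<|E|^2>` equal 1 up to sampling error
#' (Wilson statistics).  Phases are unchanged.
#'
#' @param refl A `"reflection_set"` with raw amplitudes.
#' @param n_atoms Atom count N used for the normalization.
#' @param e_lim Strong-reflection threshold (default 1.0).
#' @return A `"reflection_set"` with `E` on the normalized scale.
#' @export
normalize_to_E <- function(refl, n_atoms, e_lim = 1.0) {
  if (n_atoms < 1) stop("n_atoms must be >= 1")
  if (any(!is.finite(refl$E))) stop("non-finite amplitudes")
  reflection_set(refl$cell, refl$hkl, refl$E / sqrt(n_atoms), refl$phi,
                 d_min = refl$d_min, e_lim = e_lim)
}

#' Exact normalized data for a synthetic structure
#'
#' Convenience wrapper: direct-summation structure factors followed by
#' equal-atom normalization.  The returned phases are the true phases of the
#' generating structure.
#'
#' @inheritParams structure_factors
#' @inheritParams normalize_to_E
#' @return A normalized `"reflection_set"` carrying true phases.
#' @export
true_data <- function(st, d_min, e_lim = 1.0) {
  normalize_to_E(structure_factors(st, d_min), st$n_atoms, e_lim = e_lim)
}

# replace the phase set (half-set convention), keeping everything else
set_phases <- function(refl, phi) {
  refl$phi <- as.numeric(phi)
  refl
}

#' Random uniform phases
#'
#' Assigns an independent uniform phase on `[0, 2 pi)` to every half-set
#' reflection (the implied Friedel mate takes the negated phase, keeping
#' density maps real).
#'
#' @param refl A `"reflection_set"`.
#' @param seed Optional integer seed.
#' @return The reflection set with random `phi`.
#' @export
random_phases <- function(refl, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  set_phases(refl, stats::runif(nrow(refl$hkl), 0, 2 * pi))
}
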