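#' Random equal-atom P1 crystal structure
#'
#' Places `n_atoms` point atoms uniformly in the unit cell by rejection
#' sampling, enforcing a minimum periodic inter-atomic distance.  The result
#' emulates the equal-atom structures used to validate dual-space phasing:
#' no symmetry, no thermal motion, unit scattering power per atom.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param cell A [unit_cell()].
#' @param min_dist Minimum allowed periodic inter-atom distance in Angstrom.
#' @param seed Integer seed; the placement is deterministic for a fixed seed.
#' @param label Optional text label.
#' @param max_attempts Rejection attempts allowed per atom before the
#'   placement is declared infeasible.
#' @return An object of class `"crystal_structure"`: list with `cell`, `xyz`
#'   (n x 3 matrix of fractional coordinates in `[0,1)`), `n_atoms`, `label`.
#' @examples
#' cl <- unit_cell(9, 9.5, 10)
#' st <- random_structure(20, cl, min_dist = 1.2, seed = 7)
#' @export
random_structure <- function(n_atoms, cell, min_dist = 1.2, seed = NULL,
                             label = "synthetic", max_attempts = 5000L) {
  if (n_atoms < 1) stop("n_atoms must be >= 1")
  if (min_dist < 0) stop("min_dist must be >= 0")
  if (n_atoms > 1 && n_atoms * (4 / 3) * pi * min_dist^3 > 0.5 * cell$volume)
    stop("packing infeasible: n_atoms * sphere(min_dist) exceeds half the cell volume")
  if (!is.null(seed)) set.seed(seed)
  xyz <- matrix(NA_real_, n_atoms, 3)
  placed <- 0L
  while (placed < n_atoms) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      cand <- stats::runif(3)
      if (placed == 0L ||
          min(periodic_distances(cell, cand, xyz[seq_len(placed), , drop = FALSE])) >= min_dist) {
        placed <- placed + 1L
        xyz[placed, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("packing infeasible: could not place atom ", placed + 1L,
                  " after ", max_attempts, " attempts")
  }
  crystal_structure(cell, xyz %% 1, label = label)
}

#' Crystal structure from explicit coordinates
#'
#' @param cell A [unit_cell()].
#' @param xyz n x 3 matrix of fractional coordinates (wrapped to `[0,1)`).
#' @param label Text label.
#' @return A `"crystal_structure"` object.
#' @export
crystal_structure <- function(cell, xyz, label = "structure") {
  xyz <- rbind(xyz) %% 1
  if (ncol(xyz) != 3) stop("xyz must have three columns")
  structure(list(cell = cell, xyz = unname(xyz), n_atoms = nrow(xyz),
                 label = label),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("Crystal structure '%s': %d equal atoms in P1\n", x$label, x$n_atoms))
  print(x$cell)
  invisible(x)
}

#' Apply symmetry mates to a structure
#'
#' Expands an asymmetric set of atoms by a list of affine symmetry operations
#' (rotation matrix + translation, fractional), keeping the result as an
#' explicit P1 structure.  Phasing itself never uses symmetry; this exists so
#' that synthetic test structures can mimic, e.g., 2(1)2(1)2(1) packings.
#'
#' @param st A `"crystal_structure"`.
#' @param ops List of lists with elements `R` (3x3 integer matrix) and `t`
#'   (length-3 fractional translation).
#' @return A `"crystal_structure"` with the expanded atom list.
#' @export
expand_symmetry <- function(st, ops) {
  out <- do.call(rbind, lapply(ops, function(op) {
    (st$xyz %*% t(op$R) + matrix(op$t, st$n_atoms, 3, byrow = TRUE)) %% 1
  }))
  crystal_structure(st$cell, out, label = paste0(st$label, "_expanded"))
}

#' Write / read a structure as plain text
#'
#' Minimal fixture format: line 1 holds the six cell parameters, line 2 the
#' atom count, then one `x y z` fractional triple per line.
#'
#' @param st A `"crystal_structure"`.
#' @param path File path.
#' @return `read_structure` returns a `"crystal_structure"`.
#' @export
write_structure <- function(st, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%.6f %.6f %.6f %.4f %.4f %.4f",
                     st$cell$a, st$cell$b, st$cell$c,
                     st$cell$alpha, st$cell$beta, st$cell$gamma), con)
  writeLines(sprintf("%d", st$n_atoms), con)
  writeLines(sprintf("%.8f %.8f %.8f", st$xyz[, 1], st$xyz[, 2], st$xyz[, 3]), con)
  invisible(path)
}

#' @rdname write_structure
#' @param label Label for the structure read back.
#' @export
read_structure <- function(path, label = basename(path)) {
  ln <- readLines(path)
  cp <- scan(text = ln[1], quiet = TRUE)
  n <- as.integer(ln[2])
  xyz <- matrix(scan(text = paste(ln[3:(2 + n)], collapse = "\n"), quiet = TRUE),
                ncol = 3, byrow = TRUE)
  crystal_structure(unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6]),
                    xyz, label = label)
}
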