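#' Read a reflection file
#'
#' Accepts free-format text (`h k l amplitude [sigma]`, whitespace
#' separated) or SHELX HKLF-4 fixed-width records (3I4, 2F8.2; an all-zero
#' terminator record is honored).  Friedel mates are folded onto the unique
#' half-set; duplicate indices are merged by averaging their amplitudes with
#' a warning.  Amplitudes are taken as `|E|` unless `from_f` is set, in
#' which case they are normalized with [normalize_to_E()].
#'
#' @param path File path.
#' @param cell A [unit_cell()] (needed for d-spacings).
#' @param format `"auto"`, `"free"` or `"shelx"`.
#' @param d_min Optional resolution cutoff; reflections beyond it are
#'   dropped.  Default: the smallest d present.
#' @param from_f Interpret amplitudes as raw `|F|` and normalize.
#' @param n_atoms Atom count for `from_f` normalization.
#' @param e_lim Strong-reflection threshold.
#' @return A `"reflection_set"` (unphased).
#' @export
read_reflections <- function(path, cell, format = c("auto", "free", "shelx"),
                             d_min = NULL, from_f = FALSE, n_atoms = NULL,
                             e_lim = 1.0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) == 0) stop("empty reflection file: ", path)
  if (format == "auto") {
    # SHELX records are exactly fixed width with no separators guaranteed;
    # free format always tokenizes into >= 4 fields
    toks <- strsplit(trimws(ln[1]), "\\s+")[[1]]
    format <- if (length(toks) >= 4 &&
                  !anyNA(suppressWarnings(as.numeric(toks)))) "free" else "shelx"
  }
  if (format == "free") {
    rows <- lapply(seq_along(ln), function(i) {
      toks <- strsplit(trimws(ln[i]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      if (length(vals) < 4 || anyNA(vals[1:4]))
        stop("malformed reflection record at line ", i, ": '", ln[i], "'")
      vals[1:4]
    })
    tab <- do.call(rbind, rows)
  } else {
    rows <- lapply(seq_along(ln), function(i) {
      s <- ln[i]
      if (nchar(s) < 20) s <- formatC(s, width = 28, flag = "-")
      vals <- suppressWarnings(as.numeric(c(substr(s, 1, 4), substr(s, 5, 8),
                                            substr(s, 9, 12), substr(s, 13, 20))))
      if (anyNA(vals))
        stop("malformed reflection record at line ", i, ": '", ln[i], "'")
      vals
    })
    tab <- do.call(rbind, rows)
  }
  zero <- rowSums(abs(tab[, 1:3, drop = FALSE])) == 0
  if (any(zero)) tab <- tab[seq_len(which(zero)[1] - 1), , drop = FALSE]
  if (nrow(tab) == 0) stop("no reflections in ", path)
  hkl <- round(tab[, 1:3, drop = FALSE])
  amp <- tab[, 4]
  # fold Friedel mates onto the half-set convention
  neg <- !(hkl[, 3] > 0 |
           (hkl[, 3] == 0 & (hkl[, 1] > 0 | (hkl[, 1] == 0 & hkl[, 2] > 0))))
  hkl[neg, ] <- -hkl[neg, , drop = FALSE]
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) {
    warning("duplicate reflections merged by averaging")
    amp <- tapply(amp, key, mean)[unique(key)]
    hkl <- hkl[!duplicated(key), , drop = FALSE]
  }
  d <- d_spacing(cell, hkl)
  if (is.null(d_min)) d_min <- min(d)
  keep <- d >= d_min
  refl <- reflection_set(cell, hkl[keep, , drop = FALSE], amp[keep],
                         d_min = d_min, e_lim = e_lim)
  if (from_f) {
    if (is.null(n_atoms)) stop("from_f normalization needs n_atoms")
    refl <- normalize_to_E(refl, n_atoms, e_lim = e_lim)
  }
  refl
}

#' Write a free-format reflection file
#'
#' `h k l amplitude` records readable by [read_reflections()].
#'
#' @param refl A `"reflection_set"`.
#' @param path Output path.
#' @export
write_reflections <- function(refl, path) {
  writeLines(sprintf("%4d %4d %4d %12.6f",
                     refl$hkl[, 1], refl$hkl[, 2], refl$hkl[, 3], refl$E),
             path)
  invisible(path)
}

#' Write / read a phase table
#'
#' Text table `h k l |E| phi_deg` with phases wrapped to `[0, 360)` and two
#' decimals; a reread recovers phases to the quantization (0.005 degrees).
#'
#' @param refl A `"reflection_set"` with phases.
#' @param path File path.
#' @export
write_phases <- function(refl, path) {
  if (is.null(refl$phi)) stop("no phases to write")
  deg <- (refl$phi * 180 / pi) %% 360
  writeLines(c("   h   k   l       |E|  phi_deg",
               sprintf("%4d%4d%4d%10.4f%9.2f",
                       refl$hkl[, 1], refl$hkl[, 2], refl$hkl[, 3],
                       refl$E, deg)),
             path)
  invisible(path)
}

#' @rdname write_phases
#' @param cell A [unit_cell()] for the set read back.
#' @param d_min Resolution limit recorded in the set read back.
#' @param e_lim Strong-reflection threshold.
#' @export
read_phases <- function(path, cell, d_min = NULL, e_lim = 1.0) {
  tab <- utils::read.table(path, skip = 1,
                           col.names = c("h", "k", "l", "E", "phi_deg"))
  if (nrow(tab) == 0) stop("empty phase file: ", path)
  hkl <- as.matrix(tab[, 1:3])
  if (is.null(d_min)) d_min <- min(d_spacing(cell, hkl))
  reflection_set(cell, hkl, tab$E, tab$phi_deg * pi / 180,
                 d_min = d_min, e_lim = e_lim)
}

#' Write a density map in XPLOR/CNS ASCII format
#'
#' Whole-cell map (`AMIN = 0, AMAX = N-1` on each axis), ZYX section order,
#' 6E12.5 values per line, terminated by the conventional `-9999` record and
#' an average/sigma line.
#'
#' @param map A `"density_map"`.
#' @param path Output path.
#' @param title Title remark.
#' @export
write_map <- function(map, path, title = "smarphase map") {
  d <- map$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("", con)
  writeLines(c(sprintf("%8d !NTITLE", 1L),
               sprintf(" REMARKS %s", title)), con)
  writeLines(sprintf("%8d%8d%8d%8d%8d%8d%8d%8d%8d",
                     d[1], 0L, d[1] - 1L, d[2], 0L, d[2] - 1L,
                     d[3], 0L, d[3] - 1L), con)
  writeLines(sprintf("%12.5E%12.5E%12.5E%12.5E%12.5E%12.5E",
                     map$cell$a, map$cell$b, map$cell$c,
                     map$cell$alpha, map$cell$beta, map$cell$gamma), con)
  writeLines("ZYX", con)
  for (k in seq_len(d[3])) {
    writeLines(sprintf("%8d", k - 1L), con)
    sec <- as.vector(map$values[, , k])  # x fastest, then y (ZYX order)
    full <- length(sec) %/% 6
    lines <- character(0)
    if (full > 0)
      lines <- apply(matrix(sprintf("%12.5E", sec[seq_len(full * 6)]),
                            ncol = 6, byrow = TRUE), 1, paste0, collapse = "")
    rest <- sec[-seq_len(full * 6)]
    if (length(rest))
      lines <- c(lines, paste0(sprintf("%12.5E", rest), collapse = ""))
    writeLines(lines, con)
  }
  writeLines(sprintf("%8d", -9999L), con)
  writeLines(sprintf("%12.4E%12.4E", mean(map$values),
                     stats::sd(as.vector(map$values))), con)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  ln <- readLines(path)
  i <- 1
  while (!grepl("!NTITLE", ln[i])) i <- i + 1
  ntitle <- as.integer(substr(ln[i], 1, 8))
  i <- i + ntitle + 1
  g <- as.integer(substring(ln[i], seq(1, 72 - 7, by = 8), seq(8, 72, by = 8)))
  d <- g[c(1, 4, 7)]
  i <- i + 1
  cp <- as.numeric(substring(ln[i], seq(1, 72 - 11, by = 12), seq(12, 72, by = 12)))
  i <- i + 1  # now at the ZYX record
  vals <- array(0, d)
  for (k in seq_len(d[3])) {
    i <- i + 1  # section index line
    n <- d[1] * d[2]
    nlines <- ceiling(n / 6)
    sec <- unlist(lapply(ln[i + seq_len(nlines)], function(s)
      as.numeric(substring(s, seq(1, nchar(s) - 11, by = 12),
                           seq(12, nchar(s), by = 12)))))
    vals[, , k] <- matrix(sec, d[1], d[2])
    i <- i + nlines
  }
  density_map(vals, unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6]))
}

#' Per-iteration diagnostics as CSV
#'
#' Writes the diagnostics history of a trial in the conventional column
#' layout: iteration, -2S_delta, P, Q, R_delta, k_deltaP, zero %, -1 %,
#' CC_rho', CC_rho''.
#'
#' @param trial A `"smar_trial"`.
#' @param path Output path.
#' @export
write_diagnostics <- function(trial, path) {
  utils::write.csv(trial$history, path, row.names = FALSE)
  invisible(path)
}
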