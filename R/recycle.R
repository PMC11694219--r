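#' delta_M tangent-formula step
#'
#' One application of the delta_M tangent formula: the updated phases are the
#' phases of the forward transform of the masked product `delta_M m_delta`.
#' The scaling of the masked map (the K constant of the underlying relation,
#' and the c constant inside delta_M) never changes transform phases, so
#' only phases are recycled.
#'
#' @param delta `"density_map"` holding delta_M.
#' @param m_delta Binary mask from [compute_m_delta()] on this delta_M.
#' @param refl A `"reflection_set"`.
#' @return New phase vector (radians) over the half-set.
#' @export
tangent_step <- function(delta, m_delta, refl) {
  masked <- delta$values * m_delta
  if (all(masked == 0)) stop("masked delta_M is identically zero: phases undefined")
  forward_transform(density_map(masked, delta$cell, delta$delta_grid),
                    refl)$phase
}

#' One delta-recycling trial
#'
#' Pure delta recycling loop: the current working phases Phi are used
#' directly as the alpha set of a delta_M synthesis over all reflections;
#' the binary mask `m_delta = 1` where `delta_M >= t1 sigma(delta_M)`
#' isolates the strong peaks; the tangent step returns the updated Phi.
#' There is no `|rho|` step and no sign mask — this is the single-formula
#' recycle that predates the two-residual SMAR scheme.  With `n_peaks` set,
#' the mask is restricted to the `n_peaks` largest local maxima of delta_M
#' above the threshold, which reduces the transform to a structure-factor
#' sum over the strongest product-function peaks.
#'
#' At its stationary point the recycle does not freeze: the hard threshold
#' mask makes successive phase sets wander around the solution with a
#' sizeable zero-mean per-iteration scatter.  The trial therefore reports,
#' as its final phase set, the circular mean of the unit phasors
#' `exp(i phi)` accumulated over the trailing iterations (after the burn-in
#' fraction `avg_start` of `max_iter`), which estimates the center of the
#' basin far more precisely than any single iterate.
#'
#' @param refl Normalized `"reflection_set"`.
#' @param t1 Mask threshold multiplier (default 2.5).
#' @param n_peaks Optional peak count for the largest-peaks variant.
#' @param max_iter Iteration cap (default 70).
#' @param seed Seed for the random starting phases.
#' @param c_scale delta_M scale constant.
#' @param delta_grid,dims Grid controls as in [smar_trial()].
#' @param avg_start Fraction of `max_iter` treated as burn-in before phasor
#'   averaging begins (default 0.6).
#' @param tol_deg Early-stop threshold on the `|E|`-weighted mean phase
#'   change per iteration, in degrees (default 1): a recycle that truly
#'   freezes needs no averaging.
#' @return Object of class `"recycling_trial"` with `phi` (tail-averaged),
#'   `phi_last`, `history` (`iteration`, `phase_change_deg`, `e_cc` — the
#'   correlation of the calculated tangent-step moduli with the observed
#'   `|E|`, the trial's figure of merit — and `map_cc` against the previous
#'   iteration's delta_M), `fom` (mean tail `e_cc`), `converged`,
#'   `iterations`, `seed`.
#' @export
recycling_trial <- function(refl, t1 = 2.5, n_peaks = NULL, max_iter = 70L,
                            seed = 1, c_scale = compute_c(refl),
                            delta_grid = refl$d_min / 3,
                            dims = grid_dims(refl, delta_grid),
                            avg_start = 0.6, tol_deg = 1) {
  set.seed(seed)
  phi <- stats::runif(nrow(refl$hkl), 0, 2 * pi)
  burn_in <- floor(avg_start * max_iter)
  acc <- complex(length(phi))
  n_acc <- 0L
  prev_delta <- NULL
  rows <- vector("list", max_iter)
  n_done <- 0L
  stopped_early <- FALSE
  for (it in seq_len(max_iter)) {
    delta <- synthesize_delta_m(refl, phi, c_scale, dims = dims,
                                delta_grid = delta_grid)
    m <- compute_m_delta(delta, t1)
    if (!is.null(n_peaks)) m <- m * top_peak_mask(delta, n_peaks, t1)
    masked <- delta$values * m
    if (all(masked == 0))
      stop("masked delta_M is identically zero: phases undefined")
    ft <- forward_transform(density_map(masked, delta$cell, delta$delta_grid),
                            refl)
    phi_new <- ft$phase
    dphi <- wrap_angle(phi_new - phi)
    change <- sum(refl$E * abs(dphi)) / sum(refl$E) * 180 / pi
    cc <- if (is.null(prev_delta)) NA_real_ else
      stats::cor(as.vector(delta$values), as.vector(prev_delta$values))
    rows[[it]] <- data.frame(iteration = it, phase_change_deg = change,
                             e_cc = stats::cor(ft$modulus, refl$E),
                             map_cc = cc)
    prev_delta <- delta
    phi <- phi_new
    if (it > burn_in) {
      acc <- acc + exp(1i * phi)
      n_acc <- n_acc + 1L
    }
    n_done <- it
    if (change < tol_deg) {
      stopped_early <- TRUE
      break
    }
  }
  history <- do.call(rbind, rows[seq_len(n_done)])
  phi_final <- if (stopped_early || n_acc == 0L) phi else Arg(acc)
  tail_ecc <- history$e_cc[history$iteration > burn_in]
  fom <- if (length(tail_ecc)) mean(tail_ecc, na.rm = TRUE)
         else history$e_cc[n_done]
  converged <- stopped_early || (!is.na(fom) && fom > 0.3)
  structure(list(phi = phi_final, phi_last = phi, history = history,
                 converged = converged, fom = fom,
                 iterations = n_done, seed = seed,
                 t1 = t1, n_peaks = n_peaks, dims = dims, refl = refl),
            class = "recycling_trial")
}

# binary mask covering only the voxels of the n largest local maxima of the
# map that clear the t1 sigma threshold
top_peak_mask <- function(delta, n_peaks, t1) {
  pk <- find_local_maxima(delta)
  thr <- t1 * map_sigma(delta)
  keep <- pk$heights >= thr
  centers <- pk$centers[keep, , drop = FALSE]
  centers <- centers[seq_len(min(n_peaks, nrow(centers))), , drop = FALSE]
  m <- array(0, delta$dims)
  m[centers] <- 1
  m
}

#' @export
print.recycling_trial <- function(x, ...) {
  cat(sprintf("delta-recycling trial (seed %d): %d iterations, FOM %.3f%s\n",
              x$seed, x$iterations, x$fom,
              if (x$converged) " (solution candidate)" else ""))
  invisible(x)
}

#' Multistart delta recycling
#'
#' Runs `trials` independent delta-recycling refinements from random phases
#' (seeds `seed + 0 ...`) and ranks them by figure of merit: the mean
#' correlation, over the averaging tail, between the tangent-step calculated
#' moduli and the observed `|E|` (descending; a trial locked in the solution
#' basin reproduces the amplitudes far better than a wandering false
#' solution).  Ties break by seed.
#'
#' @inheritParams recycling_trial
#' @param trials Number of random starts.
#' @param true_phi Optional reference phases for [score_against_truth()].
#' @return Object of class `"delta_recycling"`: ranked `trials`, `best`,
#'   optional `scores`, configuration.
#' @examples
#' cl <- unit_cell(7.4, 7.8, 8.1)
#' st <- random_structure(8, cl, seed = 2)
#' dat <- true_data(st, d_min = 1.1)
#' fit <- delta_recycling(dat, trials = 2, seed = 4, max_iter = 15)
#' @export
delta_recycling <- function(refl, t1 = 2.5, n_peaks = NULL, trials = 10,
                            seed = 1, max_iter = 70L,
                            c_scale = compute_c(refl),
                            delta_grid = refl$d_min / 3, true_phi = NULL) {
  if (trials < 1) stop("trials must be >= 1")
  runs <- lapply(seq_len(trials) - 1L, function(k)
    recycling_trial(refl, t1 = t1, n_peaks = n_peaks, max_iter = max_iter,
                    seed = seed + k, c_scale = c_scale,
                    delta_grid = delta_grid))
  fom <- vapply(runs, function(tr)
    if (is.na(tr$fom)) -Inf else tr$fom, numeric(1))
  seeds <- vapply(runs, function(tr) tr$seed, numeric(1))
  o <- order(-fom, seeds)
  runs <- runs[o]
  scores <- NULL
  if (!is.null(true_phi))
    scores <- lapply(runs, function(tr)
      score_against_truth(tr$phi, true_phi, refl, dims = tr$dims))
  structure(list(trials = runs, best = runs[[1]], fom = fom[o],
                 scores = scores, t1 = t1, seed = seed, refl = refl),
            class = "delta_recycling")
}
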