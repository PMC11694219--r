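#' chi phasing step
#'
#' The first half of a SMAR iteration: the new chi phases are the phases of
#' the forward transform of `|rho(Phi)| = rho(Phi) s_rho`, evaluated at every
#' reflection of the full set.  This is the update that minimizes the R_rho
#' residual.
#'
#' @param rho `"density_map"` synthesized from the current Phi.
#' @param refl A `"reflection_set"`.
#' @return List with `alpha` (chi phases, radians) and `xi` (the `|xi|`
#'   moduli of the transform, logged but not recycled).
#' @export
chi_step <- function(rho, refl) {
  ft <- forward_transform(density_map(abs(rho$values), rho$cell,
                                      rho$delta_grid), refl)
  list(alpha = ft$phase, xi = ft$modulus)
}

#' Phi (SMAR) phasing step
#'
#' The second half of a SMAR iteration: the modified density
#' `rho' = delta_M m_rho s_rho` is formed (slightly negative rho zones are
#' zeroed, very negative zones contribute `-delta_M`), in fast mode further
#' reduced to `rho''` by inner-pixel preservation, and the new Phi phases are
#' the phases of its forward transform.
#'
#' @param delta `"density_map"` holding delta_M(chi).
#' @param masks `"mask_set"` derived from the stored rho(Phi).
#' @param refl A `"reflection_set"`.
#' @param mode `"slow"` or `"fast"`.
#' @param n_atoms Expected atom count (required in fast mode).
#' @return List with `phi` (new phases), `e_calc` (calculated moduli),
#'   `rho_prime` and, in fast mode, `rho_dprime`.
#' @export
phi_step <- function(delta, masks, refl, mode = c("slow", "fast"),
                     n_atoms = NULL) {
  mode <- match.arg(mode)
  rho_prime <- density_map(delta$values * masks$combined, delta$cell,
                           delta$delta_grid)
  rho_dprime <- NULL
  source_map <- rho_prime
  if (mode == "fast") {
    if (is.null(n_atoms) || n_atoms < 1)
      stop("fast mode requires the expected atom count n_atoms")
    rho_dprime <- apply_ipp(rho_prime, n_atoms)
    source_map <- rho_dprime
  }
  ft <- forward_transform(source_map, refl)
  list(phi = ft$phase, e_calc = ft$modulus,
       rho_prime = rho_prime, rho_dprime = rho_dprime)
}

# correlation of rho'' with |rho| restricted to the ipp support
cc_dprime <- function(rho_dprime, rho, masks) {
  supp <- rho_dprime$values != 0
  S <- mean(rho_dprime$values * rho$values * masks$s * supp)
  P <- mean(rho$values^2 * supp)
  Q <- mean(rho_dprime$values^2)
  if (P * Q > 0) S / sqrt(P * Q) else 0
}

# convergence signature: R_delta has dropped well below its starting plateau
# and has stabilized (|change| < 0.005 over 3 consecutive iterations)
convergence_reached <- function(r_history, drop = 0.25, tol = 0.005, run = 3L) {
  n <- length(r_history)
  if (n < run + 1L) return(FALSE)
  plateau <- stats::median(r_history[seq_len(min(5L, n))])
  tail_r <- r_history[(n - run + 1L):n]
  all(tail_r < plateau - drop) && all(abs(diff(tail_r)) < tol)
}

#' One SMAR phasing trial from random phases
#'
#' Runs the four-stage dual-space recycle: from the current Phi, synthesize
#' rho (all reflections in slow mode, the `|E| >= e_lim` subset in fast
#' mode); take `|rho|` and transform it to obtain the chi phases; build
#' delta_M(chi) from `c (|E| - <|E|>)` coefficients over ALL reflections;
#' derive the masks from the stored rho (threshold `t` times the
#' all-reflection Parseval sigma); form `rho' = delta_M m s` (fast mode:
#' `rho''` by ipp over the `n_atoms` largest peaks); transform back to get
#' the updated Phi.  Full diagnostics are recorded every iteration, with the
#' residual integrals evaluated before ipp.
#'
#' @param refl Normalized `"reflection_set"` (atomic resolution advisable).
#' @param mode `"fast"` (default, uses ipp) or `"slow"`.
#' @param n_atoms Expected atom count (fast mode).
#' @param t Mask threshold multiplier (default 2.5).
#' @param max_iter Iteration cap (default 50 fast, 100 slow).
#' @param seed Integer seed for the random starting phases.
#' @param c_scale delta_M scale constant (default [compute_c()]).
#' @param delta_grid Voxel edge in Angstrom (default `d_min / 3`).
#' @param dims Grid dimensions (default from [grid_dims()]).
#' @return Object of class `"smar_trial"`: `phi` and `chi` (final phase
#'   sets), `e_calc`, `xi`, `history` (one diagnostics row per iteration),
#'   `converged`, `iterations`, `seed`, `mode`.
#' @export
smar_trial <- function(refl, mode = c("fast", "slow"), n_atoms = NULL,
                       t = 2.5, max_iter = NULL, seed = 1,
                       c_scale = compute_c(refl),
                       delta_grid = refl$d_min / 3,
                       dims = grid_dims(refl, delta_grid)) {
  mode <- match.arg(mode)
  if (is.null(max_iter)) max_iter <- if (mode == "fast") 50L else 100L
  if (mode == "fast" && (is.null(n_atoms) || n_atoms < 1))
    stop("fast mode requires the expected atom count n_atoms")
  set.seed(seed)
  phi <- stats::runif(nrow(refl$hkl), 0, 2 * pi)
  sigma_all <- map_sigma(refl, "all")
  nc <- normalization_constants(refl, c_scale, mode)
  subset <- if (mode == "fast") "strong" else "all"

  hist_rows <- vector("list", max_iter)
  alpha <- NULL; xi <- NULL; e_calc <- NULL
  converged <- FALSE
  n_done <- 0L
  for (it in seq_len(max_iter)) {
    rho <- synthesize_rho(refl, phi, subset = subset, dims = dims,
                          delta_grid = delta_grid)
    masks <- compute_masks(rho, sigma_all, t)
    cs <- chi_step(rho, refl)
    alpha <- cs$alpha; xi <- cs$xi
    delta <- synthesize_delta_m(refl, alpha, c_scale, dims = dims,
                                delta_grid = delta_grid)
    ri <- residual_integrals(delta, rho, masks, nc$SRO2)
    ps <- phi_step(delta, masks, refl, mode, n_atoms)
    phi <- ps$phi; e_calc <- ps$e_calc
    cc2 <- if (mode == "fast") cc_dprime(ps$rho_dprime, rho, masks) else NA_real_
    hist_rows[[it]] <- data.frame(
      iteration = it, minus2S_delta = ri$minus2S_delta, P = ri$P, Q = ri$Q,
      R_delta = ri$R_delta,
      k_delta_p = k_delta_p(ri$P, ri$minus2S_delta),
      zero_pct = unname(masks$fractions[2]),
      neg_pct = unname(masks$fractions[3]),
      CC_rho_prime = ri$CC, CC_rho_dprime = cc2,
      SRO2 = nc$SRO2, SDEL = nc$SDEL)
    n_done <- it
    if (convergence_reached(vapply(hist_rows[seq_len(it)],
                                   function(r) r$R_delta, numeric(1)))) {
      converged <- TRUE
      break
    }
  }
  history <- if (n_done > 0) do.call(rbind, hist_rows[seq_len(n_done)])
             else data.frame()
  structure(list(phi = phi, chi = alpha, e_calc = e_calc, xi = xi,
                 history = history, converged = converged,
                 iterations = n_done, seed = seed, mode = mode,
                 n_atoms = n_atoms, t = t, c_scale = c_scale, dims = dims,
                 refl = refl),
            class = "smar_trial")
}

#' @export
print.smar_trial <- function(x, ...) {
  cat(sprintf("SMAR trial (%s mode, seed %d): %d iterations, %s\n",
              x$mode, x$seed, x$iterations,
              if (x$converged) "converged" else "not converged"))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final R_delta = %.3f  CC_rho' = %.3f  zero %% = %.2f\n",
                last$R_delta, last$CC_rho_prime, last$zero_pct))
  }
  invisible(x)
}

#' Multistart SMAR phasing
#'
#' The user-facing fitting function: runs `trials` independent SMAR phase
#' refinements from random starting phases (per-trial seeds
#' `seed + 0 ... seed + trials - 1`) and ranks them by final R_delta
#' (ascending, ties broken by seed).  On data where any trial converges, the
#' true solution stands out through its clearly lower residual and the
#' sudden S_delta increase at convergence onset.
#'
#' @inheritParams smar_trial
#' @param trials Number of random starts.
#' @param e_lim Strong-reflection threshold applied to the data (default
#'   keep the set's own).
#' @param true_phi Optional reference phases; when given, every trial is
#'   scored with [score_against_truth()].
#' @return Object of class `"smar"`: ranked `trials` list (best first),
#'   `best` (the top trial), `scores` (when `true_phi` given), and the run
#'   configuration.  Methods: `print`, `summary`, `plot`, `coef`.
#' @examples
#' cl <- unit_cell(8.2, 8.6, 9.1)
#' st <- random_structure(12, cl, seed = 3)
#' dat <- true_data(st, d_min = 1.1)
#' fit <- smar(dat, n_atoms = 12, trials = 2, seed = 5, max_iter = 12)
#' print(fit)
#' @export
smar <- function(refl, mode = c("fast", "slow"), n_atoms = NULL,
                 trials = 10, seed = 1, t = 2.5, e_lim = NULL,
                 max_iter = NULL, c_scale = compute_c(refl),
                 delta_grid = refl$d_min / 3, true_phi = NULL) {
  mode <- match.arg(mode)
  if (trials < 1) stop("trials must be >= 1")
  if (!is.null(e_lim))
    refl <- reflection_set(refl$cell, refl$hkl, refl$E, refl$phi,
                           d_min = refl$d_min, e_lim = e_lim)
  runs <- lapply(seq_len(trials) - 1L, function(k)
    smar_trial(refl, mode = mode, n_atoms = n_atoms, t = t,
               max_iter = max_iter, seed = seed + k, c_scale = c_scale,
               delta_grid = delta_grid))
  final_r <- vapply(runs, function(tr)
    if (nrow(tr$history)) tr$history$R_delta[nrow(tr$history)] else Inf,
    numeric(1))
  seeds <- vapply(runs, function(tr) tr$seed, numeric(1))
  o <- order(final_r, seeds)
  runs <- runs[o]
  scores <- NULL
  if (!is.null(true_phi))
    scores <- lapply(runs, function(tr)
      score_against_truth(tr$phi, true_phi, refl, dims = tr$dims))
  structure(list(trials = runs, best = runs[[1]], final_R_delta = final_r[o],
                 scores = scores, mode = mode, n_atoms = n_atoms, t = t,
                 seed = seed, refl = refl),
            class = "smar")
}

#' Phase-set comparison up to origin and enantiomorph
#'
#' In P1 a phase set is defined only up to a continuous origin shift Delta
#' (`phi_h -> phi_h + 2 pi h.Delta`) and inversion (`phi -> -phi`).  The
#' estimate is aligned to the reference by maximizing the amplitude-weighted
#' cosine agreement over Delta — evaluated on the map grid by FFT, then
#' polished by direct optimization — on both enantiomorphs.
#'
#' @param phi Estimated phases (half-set, radians).
#' @param phi_true Reference phases on the same reflections.
#' @param refl The `"reflection_set"` carrying the amplitudes.
#' @param dims Grid used for the translation search.
#' @return List with `mean_phase_error` (degrees, `|E|`-weighted),
#'   `map_cc` (correlation of the two E-maps after alignment), `shift`
#'   (fractional), `enantiomorph` (logical), `phi_aligned`.
#' @export
score_against_truth <- function(phi, phi_true, refl, dims = grid_dims(refl)) {
  if (length(phi) != length(phi_true) || length(phi) != nrow(refl$hkl))
    stop("phase sets must cover the same reflections")
  w2 <- refl$E^2
  hkl <- refl$hkl
  align_one <- function(phi_est) {
    dphi <- phi_true - phi_est
    A <- coefficient_grid(hkl, w2 * exp(1i * dphi), dims)
    tmap <- Re(stats::fft(A))
    idx <- which.max(tmap) - 1L
    d0 <- c(idx %% dims[1],
            (idx %/% dims[1]) %% dims[2],
            idx %/% (dims[1] * dims[2])) / dims
    obj <- function(dd) -sum(w2 * cos(dphi - 2 * pi * drop(hkl %*% dd)))
    op <- stats::optim(d0, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 500))
    list(value = -op$value, shift = op$par %% 1)
  }
  direct <- align_one(phi)
  mirror <- align_one(-phi)
  flip <- mirror$value > direct$value
  best <- if (flip) mirror else direct
  phi_est <- if (flip) -phi else phi
  phi_aligned <- phi_est + 2 * pi * drop(hkl %*% best$shift)
  dphi <- wrap_angle(phi_true - phi_aligned)
  list(mean_phase_error = sum(refl$E * abs(dphi)) / sum(refl$E) * 180 / pi,
       map_cc = sum(w2 * cos(dphi)) / sum(w2),
       shift = best$shift, enantiomorph = flip,
       phi_aligned = wrap_angle(phi_aligned))
}

# wrap to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
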