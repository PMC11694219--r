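#' Normalized squared g-peak constant
#'
#' The R_delta residual of a correctly phased data set does not reach zero:
#' the sea of weak cross-vector peaks left under the `m = 1` part of the mask
#' contributes `<g^2>` per unit volume, whose normalized value is 1.12.  The
#' floor is therefore `1.12 <m_rho>`.
#' @export
G2NORM <- 1.12

#' Theoretical floor of the R_delta residual
#'
#' `R_delta(true phases) ~ G2NORM * <m_rho>`: about `1.12 x 0.45 = 0.50` in
#' slow mode (where the `m = 1` part of the mask covers ~45 percent of the
#' cell after convergence) and `1.12 x 27 N / N_vox ~ 0.06` in fast mode
#' (where ipp shrinks the support to the inner peak pixels).
#'
#' @param mean_m Mean of the `m` mask over the cell, in `[0, 1]`.
#' @return The floor value `G2NORM * mean_m`.
#' @export
r_delta_floor <- function(mean_m) {
  if (any(mean_m < 0 | mean_m > 1)) stop("mean_m must lie in [0, 1]")
  G2NORM * mean_m
}

#' Normalization constants SRO2 and SDEL
#'
#' `SRO2 = integral rho^2 dV` over the working reflection subset (all
#' reflections in slow mode, the strong subset in fast mode) — phase
#' independent via Parseval, it normalizes every residual integral.
#' `SDEL = integral delta_M^2 dV / SRO2`, which only depends on the
#' `(|E| - <|E|>)^2` values; with the default scale constant c and the full
#' working set, `SDEL = c` identically.
#'
#' @param refl A `"reflection_set"`.
#' @param c_scale Scale constant of the delta_M synthesis.
#' @param mode `"slow"` (all reflections in rho) or `"fast"` (strong subset).
#' @return List with `SRO2` and `SDEL`.
#' @export
normalization_constants <- function(refl, c_scale = compute_c(refl),
                                    mode = c("slow", "fast")) {
  mode <- match.arg(mode)
  keep <- if (mode == "fast") refl$strong else rep(TRUE, nrow(refl$hkl))
  if (!any(keep)) stop("empty working set")
  V <- refl$cell$volume
  SRO2 <- 2 * sum(refl$E[keep]^2) / V
  SDEL <- c_scale^2 * (2 * sum((refl$E - refl$e_mean)^2) / V) / SRO2
  list(SRO2 = SRO2, SDEL = SDEL)
}

# integral of a voxel field over the cell: V * (voxel mean)
cell_integral <- function(values, V) V * mean(values)

#' Residual integrals of one SMAR iteration
#'
#' The normalized integrals driving the phase refinement, all divided by
#' SRO2 and all evaluated on the shared grid as `V * (voxel mean)`:
#' `S_delta = integral delta_M m s rho dV`, `P = integral rho^2 m dV`,
#' `Q = integral delta_M^2 m dV`, `R_delta = P + Q - 2 S_delta`, and the
#' correlation coefficient `CC = S_delta / sqrt(P Q)` measuring the agreement
#' of the masked delta_M with `|rho|` on the mask support.
#'
#' @param delta `"density_map"` holding delta_M.
#' @param rho `"density_map"` holding the stored rho of the iteration.
#' @param masks `"mask_set"` computed from that rho.
#' @param SRO2 Normalization constant (see [normalization_constants()]).
#' @return List with `S_delta`, `minus2S_delta`, `P`, `Q`, `R_delta`, `CC`.
#' @export
residual_integrals <- function(delta, rho, masks, SRO2) {
  if (!identical(dim(delta$values), dim(rho$values)) ||
      !identical(dim(delta$values), dim(masks$m)))
    stop("delta, rho and masks must share one grid")
  V <- rho$cell$volume
  S <- cell_integral(delta$values * masks$combined * rho$values, V) / SRO2
  P <- cell_integral(rho$values^2 * masks$m, V) / SRO2
  Q <- cell_integral(delta$values^2 * masks$m, V) / SRO2
  CC <- if (P * Q > 0) S / sqrt(P * Q) else 0
  list(S_delta = S, minus2S_delta = -2 * S, P = P, Q = Q,
       R_delta = P + Q - 2 * S, CC = CC)
}

#' Empirical slope between P and 2 S_delta
#'
#' During a refinement the growth of P above its theoretical random-phase
#' value `P0 = 0.50` tracks `2 S_delta` linearly:
#' `k = (P - 0.50) / (2 S_delta)`, typically ~0.16 for atomic-resolution
#' equal-atom data.
#'
#' @param P Normalized integral P.
#' @param minus2S The quantity `-2 S_delta` as logged per iteration.
#' @return The slope, or `NA` when `S_delta = 0`.
#' @export
k_delta_p <- function(P, minus2S) {
  twoS <- -minus2S
  ifelse(twoS == 0, NA_real_, (P - 0.50) / twoS)
}

#' R_rho residual and S_rho integral
#'
#' The second SMAR residual compares a rho synthesis built with the chi
#' phases against `rho(Phi) s_rho = |rho(Phi)|`:
#' `R_rho = integral [rho(chi) - rho(Phi) s]^2 dV / SRO2` and
#' `S_rho = integral rho(chi) rho(Phi) s dV / SRO2` (its phase-dependent
#' part).  At chi equal to the phases of the full transform of `|rho(Phi)|`
#' the residual closes to ~0; maximizing S_rho over chi yields the chi
#' phasing formula (phases of `FT |rho|`).
#'
#' @param rho_chi `"density_map"` built from the chi phase set.
#' @param rho_phi `"density_map"` built from the Phi phase set.
#' @param s Sign field of `rho_phi` (array of +-1).
#' @param SRO2 Normalization; default `integral rho_phi^2 dV` from the grid.
#' @return List with `R_rho` and `S_rho`.
#' @export
r_rho <- function(rho_chi, rho_phi, s,
                  SRO2 = cell_integral(rho_phi$values^2, rho_phi$cell$volume)) {
  if (!identical(dim(rho_chi$values), dim(rho_phi$values)))
    stop("maps must share one grid")
  V <- rho_phi$cell$volume
  list(R_rho = cell_integral((rho_chi$values - rho_phi$values * s)^2, V) / SRO2,
       S_rho = cell_integral(rho_chi$values * rho_phi$values * s, V) / SRO2)
}
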