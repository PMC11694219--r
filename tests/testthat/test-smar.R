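test_that("chi step returns the transform phases of |rho|", {
  dat <- ref10()$dat
  rho <- synthesize_rho(dat, subset = "all")
  cs <- chi_step(rho, dat)
  # against the naive DFT oracle on |rho|
  pick <- round(seq(1, nrow(dat$hkl), length.out = 10))
  oracle <- naive_dft(density_map(abs(rho$values), rho$cell),
                      dat$hkl[pick, , drop = FALSE])
  expect_lt(max(abs(wrapped(cs$alpha[pick] - oracle$phase))), 1e-8)
  expect_equal(cs$xi[pick], oracle$modulus, tolerance = 1e-8)
  # an everywhere-nonnegative map: |map| = map, so alpha = its own phases
  pos <- density_map(abs(rho$values), rho$cell)
  expect_equal(chi_step(pos, dat)$alpha, forward_transform(pos, dat)$phase,
               tolerance = 1e-12)
})

test_that("Phi step is the identity at an all-positive fixed point", {
  dat <- ref10()$dat
  rho <- synthesize_rho(dat, subset = "all")
  ones <- array(1, rho$dims)
  mk <- structure(list(m = ones, s = ones, combined = ones, t = 2.5,
                       fractions = c(positive = 100, slightly_negative = 0,
                                     very_negative = 0)),
                  class = "mask_set")
  ps <- phi_step(rho, mk, dat, "slow")
  expect_lt(max(abs(wrapped(ps$phi - dat$phi))), 1e-10)
  expect_equal(ps$e_calc, dat$E, tolerance = 1e-10)
  expect_error(phi_step(rho, mk, dat, "fast"), "n_atoms")
})

test_that("very negative voxels contribute -delta_M to rho'", {
  dat <- ref10()$dat
  rp <- random_phases(dat, seed = 21)
  rho <- synthesize_rho(rp, subset = "all")
  sig <- map_sigma(dat, "all")
  mk <- compute_masks(rho, sig, 2.5)
  delta <- synthesize_delta_m(dat, chi_step(rho, dat)$alpha)
  ps <- phi_step(delta, mk, dat, "slow")
  very <- rho$values <= -2.5 * sig
  snz <- rho$values <= 0 & !very
  expect_gt(sum(very), 0)
  expect_equal(ps$rho_prime$values[very], -delta$values[very])
  expect_true(all(ps$rho_prime$values[snz] == 0))
  expect_equal(ps$rho_prime$values[rho$values > 0],
               delta$values[rho$values > 0])
})

test_that("trials are deterministic and respect max_iter", {
  dat <- ref10()$dat
  tr0 <- smar_trial(dat, mode = "slow", max_iter = 0, seed = 4)
  expect_equal(tr0$iterations, 0)
  expect_equal(nrow(tr0$history), 0)
  set.seed(4)
  expect_equal(tr0$phi, stats::runif(nrow(dat$hkl), 0, 2 * pi))
  tr1 <- smar_trial(dat, mode = "fast", n_atoms = 10, max_iter = 3, seed = 8)
  tr2 <- smar_trial(dat, mode = "fast", n_atoms = 10, max_iter = 3, seed = 8)
  expect_identical(tr1$phi, tr2$phi)
  expect_equal(nrow(tr1$history), 3)
  expect_true(all(c("minus2S_delta", "P", "Q", "R_delta", "k_delta_p",
                    "zero_pct", "neg_pct", "CC_rho_prime",
                    "CC_rho_dprime") %in% names(tr1$history)))
  # identity holds on every logged iteration
  expect_equal(tr1$history$R_delta,
               tr1$history$P + tr1$history$Q + tr1$history$minus2S_delta,
               tolerance = 1e-10)
})

test_that("multistart ranks by final R_delta with seed ties", {
  dat <- ref10()$dat
  fit <- smar(dat, mode = "fast", n_atoms = 10, trials = 3, seed = 5,
              max_iter = 4)
  expect_length(fit$trials, 3)
  expect_equal(fit$final_R_delta, sort(fit$final_R_delta))
  single <- smar(dat, mode = "fast", n_atoms = 10, trials = 1, seed = 5,
                 max_iter = 4)
  direct <- smar_trial(dat, mode = "fast", n_atoms = 10, max_iter = 4,
                       seed = 5)
  expect_equal(single$best$phi, direct$phi)
  expect_output(print(fit), "SMAR multistart")
  expect_s3_class(summary(fit), "summary.smar")
})

test_that("all maps respect Friedel symmetry (real densities)", {
  dat <- ref10()$dat
  rp <- random_phases(dat, seed = 2)
  rho <- synthesize_rho(rp, subset = "all")
  expect_true(is.numeric(rho$values))
  # transform of a masked (real) map: F(-h) = conj(F(h))
  clipped <- density_map(pmax(rho$values, 0), rho$cell)
  C <- fft(clipped$values, inverse = TRUE) * rho$cell$volume /
    prod(rho$dims)
  iplus <- smarphase:::grid_index(dat$hkl, rho$dims)
  iminus <- smarphase:::grid_index(dat$hkl, rho$dims, negate = TRUE)
  expect_lt(max(Mod(C[iplus] - Conj(C[iminus]))), 1e-8)
})

test_that("phase scoring aligns origin and enantiomorph exactly", {
  dat <- ref10()$dat
  s0 <- score_against_truth(dat$phi, dat$phi, dat)
  expect_equal(s0$mean_phase_error, 0, tolerance = 1e-8)
  expect_equal(s0$map_cc, 1, tolerance = 1e-12)
  shift <- c(0.13, 0.57, 0.91)
  moved <- -(dat$phi + 2 * pi * drop(dat$hkl %*% shift))
  s1 <- score_against_truth(moved, dat$phi, dat)
  expect_lt(s1$mean_phase_error, 0.01)
  expect_true(s1$enantiomorph)
  expect_equal(s1$map_cc, 1, tolerance = 1e-6)
  # random phases: raw wrapped error is 90 deg (uniform expectation);
  # origin/enantiomorph optimization recovers only a few degrees of it
  set.seed(6)
  rnd <- stats::runif(nrow(dat$hkl), 0, 2 * pi)
  raw <- mean_phase_change_deg(dat, rnd, dat$phi)
  expect_equal(raw, 90, tolerance = 3)
  s2 <- score_against_truth(rnd, dat$phi, dat)
  expect_gt(s2$mean_phase_error, 70)
  expect_lt(s2$mean_phase_error, 90)
  expect_lt(abs(s2$map_cc), 0.35)
})

test_that("a fast-mode step at the true solution stays in its basin", {
  fx <- ref60()
  dat <- fx$dat
  rho <- synthesize_rho(dat, subset = "strong")
  mk <- compute_masks(rho, map_sigma(dat, "all"), 2.5)
  alpha <- chi_step(rho, dat)$alpha
  # chi of the true |rho| stays close to the true phases
  expect_lt(mean_phase_change_deg(dat, alpha, dat$phi), 25)
  delta <- synthesize_delta_m(dat, alpha)
  ps <- phi_step(delta, mk, dat, "fast", n_atoms = 60)
  w <- dat$E[dat$strong]
  step <- mean_phase_change_deg(dat, ps$phi[dat$strong],
                                dat$phi[dat$strong], weights = w)
  expect_lt(step, 25)   # far inside the basin; random baseline is 90
})

test_that("slow mode uses all reflections and fast mode the strong subset", {
  dat <- ref10()$dat
  rp <- random_phases(dat, seed = 1)
  rs <- synthesize_rho(rp, subset = "strong")
  ra <- synthesize_rho(rp, subset = "all")
  # the strong-subset map must match a synthesis of the zeroed-weak set
  Ez <- ifelse(dat$strong, dat$E, 0)
  rz <- synthesize_rho(reflection_set(dat$cell, dat$hkl, Ez, rp$phi,
                                      d_min = dat$d_min), subset = "all",
                       dims = rs$dims)
  expect_equal(rs$values, rz$values, tolerance = 1e-12)
  expect_gt(max(abs(rs$values - ra$values)), 1e-6)
})
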