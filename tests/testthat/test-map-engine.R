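test_that("synthesis and forward transform are exact inverses", {
  dat <- ref10()$dat
  rho <- synthesize_rho(dat, subset = "all")
  expect_lt(abs(mean(rho$values)), 1e-10)
  ft <- forward_transform(rho, dat)
  expect_lt(max(abs(ft$modulus - dat$E)), 1e-10)
  expect_lt(max(abs(wrapped(ft$phase - dat$phi))), 1e-10)
  # empty synthesis
  z <- reflection_set(dat$cell, dat$hkl, rep(0, nrow(dat$hkl)), dat$phi,
                      d_min = dat$d_min)
  expect_true(all(synthesize_rho(z, subset = "all")$values == 0))
  expect_error(synthesize_rho(z, subset = "strong"), "no strong")
})

test_that("forward transform equals the naive DFT, also off band limit", {
  dat <- ref10()$dat
  rho <- synthesize_rho(dat, subset = "all")
  pick <- round(seq(1, nrow(dat$hkl), length.out = 12))
  sub <- dat$hkl[pick, , drop = FALSE]
  ft <- forward_transform(rho, dat)
  oracle <- naive_dft(rho, sub)
  expect_equal(ft$modulus[pick], oracle$modulus, tolerance = 1e-8)
  expect_lt(max(abs(wrapped(ft$phase[pick] - oracle$phase))), 1e-8)
  # a masked map is not band-limited; the contract is the grid DFT as-is
  clipped <- density_map(pmax(rho$values, 0), rho$cell, rho$delta_grid)
  ft2 <- forward_transform(clipped, dat)
  oracle2 <- naive_dft(clipped, sub)
  expect_equal(ft2$modulus[pick], oracle2$modulus, tolerance = 1e-8)
  expect_lt(max(abs(wrapped(ft2$phase[pick] - oracle2$phase))), 1e-8)
  expect_error(forward_transform(density_map(array(0, c(4, 4, 4)), dat$cell),
                                 dat), "Nyquist")
})

test_that("true phases place the N strongest peaks on the atoms", {
  fx <- ref10()
  rho <- synthesize_rho(fx$dat, subset = "all")
  pk <- find_local_maxima(rho)
  voxel <- max(cell_lengths(fx$st$cell) / rho$dims)
  for (i in seq_len(10)) {
    d <- min(smarphase:::periodic_distances(fx$st$cell, pk$frac[i, ],
                                            fx$st$xyz))
    expect_lt(d, sqrt(3) * voxel)
  }
})

test_that("map sigma agrees between Parseval and grid routes", {
  dat <- ref10()$dat
  rho <- synthesize_rho(dat, subset = "all")
  expect_equal(map_sigma(dat), map_sigma(rho), tolerance = 1e-8)
  expect_equal(map_sigma(density_map(3 * rho$values, rho$cell)),
               3 * map_sigma(rho), tolerance = 1e-12)
  expect_equal(map_sigma(density_map(array(0, c(4, 4, 4)), dat$cell)), 0)
})

test_that("the scale constant c matches hand arithmetic and Wilson data", {
  cl <- unit_cell(6, 6, 6)
  two <- reflection_set(cl, rbind(c(1, 0, 0), c(0, 1, 0)), c(2, 0),
                        d_min = 2)
  expect_equal(compute_c(two), 2)
  expect_error(compute_c(reflection_set(cl, rbind(c(1, 0, 0), c(0, 1, 0)),
                                        c(1, 1), d_min = 2)), "undefined")
  # Monte Carlo oracle: acentric Wilson |E| is Rayleigh with <|E|^2> = 1
  set.seed(123)
  e_mc <- sqrt(stats::rexp(20000))
  c_mc <- sum(e_mc^2) / sum((e_mc - mean(e_mc))^2)
  expect_equal(c_mc, 1 / (1 - pi / 4), tolerance = 0.05)
  expect_lt(abs(compute_c(ref60()$dat) - 1 / (1 - pi / 4)), 0.35)
})

test_that("delta_M synthesis is linear with zero-coefficient invariance", {
  dat <- ref10()$dat
  alpha <- dat$phi
  d1 <- synthesize_delta_m(dat, alpha, c_scale = 1)
  d2 <- synthesize_delta_m(dat, alpha, c_scale = 2)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)
  ft1 <- forward_transform(d1, dat)
  ft2 <- forward_transform(d2, dat)
  expect_lt(max(abs(wrapped(ft1$phase - ft2$phase))), 1e-10)
  # a reflection with |E| = <|E|> contributes nothing: its alpha is moot
  E <- dat$E
  k <- 7L
  E[k] <- sum(E[-k]) / (length(E) - 1)  # makes E[k] the set's own mean
  refl2 <- reflection_set(dat$cell, dat$hkl, E, dat$phi, d_min = dat$d_min)
  expect_lt(abs(refl2$E[k] - refl2$e_mean), 1e-9)
  a2 <- alpha
  a2[k] <- a2[k] + 2
  m1 <- synthesize_delta_m(refl2, alpha)
  m2 <- synthesize_delta_m(refl2, a2)
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
  expect_error(synthesize_delta_m(dat, alpha[-1]), "alpha")
})

test_that("delta_M carries A peaks equal to rho and B peaks at cross vectors", {
  # grid-commensurate 3-atom toy at near-full resolution: every A and B
  # position falls exactly on a voxel, so heights are read off directly
  cl <- unit_cell(8, 8, 8)
  xyz <- rbind(c(3, 5, 7), c(11, 21, 9), c(25, 13, 27)) / 32
  st <- crystal_structure(cl, xyz)
  dat <- true_data(st, d_min = 0.6)
  dims <- c(32L, 32L, 32L)
  rho <- synthesize_rho(dat, subset = "all", dims = dims)
  delta <- synthesize_delta_m(dat, dat$phi, dims = dims)
  atom_vox <- xyz * 32 + 1
  # A peaks: delta_M(r_l) = rho(r_l)
  expect_equal(delta$values[atom_vox], rho$values[atom_vox],
               tolerance = 0.05)
  # B peaks at r_j + r_l - r_m (l != m, j != m): height ~ atom peak / (N-1)
  B <- NULL
  for (j in 1:3) for (l in 1:3) for (m in 1:3) {
    if (l != m && j != m)
      B <- rbind(B, (xyz[j, ] + xyz[l, ] - xyz[m, ]) %% 1)
  }
  B <- unique(round(B * 32)) %% 32 + 1
  ratio <- median(delta$values[B]) / median(delta$values[atom_vox])
  expect_gt(ratio, 0.8 / 2)
  expect_lt(ratio, 1.2 / 2)
})

test_that("CORE radius comes from the termination-kernel root", {
  # dense-scan oracle for the first positive root of sin u - u cos u
  u <- seq(0.1, 6, by = 1e-5)
  f <- sin(u) - u * cos(u)
  i <- which(f[-1] * f[-length(f)] < 0)[1]
  u_scan <- u[i]
  expect_equal(u_scan, 4.4934, tolerance = 1e-4)
  expect_equal(core_radius(1) * 2 * pi, u_scan, tolerance = 1e-4)
  expect_equal(round(core_radius(1), 2), 0.72)
  expect_equal(core_radius(2.4), 2.4 * core_radius(1), tolerance = 1e-12)
  expect_error(core_radius(-1), "positive")
})

test_that("grid policy is Nyquist-sufficient and FFT-friendly", {
  dat <- ref60()$dat
  dims <- grid_dims(dat)
  hmax <- apply(abs(dat$hkl), 2, max)
  expect_true(all(dims >= 2 * hmax + 2))
  smooth_ok <- vapply(dims, function(n) {
    for (p in c(2, 3, 5)) while (n %% p == 0) n <- n / p
    n == 1
  }, logical(1))
  expect_true(all(smooth_ok))
  expect_true(all(dims >= cell_lengths(dat$cell) / (dat$d_min / 3) - 1))
})
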