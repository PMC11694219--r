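# Shared fixtures (built once per run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# ~60-atom reference structure at atomic resolution: the standard synthetic
# study condition (organic-crystal atom density, slightly triclinic P1 cell)
ref60 <- function() fixture("ref60", function() {
  cl <- unit_cell(10.2, 10.8, 11.4, 92, 95, 88)
  st <- random_structure(60, cl, min_dist = 1.2, seed = 11)
  list(st = st, dat = true_data(st, d_min = 1.0))
})

# small 10-atom structure for map-engine tests
ref10 <- function() fixture("ref10", function() {
  cl <- unit_cell(8.0, 8.4, 8.9, 91, 93, 88)
  st <- random_structure(10, cl, min_dist = 1.2, seed = 5)
  list(st = st, dat = true_data(st, d_min = 1.0))
})

# independent oracle: structure factors by per-reflection cosine/sine
# accumulation (no complex arithmetic, no vectorized matrix product)
naive_structure_factors <- function(st, hkl) {
  n <- nrow(hkl)
  amp <- numeric(n)
  ph <- numeric(n)
  for (i in seq_len(n)) {
    re <- 0; im <- 0
    for (j in seq_len(st$n_atoms)) {
      arg <- 2 * pi * sum(hkl[i, ] * st$xyz[j, ])
      re <- re + cos(arg)
      im <- im + sin(arg)
    }
    amp[i] <- sqrt(re^2 + im^2)
    ph[i] <- atan2(im, re)
  }
  list(modulus = amp, phase = ph)
}

# independent oracle: direct DFT of a gridded map at a few Miller indices,
# F(h) = (V/N_vox) * sum_voxels map(r) exp(+2 pi i h.r)
naive_dft <- function(map, hkl) {
  d <- map$dims
  fx <- (seq_len(d[1]) - 1) / d[1]
  fy <- (seq_len(d[2]) - 1) / d[2]
  fz <- (seq_len(d[3]) - 1) / d[3]
  n <- nrow(hkl)
  out_mod <- numeric(n)
  out_ph <- numeric(n)
  for (i in seq_len(n)) {
    h <- hkl[i, ]
    phase <- outer(outer(2 * pi * h[1] * fx, 2 * pi * h[2] * fy, "+"),
                   2 * pi * h[3] * fz, "+")
    re <- sum(map$values * cos(phase))
    im <- sum(map$values * sin(phase))
    Fh <- complex(real = re, imaginary = im) * map$cell$volume / prod(d)
    out_mod[i] <- Mod(Fh)
    out_ph[i] <- Arg(Fh)
  }
  list(modulus = out_mod, phase = out_ph)
}

wrapped <- function(x) smarphase:::wrap_angle(x)

mean_phase_change_deg <- function(refl, p1, p2, weights = refl$E) {
  sum(weights * abs(wrapped(p1 - p2))) / sum(weights) * 180 / pi
}
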