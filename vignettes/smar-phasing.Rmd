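---
title: "Dual-space phasing with SMAR and delta recycling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-space phasing with SMAR and delta recycling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smarphase)
```

## The phase problem and the delta direct methods

A single-crystal diffraction experiment measures only the moduli of the
normalized structure factors, $|E_h|$.  The electron density

$$\rho(\mathbf r) \;=\; \frac{1}{V}\sum_{\pm h} |E_h|\,
  \cos(2\pi\,\mathbf h\!\cdot\!\mathbf r - \varphi_h)$$

also needs the phases $\varphi_h$, which must be recovered computationally.
For equal-atom structures at atomic resolution, direct methods recover them
from two facts about $\rho$: it is nonnegative, and it is atomic (sharp,
well-separated peaks).

This package implements the family of methods built on the $\delta_M$
Fourier synthesis, whose coefficients are the *difference* moduli,

$$\delta_M(\mathbf r) \;=\; \frac{c}{V}\sum_{\pm h}
  \bigl(|E_h| - \langle|E|\rangle\bigr)\,
  \cos(2\pi\,\mathbf h\!\cdot\!\mathbf r - \alpha_h),$$

with $c$ a positive scale constant.  When the $\alpha$ set is (close to) the
true phase set, $\delta_M$ decomposes into two peak populations: the $N$
atomic peaks of $\rho$ itself (type A, with $\delta_M(\mathbf r_l) =
\rho(\mathbf r_l)$), and a sea of $N(N-1)^2$ much weaker positive peaks at
the cross vectors $\mathbf r_j + \mathbf r_l - \mathbf r_m$ (type B), each
roughly $1/(N-1)$ of an atomic peak.  Writing $g$ for the type-B sea, the
general relation is simply

$$\delta_M \;=\; \rho + g .$$

Both algorithms in the package are ways of exploiting this relation while
suppressing the unknown $g$:

* **delta recycling** solves the relation for $\rho$ and kills $g$ with a
  hard threshold mask on $\delta_M$ itself;
* **SMAR** isolates $g$ ($\delta_M - \rho = g$) and suppresses it with a
  mask derived from the *sign structure* of $\rho$, which also provides a
  second, independent residual through $|\rho|$.

## The mask system

A $\rho$ synthesis truncated at resolution $d_{\min}$ broadens each point
atom into a spherical positive core (the CORE, radius $\approx 0.72\,
d_{\min}$, the first zero of the spherical termination kernel
$\sin u - u\cos u$) surrounded by decaying ripples.  Away from the cores the
ripples of many atoms overlap into slightly positive and slightly negative
zones.  Because the true density is nonnegative, slightly negative values
carry a clear message: *no atom here*.  The per-voxel masks encode this:

| condition on $\rho$                | class             | $m$ | $s$ | $m\,s$ |
|------------------------------------|-------------------|-----|-----|--------|
| $\rho > 0$                         | COREs + SPZs      | 1   | 1   | 1      |
| $0 \ge \rho > -t\,\sigma_\rho$     | SNZs ("zero conversion") | 0 | $-1$ | 0 |
| $\rho \le -t\,\sigma_\rho$         | very negative     | 1   | $-1$ | $-1$  |

with $t = 2.5$ by default and $\sigma_\rho$ **always** the phase-independent
Parseval value over the full reflection set, even when $\rho$ itself is
synthesized from the strong subset.  Only this convention reproduces, at
random phases, both the slow-mode class percentages (about $50.0$ / $49.4$ /
$0.62\,\%$, the Gaussian expectations for a $2.5\sigma$ threshold) and the
fast-mode very-negative percentage of about $0.18\,\%$ (the threshold is
then effectively $2.5\sqrt{\Sigma_{\text{all}}/\Sigma_{\text{strong}}}
\approx 2.9$ in units of the map's own sigma).  Boundary ties are resolved
downward: $\rho = 0$ is slightly negative, $\rho = -t\sigma$ is very
negative.  Scans over $t$ favor $2.0$–$2.5$; at $t \ge 10$ all negative
density is zeroed, which measurably hurts the refinement.

## One SMAR iteration

Each iteration applies two phasing formulas in sequence
(`smar_trial()`):

1. **chi step.**  From the current $\Phi$, synthesize $\rho(\Phi)$ and take
   $|\rho| = \rho\, s_\rho$.  The new $\chi$ phases are the phases of
   $\mathrm{FT}\{|\rho|\}$ at every reflection.  This minimizes the residual
   $R_\rho = \tfrac{1}{\mathrm{SRO2}}\int[\rho(\chi) - \rho(\Phi)s_\rho]^2\,
   dV$, whose minimum at the solution is $\approx 0$.
2. **Phi step.**  Build $\delta_M(\chi)$ over *all* reflections, derive the
   masks from the stored $\rho(\Phi)$, and form the modified density
   $\rho' = \delta_M\, m_\rho\, s_\rho$: slightly negative zones are zeroed,
   positive zones take $\delta_M$, very negative zones take $-\delta_M$
   (restoring their sign).  The new $\Phi$ phases are the phases of
   $\mathrm{FT}\{\rho'\}$ (slow mode) or of $\mathrm{FT}\{\rho''\}$ (fast
   mode, below).  This maximizes $S_\delta$ and thereby minimizes the
   residual $R_\delta = P + Q - 2S_\delta$ with
   $S_\delta = \tfrac{1}{\mathrm{SRO2}}\int \delta_M\, m\, s\, \rho\, dV$,
   $P = \tfrac{1}{\mathrm{SRO2}}\int \rho^2 m\, dV$,
   $Q = \tfrac{1}{\mathrm{SRO2}}\int \delta_M^2 m\, dV$.

All integrals are evaluated as $V \times$ (voxel mean) and normalized by
$\mathrm{SRO2} = \int\rho^2 dV$ over the working reflection subset, making
them volume-free ratios.  Because of the $g$ sea left under the $m = 1$ part
of the mask, $R_\delta$ does not reach zero at the true phases: its floor is
proportional to the mask mean, `r_delta_floor(mean_m) = 1.12 * mean_m`
(about $0.50$ in slow mode where $\langle m\rangle \approx 0.45$, about
$0.06$ in fast mode where ipp shrinks the support to $27N/N_{\text{vox}}
\approx 0.05$).

**Modes.**  Slow mode synthesizes $\rho$ from all reflections and works with
density functions only.  Fast mode (the default) uses just the strong
reflections ($|E| \ge 1.0$) for $\rho$ — they carry a fraction $2/e \approx
0.74$ of $\Sigma|E|^2$ under Wilson statistics — while $\delta_M$ always
uses the full set, and compresses $\rho'$ to $\rho''$ by **inner-pixel
preservation (ipp)**: the 27-voxel cubes around the $N$ largest peaks are
kept, everything else is zeroed.  A peak is a voxel strictly exceeding its
26 periodic neighbors (ties disqualify; no sub-voxel interpolation), which
on the default $\approx d_{\min}/3$ grid implicitly enforces a minimum
interpeak separation of two voxel steps.

**Diagnostics.**  Every iteration logs $-2S_\delta$, $P$, $Q$, $R_\delta$,
the empirical slope $k_{\Delta P} = (P - 0.50)/(2S_\delta)$ (the theoretical
random-phase value of $P$ is $P_0 = 0.50$; the observed start is
$\approx 0.518$ in fast mode because the very negative class re-enters $m$),
the zero and $-1$ mask percentages, and the correlation coefficients
$\mathrm{CC}_{\rho'} = S_\delta/\sqrt{PQ}$ and its $\rho''$ analogue on the
ipp support.  Convergence shows as a sudden $S_\delta$ rise and $R_\delta$
collapse toward the floor, with the zero class growing by 3–7 points.

## Pure delta recycling

`delta_recycling()` iterates the $\delta_M$ tangent formula alone: the
current phases are used directly as the $\alpha$ set of $\delta_M$, the
binary mask $m_{\Delta\delta} = 1$ where $\delta_M \ge t_1\,\sigma(\delta_M)$
(default $t_1 = 2.5$, sigma from the grid) isolates the strong peaks, and
the new phases are those of $\mathrm{FT}\{\delta_M\, m_{\Delta\delta}\}$.
With `n_peaks = N` the mask is restricted to the $N$ largest maxima above
the threshold, reducing the transform to a structure-factor sum over the
strongest product-function peaks.  All phase updates are invariant under
rescaling of either $c$ or the masked map (the tangent formula only ever
uses transform *phases*), and the threshold is relative, so the whole
recycle is scale-free.

Two numerical devices, chosen during development on synthetic data and
reported here as the package's own design:

* **Tail phasor averaging.**  The hard threshold makes the recycle wander
  around its fixed point instead of freezing: at $N = 20$, $d_{\min} =
  1.0$ Å the single-iterate scatter is a 30–35° weighted phase error even
  when started *at* the true solution.  The scatter is almost zero-mean, so
  the trial's final phase set is the circular mean of $e^{i\varphi}$ over
  the trailing 40 % of iterations, which roughly halves the error
  (to $\approx$ 18–24° in the same setting).
* **Figure of merit.**  Trials are ranked by the mean tail correlation
  between the calculated tangent-step moduli and the observed $|E|$ — in
  our experiments solutions score $\approx 0.38$–$0.42$ against
  $0.16$–$0.22$ for false minima, a much cleaner separation than the
  correlation of successive $\delta_M$ maps.  A trial with figure of merit
  above $0.3$ is flagged a solution candidate.

## The scale constant c

The coefficient scale of $\delta_M$ is fixed as
$c = \Sigma|E|^2 / \Sigma(|E| - \langle|E|\rangle)^2$ (about
$1/(1 - \pi/4) \approx 4.66$ for acentric Wilson data).  This is the unique
scale at which the projection of the $\delta_M$ coefficients onto the $|E|$
coefficients is exactly 1 — equivalently, the $\rho$ component inside
$\delta_M$ is unit-scaled, so type-A peaks satisfy $\delta_M(\mathbf r_l) =
\rho(\mathbf r_l)$ — and it makes the normalization constant
$\mathrm{SDEL} = \int\delta_M^2 dV / \mathrm{SRO2}$ equal $c$ identically in
slow mode.  `c_scale` is configurable, and everything that drives the
refinement — all phase updates, the masks, $P$, $\mathrm{CC}$, $Q/\mathrm{SDEL}$
and the mask fractions — is provably invariant under $c \to \lambda c$
(the slope $k_{\Delta P}$ scales as $1/\lambda$, since $S_\delta$ is linear
in $c$); the test suite asserts this numerically.  Absolute levels of
$S_\delta$, $Q$ and $R_\delta$ do scale with $c$, so they are validated
through scale-free identities ($R_\delta = P + Q - 2S_\delta$;
$Q_0 \approx 0.50\,\mathrm{SDEL}$) rather than raw magnitudes.

## Synthetic data: what it emulates and what it does not

`random_structure()` places $N$ equal point atoms uniformly in a P1 cell by
rejection sampling with a 1.2 Å minimum periodic distance (a bonding-scale
floor), and `true_data()` computes exact normalized structure factors by
direct summation, $E_h = N^{-1/2}\sum_j e^{2\pi i\,\mathbf h\cdot\mathbf
r_j}$ — the oracle against which every FFT route is tested.  The defaults
emulate a small organic crystal: $\approx 20$ Å$^3$ per atom, atomic
resolution $d_{\min} = 1.0$ Å, complete data to the resolution sphere.
Generated data reproduce acentric Wilson statistics
($\langle|E|^2\rangle = 1$, $\langle|E|\rangle = \sqrt\pi/2 \approx 0.886$,
strong-subset share $2/e$ of $\Sigma|E|^2$).

Deliberately absent: scattering-factor and thermal falloff (atoms are
points), measurement noise and incompleteness, space-group symmetry and
centric zones (phasing is always done in P1; the generator can place
symmetry mates, but no phase restrictions are imposed), and solvent or
disorder.  Passing tests therefore demonstrate the *algorithms* — their
transforms, masks, residuals and convergence — under ideal equal-atom
conditions; they do not demonstrate robustness to experimental data quality.

## Numerical conventions

* **Transforms.**  $F_h = \sum_j e^{+2\pi i\,\mathbf h\cdot\mathbf r_j}$,
  $\rho(\mathbf r) = V^{-1}\sum F_h e^{-2\pi i\,\mathbf h\cdot\mathbf r}$,
  enforced by a shift-theorem test (translating the structure by
  $\Delta$ adds $+2\pi\,\mathbf h\cdot\Delta$ to each phase).  Reflections
  are stored as a unique half-set; Friedel completion keeps every map real,
  and (0,0,0) is always excluded, so maps are mean-zero.
* **Grid.**  Per axis, the smallest 2,3,5-smooth integer at least
  $\max(\text{edge}/\Delta_{\text{grid}},\ 2h_{\max}+2)$, with
  $\Delta_{\text{grid}} = d_{\min}/3$ ($\approx 0.33$ Å at atomic
  resolution, the spacing the ipp neighborhood criterion presumes).  Masked
  maps are transformed as-is on this grid — aliasing of the non-band-limited
  product is part of the method's definition, and the FFT is checked against
  a naive DFT oracle on exactly such maps.
* **Convergence (SMAR).**  The printed trajectories show a plateau followed
  by a collapse of $R_\delta$ within a few iterations.  A trial is declared
  converged when $R_\delta$ sits more than $0.25$ below the median of its
  first five iterations and has changed by less than $0.005$ over three
  consecutive iterations.
* **Origin and enantiomorph.**  P1 phases are defined only up to a
  continuous origin shift and inversion.  `score_against_truth()` aligns an
  estimate to a reference by maximizing the $|E|^2$-weighted cosine
  agreement over the shift — an FFT translation map seeds a Nelder–Mead
  polish — on both enantiomorphs, then reports the $|E|$-weighted mean
  absolute wrapped phase difference and the map correlation
  $\Sigma|E|^2\cos\Delta\varphi / \Sigma|E|^2$.  Uniform random phases give
  a raw error of 90°; the alignment's freedom recovers a few degrees of
  that (to $\approx 80$–85° on $\sim 10^3$ reflections), which is the
  correct null reference for judging solutions.
* **Degenerate inputs.**  Empty reflection sets, constant maps, all-equal
  $|E|$ (undefined $c$), an empty strong subset, masks that zero the whole
  map, and infeasible packings all raise explicit errors; ipp warns and
  proceeds when fewer peaks exist than requested.

## Problem sizes used in validation

The shipped tests and the acceptance script use: a 60-atom P1 structure
($10.2 \times 10.8 \times 11.4$ Å, $\approx 2600$ unique reflections at
$d_{\min} = 1.0$ Å) for mask statistics and iteration-1 integrals, averaged
over 20 random phase sets in the script (at least 10 everywhere); a 40-atom
structure with 10 fast-mode trials for the end-to-end SMAR solve; a 20-atom
structure with 20 trials for the delta-recycling solve; and 3–10-atom toys
for the exactly enumerable properties (B-peak positions, peak picking,
transform oracles).  These sizes were chosen so every statistic sits well
inside its asymptotic regime while a full validation run stays interactive.

## Known limitations

* The fixed-point wobble of both engines leaves a finite phase error even
  from perfect starting phases (about 14° for a fast-mode SMAR step on the
  working set, larger for the raw recycle step); the final maps are easily
  interpretable (map CC $\ge 0.85$) but the phases are not refined to
  crystallographic convergence — that is the job of a subsequent Fourier
  refinement, which is out of scope.
* Slow-mode SMAR recycles the full reflection set and consequently carries
  a larger per-step wobble than fast mode; on our synthetic conditions fast
  mode is strictly the better default, matching its role as the method's
  default operating mode.
* No space-group machinery: centric phase restrictions are neither imposed
  nor exploited, origin fixing is continuous, and symmetry is only ever a
  property of the generator, not of the phasing.
* The physical meaning of the very negative density class is an open
  question in the field; the implementation simply follows the sign-restore
  rule and exposes the class percentage per iteration.
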