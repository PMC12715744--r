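---
title: "Characterizing a PHIP polarizer: models, fits and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a PHIP polarizer: models, fits and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phiptools)
```

## What this package models

Parahydrogen-induced polarization (PHIP) produces hyperpolarized contrast
agents by hydrogenating an unsaturated precursor with parahydrogen (pH2):
the nuclear singlet order of pH2 is deposited on the two nascent protons
and converted into observable magnetization by a pulse sequence. A
polarizer built around a low-field (here 0.4454 T) MRI magnet must be
characterized along several axes before its polarization numbers can be
trusted: B0 homogeneity (line widths), B1 homogeneity across the sample
(nutation curves), field stability and effective T2 (CPMG), injection
reproducibility, hydrogenation kinetics, and finally the polarization
yield relative to a thermal reference. `phiptools` implements the
computational side of each of those steps, together with seeded synthetic
data generators so that every fitting stage can be validated as a
generator-to-fitter round trip without any instrument attached.

## Spin simulation

### Hamiltonian and propagation

Systems of up to 8 spin-1/2 nuclei are simulated in the rotating frame
with the Hamiltonian (angular-frequency units)

$$H = \sum_i 2\pi\,\delta_i\,10^{-6}\,\nu_{\mathrm{ref}}\,I_{iz}
    + \sum_{i<j} 2\pi J_{ij}\,\mathbf{I}_i\cdot\mathbf{I}_j ,$$

i.e. full (strong) scalar coupling by default. This matters at low field:
for the ethyl acetate protons the shift difference (2.86 ppm, about
53.5 Hz at an 18.717 MHz carrier) is only 7.5 times the 7.1 Hz vicinal
coupling, so second-order effects shift sequence optima by several
percent relative to the weak-coupling (secular, $I_{iz}I_{jz}$) limit.
The weak-coupling truncation is available via
`build_spin_system(..., coupling = "weak")`; its closed-form product-operator
solutions serve as independent oracles in the test suite.

Note that the carrier frequency anchoring 0 ppm is an instrument setting
and is deliberately a parameter separate from $B_0$: the defaults pair
0.4454 T with an 18.717 MHz carrier even though $\gamma B_0/2\pi$ for
protons at that field is about 18.96 MHz.

Free evolution uses the exact eigendecomposition of the (time-independent)
Hamiltonian, computed once per system; there is no integration step size
to tune. Pulses are ideal, zero-duration rotations
$U = \exp[-i\theta(F_x\cos\phi + F_y\sin\phi)]$. Both are unitary by
construction, and the test suite asserts eigenvalue preservation of the
density operator to 1e-10 across random sequences. B1 inhomogeneity is
deliberately *not* modelled inside the propagator; it enters only at the
ensemble level (below), keeping the two concerns separate.

### PASADENA state and enrichment bookkeeping

`pasadena_state()` places parahydrogen-derived order on the two nascent
protons. Because hydrogenation takes seconds — long compared with the
inverse shift difference of the pair — the zero-quantum coherences of the
singlet average away, and the default initial deviation is the
longitudinal two-spin order $-s\,I_{1z}I_{2z}$ (`dephased = TRUE`); the
full singlet projector is available behind the flag. The enrichment
factor $s = (4f-1)/3$ maps the pH2 fraction $f$ onto usable spin order:
$s = 0$ at the thermal fraction $f = 1/4$, $s = 1$ at pure pH2. Every
detected signal is exactly linear in $s$ (a tested invariant), and the
polarization ceiling of the two-proton sequence,
`max_polarization(f)` $= 0.5\,(4f-1)/3$, evaluates to 50% at $f = 1$ and
44.7% at $f = 0.92$.

### Detection conventions

One set of conventions is fixed package-wide so that signal integrals are
comparable across experiments:

* the observable is $2^{2-N}\,\mathrm{Tr}[\rho\,\sum_i (I_{ix}+iI_{iy})]$,
  normalized so a unit $I_{ix}$ deviation detects as 1;
* the receiver is aligned with $+x$: thermal $I_z$ excited by a 90° pulse
  of phase $+y$ gives a positive real signal, and the in-phase channel is
  the real part;
* "signal integral" means the real part of the first FID point, which by
  the Fourier identity carries the spectrum integral (the trapezoidal
  spectrum returned by `fid_to_spectrum()` integrates to half the first
  point);
* `detect_fid(..., lw = )` applies $\exp(-\pi\,\mathrm{lw}\,t)$
  apodization, i.e. a Lorentzian line of FWHM `lw` Hz — the package's
  homogeneous-broadening model for simulated spectra;
* `fid_to_spectrum()` halves the first FID point before the DFT
  (trapezoidal quadrature). Without this standard correction the
  rectangle-rule baseline inflates a measured 8 Hz FWHM by about 3%.

## The out-of-phase echo sequence

The OPE sequence `45x - [tau - 90x 180y 90x - tau] x 3 - FID` converts the
antiphase PASADENA pattern into in-phase signal while refocusing chemical
shifts, which makes it usable in the inhomogeneous field of a large-bore
low-field magnet. The composite block `90x 180y 90x` acts as a broadband
inversion. For two weakly coupled spins starting from $-s I_{1z}I_{2z}$
the detected integral has the closed form

$$S(\tau) = \tfrac{s}{2}\,\sin(6\pi J\tau)\,e^{-\tau/T_d},$$

giving an undamped optimum at $\tau = 1/(12J)$ and, with damping, at
$\tan(6\pi J\tau) = 6\pi J T_d$. The phenomenological factor
$e^{-\tau/T_d}$ absorbs relaxation and couplings outside the simulated
spin set (for the deuterated product, notably the deuteron couplings,
which are not simulated).

Two presets are bundled (`ea_spin_system()`), both products of vinyl
acetate hydrogenation at the defaults above:

* **EA-d6** — the deuterated isotopologue, reduced to the two nascent
  protons (1.26 / 4.12 ppm, $^3J$ = 7.1 Hz), default $T_d$ = 160 ms;
* **EA-h6** — the protonated ethyl fragment: CH3 (3 × 1.26 ppm) and OCH2
  (2 × 4.12 ppm) with all six inter-group couplings at 7.1 Hz, default
  $T_d$ = 60 ms. Couplings among magnetically equivalent spins are set to
  zero (they do not influence the dynamics), and the distant, uncoupled
  acetate methyl is excluded, keeping the dimension at $2^5$.

`ope_tau_scan()` evaluates a fresh initial state per delay and refines the
grid optimum by quadratic interpolation through its three surrounding
points; with the default 0.1 ms grid the interpolation error is far below
the grid step. With the defaults, the scans place the optima at 10.5 ms
(EA-d6) and 7.1 ms (EA-h6) — the strong-coupling density-matrix treatment,
not any tuned constant, produces these values.

```{r ope-example, eval = FALSE}
sys <- ea_spin_system("EA-d6")
scan <- ope_tau_scan(
  function() pasadena_state(sys, attr(sys, "pasadena_pair"), f = 0.92),
  ope_config(tau = 1e-3, td = attr(sys, "default_td")),
  taus = seq(1e-3, 30e-3, by = 1e-4))
scan$tau_opt
```

## B1 homogeneity from nutation curves

A nutation curve (signal versus excitation-pulse duration) decays when
different sample regions nutate at different rates. Two models are
involved:

* the *fitting* model `fit_damped_sine()`:
  $A e^{-kt}\sin(2\pi t/T)$, a phenomenological damped sine whose decay
  rate $k$ summarizes the inhomogeneity. Start values come from the FFT
  (period) and the oscillation-peak envelope (rate); curves whose dominant
  FFT magnitude is below 6 times the median spectral magnitude — a level
  white noise alone can approach — are rejected rather than fitted.
* the *physical* model `nutation_ensemble()`: nutation frequencies drawn
  from $\nu \sim N(1/T,\ \sigma_{\mathrm{rel}}/T)$, averaged by 64-node
  Gauss–Hermite quadrature. The average equals
  $\sin(2\pi\nu_0 t)\,e^{-2\pi^2\sigma_\nu^2 t^2}$ analytically, and the
  quadrature reproduces that envelope to 1e-8 (a tested invariant).

`estimate_b1_sigma()` inverts the physical model: it simulates noiseless
ensemble curves over the fit window, fits them with the *same* damped-sine
model that was applied to the data, and bisects on
$\sigma_{\mathrm{rel}} \in [0, 0.2]$ (tolerance 1e-4) until the simulated
decay rate matches the observed one. Fitting the identical model to data
and simulation is what makes the inversion well defined despite the
Gaussian-versus-exponential envelope mismatch. The estimate depends on
the fit window, which is therefore an explicit argument and is recorded
in the result; the default window, 0–1.2 ms (about 13 periods at
$T$ = 90.3 µs), covers the usable extent of a typical low-field nutation
measurement. Round trips over $\sigma \in \{0.26, 1.03, 2.30, 4.08\}\%$
recover the generating spread to within 0.1 percentage point.

## CPMG relaxometry with a diffusion-homogeneity term

For a CPMG train with echo spacing $2\tau$, echo amplitudes follow
$M_n = M_0\,e^{-R_2^{\mathrm{obs}}\,2n\tau}$ with

$$R_2^{\mathrm{obs}} = \frac{1}{T_2} + D^{*}\,(2\tau)^2 , \qquad
  D^{*} = \tfrac{1}{12}\gamma^2 G^2 D ,$$

where the effective diffusion-homogeneity coefficient $D^{*}$ lumps the
residual field gradient $G$ and the diffusion coefficient $D$; only the
product is identifiable, so neither is represented separately. The
analysis is two-stage, mirroring how such data are acquired and reported:

1. `fit_echo_decay()` fits each train monoexponentially — weighted
   log-linear least squares (weights $\propto$ amplitude²) with a
   nonlinear refinement; trains whose late echoes fall below zero under
   noise skip the log stage and are fitted nonlinearly.
2. `fit_hahn()` regresses the per-$\tau$ rates on $(2\tau)^2$, giving
   $1/T_2$ (intercept) and $D^{*}$ (slope).

The default fitting window keeps $2\tau \in [40, 400]$ ms. Below 40 ms
the observed rates of bubbling reactors are inflated by convection and by
the limited kinetic window of a finite echo train; both effects lack a
quantitative model here, so short spacings are excluded rather than
modelled. Both the window and the 169-echo default are configuration,
not constants. `correlate_dstar_fwhm()` closes the loop between the two
inhomogeneity measures, regressing $D^{*}$ against the line width with an
optional origin point; both intercept and through-origin fits are
available (default: intercept), and $R^2$ is computed about the mean of
the augmented responses.

## Hydrogenation kinetics and polarization accounting

The hyperpolarized product concentration during bubbling follows
rise-and-fall kinetics,

$$[\mathrm{PC_H}] = [\mathrm{PC_0}]\,P_0\,\frac{1}{1 - R/k_1}
  \left(e^{-\tau_b R} - e^{-\tau_b k_1}\right),$$

with both exponents decaying — precursor consumption at $k_1$ competing
with signal decay at $R$ — so the curve rises, peaks at
$\tau_b^{*} = \ln(k_1/R)/(k_1-R)$ and falls. The removable singularity at
$R = k_1$ is replaced by its analytic limit
$[\mathrm{PC_0}] P_0 k_1 \tau_b e^{-k_1\tau_b}$. Whether $R$ is best read
as a relaxation or a reaction rate is left open; the parameter names are
neutral.

`quantify_polarization()` implements thermal-reference accounting:
$P = (S_{\mathrm{hyp}}/S_{\mathrm{th}})\,c\,P_{\mathrm{th}}$, where the
correction coefficient $c$ is the fraction of the (spectrally unresolved)
low-field thermal spectrum that belongs to the product, determined on a
high-resolution system. $P_{\mathrm{th}} = \tanh[\gamma\hbar B_0/(2k_BT)]$
is about 3.2e-5 at 9.4 T / 300 K and 1.5e-6 at 0.4454 T. The thermal
reference temperature is an explicit argument, since sample and magnet
temperature need not coincide. The molar polarization
$n_{\mathrm{protons}} \times c_{\mathrm{product}} \times P$ (mM) is
reported alongside $P$ because it is invariant under sequences that
redistribute the same order over fewer protons (a tested invariant:
doubling $P$ while halving $n_{\mathrm{protons}}$ leaves it unchanged).

`reactor_volume()` models the fill volume as a cylinder with an optional
hemispherical bottom, $\pi r^2 h - \tfrac{1}{3}\pi r^3$. This reproduces
weighed fill volumes of 16 mm OD (ID 12.5 mm) and 5 mm OD (ID 4.2 mm)
tubes filled to 20 mm within 1–2%, but it is a genuine limitation that
intermediate 10 mm geometries with thicker walls or tapered bottoms are
not captured (the model overestimates a nominal 1.013 mL fill by ~19%);
the model is validated only for the two tube families above.

## Synthetic data: what it does and does not emulate

Each generator draws from the same model family its fitter assumes, plus
noise: damped-sine or Gaussian-ensemble nutation curves, CPMG trains from
the $R_2^{\mathrm{obs}}$ law, normally distributed injection series at a
set coefficient of variation, and OPE tau-scans from the density-matrix
simulation. Defaults represent the study conditions used throughout the
documentation: 10 echo spacings with $2\tau \in [40, 400]$ ms and 169
echoes; nutation grids of 0–1.2 ms in 2 µs steps; 3 series of 10
injections; tau grids of 1–30 ms in 0.1 ms steps. The default noise is
1% additive (relative to the maximum amplitude), the level at which all
recovery figures are quoted; generators are bit-reproducible functions of
their parameters and seed, restore the caller's RNG state, and embed
their ground truth as a `truth` attribute.

Passing round-trip tests therefore demonstrates *estimator correctness
under the assumed models*, not robustness to everything real instruments
produce: baseline drift and phase errors, non-Gaussian B1 profiles,
convection at short echo spacings, radiation damping, magnet thermal
drift (1–2 ppm/mK class), and bubbling-induced signal loss are all
outside the generators on purpose.

## Numerical choices, in one place

* Free evolution by exact eigendecomposition; no step-size knob exists.
* Quadratic interpolation refines OPE grid optima; report-grade scans use
  a 0.1 ms grid.
* Gauss–Hermite quadrature with 64 nodes (exact for polynomial degree
  127) for the nutation ensemble.
* Bisection on $\sigma_{\mathrm{rel}}$ with tolerance 1e-4 (0.01
  percentage point).
* Echo-decay fits: weighted log-linear with nonlinear polish
  (`minpack.lm::nlsLM`); constant trains return rate 0; non-positive
  amplitudes switch to the purely nonlinear route.
* First-FID-point halving in the DFT; FWHM by linear interpolation of the
  half-height crossings.
* Test problem sizes: 50-seed medians for CPMG and nutation recovery,
  20–100 seeds for bias/CV properties, chosen so the whole suite runs in
  seconds while sampling error stays well inside the asserted tolerances.

## Known limitations

Ideal pulses only (no finite-pulse or off-resonance effects inside the
propagator); spin-1/2 nuclei only — deuterated species are represented by
their proton subsystem with deuteron couplings absorbed into $T_d$; no
relaxation superoperators (relaxation enters only through phenomenological
factors: `lw`, $T_d$, $R$); no heteronuclear transfer sequences; no
explicit convection or diffusion simulation inside CPMG (only the
effective $(2\tau)^2$ law); no vendor spectrometer formats (CSV/JSON and
the plain-text spin-system configuration only).
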