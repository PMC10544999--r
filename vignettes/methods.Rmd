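---
title: "Models and methods behind phycoexciton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phycoexciton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycoexciton)
```

# The problem

Cryptophyte algae harvest light with phycobiliprotein antennae built from
two alpha-beta protomers carrying eight open-chain tetrapyrrole (bilin)
chromophores — phycocyanobilin (PCB), 15,16-dihydrobiliverdin (DBV) and
mesobiliverdin (MBV) in the complexes this package targets.  Two
quaternary forms exist: a "closed" arrangement with a strongly coupled
central DBV pair, and an "open" one in which a ~73 degree rotation of one
protomer attenuates that coupling by an order of magnitude.  The optical
properties (absorption, circular dichroism, fluorescence) are controlled
by (i) the site energies of the bilins, which the protein scaffold tunes
through the torsions of the methine bridges connecting the pyrrole rings,
(ii) interpigment excitonic couplings, and (iii) static and dynamic
disorder from slow protein conformations and fast nuclear motions.

`phycoexciton` implements the analysis layer of this problem: from site
energies, couplings and bath models to disorder-averaged spectra, plus
the structural descriptors (bilin torsions, RMSF, protomer rotation) and
the disorder estimators used to interpret nested molecular-dynamics
ensembles.  The quantum-chemistry and MD machinery that would produce
real inputs is out of scope; a synthetic generator with known ground
truth replaces it, which is what makes the test suite's parameter
recovery meaningful.

# Exciton model

The Frenkel Hamiltonian is
$$H = \sum_{n=1}^N \varepsilon_n |n\rangle\langle n| +
      \sum_{n\neq m} V_{nm} |n\rangle\langle m|,$$
with site energies $\varepsilon_n$ and couplings $V_{nm}$ in
cm$^{-1}$.  Diagonalization yields exciton states
$|k\rangle = \sum_n C_{nk}|n\rangle$ with energies $\varepsilon_k$
(ascending; degenerate blocks ordered by descending dipole strength, and
each eigenvector's largest coefficient made positive, for reproducible
output).  Derived per state: dipole strengths
$D_k = |\sum_n C_{nk}\boldsymbol\mu_n|^2$ (Debye$^2$), rotational
strengths in the point-dipole exciton form
$R_k = \sum_{n<m} C_{nk} C_{mk}\, \mathbf{r}_{nm}\cdot
(\boldsymbol\mu_n\times\boldsymbol\mu_m)$ with a unit prefactor (CD is
plotted in arbitrary units, so the prefactor convention is recorded here
and fixed to one), and the inverse participation ratio
$(\sum_n C_{nk}^4)^{-1}$ as a delocalization length.  Three sum rules
($\sum_k \varepsilon_k = \sum_n \varepsilon_n$,
$\sum_k D_k = \sum_n |\boldsymbol\mu_n|^2$, $\sum_k R_k = 0$) are
enforced as tested invariants.

# Bath model and lineshape theory

Each site couples to a harmonic bath summarized by a spectral density

$$J(\omega) = \underbrace{\frac{2\lambda_c\gamma_c\,\omega}
{\omega^2+\gamma_c^2}}_{\text{overdamped Brownian oscillator}}
 + \sum_j \frac{2 S_j\omega_j^3\,\gamma_j\,\omega}
{(\omega^2-\omega_j^2)^2 + \gamma_j^2\omega^2},$$

an overdamped continuum for slow environmental motions plus damped
discrete intramolecular modes with Huang-Rhys factors $S_j$
($\lambda_j = S_j\omega_j$).  The total reorganization energy is
$\lambda = \lambda_c + \sum_j S_j\omega_j$, and `stokes_calibrate()`
solves $2\lambda = $ target Stokes shift for $\lambda_c$ given a mode
list — the calibration used when the continuum is fitted against an
observed Stokes shift.

The second-order cumulant lineshape function
$$g(t) = \frac1\pi\int_0^\infty \frac{J(\omega)}{\omega^2}
\left[\coth\frac{\hbar\omega}{2k_BT}\,(1-\cos\omega t)
+ i(\sin\omega t - \omega t)\right]d\omega$$
is evaluated with the OBO part in closed form (exponential plus a
200-term Matsubara series; the OBO correlation function decays only as
$1/\omega$ in frequency, which makes it hostile to quadrature) and the
mode part by trapezoid quadrature on a grid that resolves both the mode
widths and the fastest oscillation, renormalized so the modes'
reorganization energy is exact.  This gives $g(0)=\dot g(0)=0$ exactly
and the exact long-time slope $\mathrm{Im}\,\dot g \to -\lambda$.

Two spectral theories share this $g$:

* **Modified Redfield (secular).**  State $k$ absorbs with lineshape
  $\exp[-g_k(t)]$, $g_k = \sum_n C_{nk}^4 g_n$, damped by half its total
  depopulation rate from the standard modified-Redfield rate expression
  (diagonal exciton-bath coupling to all orders, off-diagonal to second
  order).  The rate integrand is assembled from lineshape tensors
  $g_{abcd}(t) = \sum_n C_{na}C_{nb}C_{nc}C_{nd}\,g_n(t)$ — fully
  index-symmetric here because fluctuations are site-diagonal and
  mutually uncorrelated (one spectral density per site, shared by
  default).  The implementation reproduces the Foerster
  donor-emission/acceptor-absorption overlap rate in the weak-coupling
  localized limit and near-Boltzmann detailed balance, both tested.
* **Matrix cumulant (non-secular, full-cumulant-expansion style).**
  The literature treats the full cumulant expansion for aggregates as a
  code rather than one canonical printed formula, so the package
  implements the standard second-order matrix cumulant:
  $U(t) = e^{-i\Omega t}\, e^{-K(t)}$ with
  $K_{kk'}(t) = \sum_{k''}\sum_n C_{nk}C_{nk''}^2C_{nk'}
  \int_0^t\!\!\int_0^{\tau}\! C_n(s)\,
  e^{i\omega_{kk''}s} e^{i\omega_{kk'}(\tau - s)}\,ds\,d\tau$ expressed
  through $g$ and $\dot g$ alone (integration by parts twice), so the
  monomer limit $K = g$ is *exact* on the shared time grid.  Off-diagonal
  and $k''\neq k$ terms carry the non-Markovian lifetime kernel and
  non-secular mixing.  The spectrum contracts $U(t)$ with
  $\boldsymbol\mu_k\cdot\boldsymbol\mu_{k'}$ (OD) or the cross-state
  rotational-strength matrix (CD).  Both theories reduce to the same
  monomer response and to sums of monomer responses at zero coupling;
  those two anchors, not any printed working equation, are the
  correctness contract.

Fluorescence uses Boltzmann-weighted emitting states with the
mirror-image emission lineshape $e^{-g_k^*(t)}$ shifted by $2\lambda_k$;
for a monomer this places the emission peak exactly mirror-symmetric to
absorption about $\varepsilon-\lambda$, so the peak-to-peak Stokes shift
is $2\lambda$ in the slow-modulation limit.  Motional narrowing erodes
this: at $\gamma_c = 53$ cm$^{-1}$ the peaks close in by tens of
cm$^{-1}$, which is physics, not error.  The Stokes-shift acceptance
check therefore uses a slow bath ($\gamma_c = 5$ cm$^{-1}$, a ~1 ps
correlation time appropriate for "slow environmental motions") and a
10 cm$^{-1}$ spectral grid.

Numerical choices: time grid 0–3 ps at 1 fs by default; half-Fourier
transform by trapezoid with a raised-cosine window over the final 20% of
the record; spectra carry no extra $\omega$ prefactor (arbitrary units),
which makes integrated OD exactly conserved between coupled and
uncoupled calculations; negative OD ripple beyond $10^{-6}$ of the peak
is an error, smaller ripple is clipped to zero.  The modified-Redfield
rate integral refuses (rather than truncates) a time grid on which the
integrand has not decayed to 5% of its maximum — weakly damped vibronic
coherences ring for picoseconds and are handled by the window, hence the
loose default.

# Static disorder: model and estimators

Static disorder is modelled as independent Gaussian site-energy
perturbations of width $\sigma$ (couplings untouched), averaged over
Monte-Carlo realizations; $\sigma = 100$ cm$^{-1}$, the value fitted
previously against experimental lineshapes, is the reference setting.
Averaging happens on time-domain response functions (the transform is
linear), which makes the 2000-realization monomer criterion cheap; the
monomer oracle is the homogeneous spectrum convolved with a Gaussian of
width $\sigma$.

Two estimators mirror the two sampling protocols of a dual classical/
quantum MD design (34 starting frames; 25 snapshots per frame for the
quantum trajectories, 850 samples per pigment):

* `disorder_from_opt`: sample SD across the 34 per-frame energies —
  converges to the slow (frozen) disorder $\sigma_s$.
* `disorder_from_bomd`: SD across the 34 per-trajectory means — biased
  upward to $\sqrt{\sigma_s^2 + \sigma_f^2/25}$ because each short
  trajectory retains $\sigma_f^2/25$ of fast-fluctuation variance.  This
  is exactly why short quantum-MD runs overestimate static disorder, and
  the generator-recovery tests verify the formula.

Sample ($n-1$) standard deviations are used throughout ($n = 34$ is
small).  Uniform shift fitting detects bands as local maxima above 5% of
the global maximum after smoothing with a fixed 30 cm$^{-1}$ Gaussian
kernel (a deterministic stand-in for visual band alignment) and the
least-squares rigid shift is the mean per-peak offset.

# Synthetic data: the stated world

`gen_site_energy_ensemble` draws per-frame baselines
$\mathcal N(\mu, \sigma_s^2)$ — frames 14 ns apart are effectively
independent — and within each frame an Ornstein-Uhlenbeck path with
stationary SD $\sigma_f$ and correlation time $\tau_c$, sampled by exact
conditional sampling (no Euler bias, so the lag-$k$ autocorrelation is
exactly $e^{-k\Delta t/\tau_c}$ in expectation).  Defaults: 34 frames,
25 snapshots, 20 fs spacing (500 fs of usable trajectory), and
$\tau_c = 5$ fs so successive snapshots decorrelate — the condition
under which the $\sqrt{\sigma_s^2+\sigma_f^2/25}$ decomposition holds.
Typical magnitudes used in fixtures ($\sigma_s \approx 100$,
$\sigma_f \approx 300$ cm$^{-1}$) match the scale of site-energy scatter
in polarizable-embedding excited-state calculations on bilins.

`gen_bilin_geometry` builds a bonded chain carrying the standard
tetrapyrrole atom names so that every topology-defined torsion is
realized exactly (bond 1.4 Å, angles 120°, unconstrained linkers anti);
it is a measurement fixture, not a chemically complete bilin.
`gen_phycocyanin_structure` assembles a small synthetic two-protomer
complex with the open (6 PCB + 2 DBV) or closed (4 PCB + 2 DBV + 2 MBV)
pigment complement, with a controllable protomer rotation.
`gen_antenna_fixture` wires an 8-site Hamiltonian whose central DBV pair
couples at 238 cm$^{-1}$ (closed) or 16 cm$^{-1}$ (open) — the two
printed reference couplings — with invented but magnitude-realistic
energies, dipoles (~13 D) and geometry.

What a green test does *not* establish: that real force-field or QM/MM
ensembles share the generator's Gaussian/OU statistics; that the
torsion topology table matches any particular crystal structure's atom
naming (the quadruples ship as an editable JSON config precisely so a
mismatch can be fixed without code changes); or that the CD intensity
scale is comparable between systems (shape only).

# Structural analyses

Torsions are IUPAC dihedrals mapped to the branch $(-90°, 270°]$ —
near-anti bridges are conventionally reported as 168–203° without
wrapping — with circular means and SDs ($\sqrt{-2\ln \bar R}$ in
degrees) so that ensembles straddling the ±180 cut average correctly.
Each methine bridge contributes two torsions, one per inter-ring bond,
via quadruples (N$_X$, C4$_X$, CH$_Y$, C1$_Y$) and (C4$_X$, CH$_Y$,
C1$_Y$, N$_Y$); DBV omits the saturated C–D bridge, giving its 4-entry
rows.  RMSF superposes every frame on an iterated mean structure
(least-squares Kabsch fit on C-alpha) and reports per-residue values;
superposition absorbs six rigid degrees of freedom, a ~1% downward bias
at these sizes.  The protomer rotation angle superposes two structures
on their first protomer and extracts the angle of the best-fit rotation
relating the second protomers from the rotation-matrix trace.

This environment has no access to the deposited crystal structures, so
every structural acceptance check runs on synthetic stand-ins labelled
as such; the ~73° open-closed rotation is treated as a constructed
recovery target, not a recomputed crystallographic value.

# Known limitations

* The non-secular cumulant uses the time-ordering-free prefactor form
  $e^{-i\Omega t}e^{-K(t)}$; it is exact for monomers and uncoupled
  aggregates and second-order accurate otherwise, but it is not the only
  defensible truncation.
* Modified-Redfield detailed balance is approximate (a property of the
  theory, not the code); deviations of a few percent from Boltzmann
  branching are expected.
* Fluorescence is secular in both theories (Boltzmann-weighted relaxed
  states), without excitation-frequency memory.
* CD intensities are arbitrary-units by construction; only band shapes
  and signs are comparable.
* The disorder model has no intersite correlation, consistent with
  per-site $\sigma$; correlated protein modes would need a covariance
  extension.
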