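---
title: "Dynamical refinement of continuous-rotation 3D electron diffraction data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical refinement of continuous-rotation 3D ED data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Continuous-rotation 3D electron diffraction (3D ED / MicroED) collects
diffraction frames from a nanocrystal while the goniometer rotates at
constant speed; each frame integrates the diffracted intensity over a small
angular interval $\Delta\alpha$ (typically a fraction of a degree).
Electrons scatter strongly, so a crystal a few hundred angstroms thick
multiply scatters the beam: measured intensities deviate non-linearly from
the kinematical expectation $I_\mathbf{h} \propto |F_\mathbf{h}|^2$, they
depend on thickness and orientation, and symmetry-equivalent reflections
are no longer equivalent. Refining a structure model against such data with
a kinematical target inflates the residuals, biases atomic positions and
drowns weak features (hydrogen atoms, guest molecules) in difference-map
noise. On the other hand, multiple scattering makes the intensities
sensitive to the handedness of a noncentrosymmetric crystal — information
that is absent from kinematical intensities, where Friedel mates are
exactly equal.

`dyned` implements a full dynamical treatment of continuous-rotation data:
data reduction into *overlapping virtual frames* (OVFs), Bloch-wave
calculation of integrated intensities, weighted least-squares refinement,
dual-enantiomorph comparison with a binomial $z$ statistic, and difference
electrostatic-potential (DESP) maps. A forward simulator of the whole
acquisition makes every stage testable with no external data.

# Data reduction: overlapping virtual frames

An experimental frame covers $[\alpha - \Delta\alpha/2, \alpha +
\Delta\alpha/2]$. Dynamical intensities of a *single* frame are impractical
to model (they depend on where inside the frame the reflection crossed the
Ewald sphere), so $N_F$ consecutive frames are grouped into a virtual frame
of angular range $\Delta\alpha_v = N_F\,\Delta\alpha$, characterized by the
average goniometer angle $\alpha_v$. Consecutive OVFs share $N_O$ frames
(default $N_O = N_F/2$), so that reflections whose rocking curve is cut by
one OVF boundary are measured intact on the neighbouring OVF. Observed
integrated intensities are plain sums of the per-frame intensities over the
contributing frames, with quadrature-summed uncertainties — no scale
factors and no Lorentz correction are applied on this path. The same
reflection on two OVFs gives two independent observations that are never
merged before refinement.

Reflections in exact diffracting condition near one of the two *limiting
Ewald spheres* (the sphere positions at $\alpha_v \pm \Delta\alpha_v/2$)
have truncated rocking curves. Two geometric filters exclude them: the
distance $D_{Sg}$ of the reciprocal-lattice point from the nearer limiting
sphere (measured along the sphere normal, i.e. the excitation-error
magnitude at the extreme orientations) must satisfy $D_{Sg} \ge
D_{Sg}^{min}$, and the ratio

$$R_{Sg} = \frac{|S_g|}{D_{Sg} + |S_g|}$$

must satisfy $R_{Sg} \le R_{Sg}^{max}$, where $S_g$ is the excitation error
at $\alpha_v$. Defaults: $D_{Sg}^{min} = 0.002\ \mathrm{Å^{-1}}$ (useful
range 0.0015–0.0030) and $R_{Sg}^{max} = 0.65$ (useful range 0.5–0.8,
default at the midpoint). Tightening $R_{Sg}^{max}$ from 0.8 to 0.5 can
only shrink the included set; the suite tests this monotonicity.

# The Bloch-wave engine

Conventions (any self-consistent set is acceptable; this one is validated
against the closed-form two-beam solution to $10^{-8}$):

* Lab frame: beam axis $z$, incident wavevector $\mathbf{k} = (0,0,-K)$
  with $K = 1/\lambda$; the relativistic wavelength comes from CODATA
  constants ($\lambda = 0.025079$ Å at 200 kV).
* Excitation error $S_g = (K^2 - |\mathbf{k}+\mathbf{g}|^2)/(2K)$, positive
  inside the Ewald sphere.
* Potential coefficients $U_g = \gamma_{rel} F_g / (\pi V_c)$ in
  $\mathrm{Å^{-2}}$, with $F_g$ the kinematical structure factor (electron
  form factors from the packaged 5-Gaussian parameterization of Peng et
  al. 1996, Debye–Waller factor $\exp(-8\pi^2 U_{iso} s^2)$, phase
  convention $F_\mathbf{h} = \sum f_j \exp(+2\pi i\, \mathbf{h}\cdot
  \mathbf{r}_j)$).
* Structure matrix $A_{gg} = 2KS_g$, $A_{gh} = U_{g-h}$; no absorption, so
  $A$ is Hermitian and total intensity is conserved to $10^{-10}$
  (tested). Eigendecomposition $A = C\Gamma C^\dagger$ and
  $\psi_g(t) = \sum_j C_{gj}\, e^{i\pi\gamma_j t/K_n}\, C^*_{0j}$ with
  $K_n = K$: the crystal is a parallel-sided block normal to the beam, so
  the surface normal coincides with the beam axis at every orientation.
  Thickness $t$ is measured along the beam.

Beam selection uses a dual cutoff: $|\mathbf{g}| \le g_{beam}$ and $|S_g|
\le s_{beam}$ (defaults 0.9 and 0.012 $\mathrm{Å^{-1}}$), with a
deterministic ordering (transmitted beam first, then by $|S_g|$, then
lexicographic) and a hard cap that errors with advice to tighten the
cutoffs. Bethe perturbation corrections for weak beams are deliberately
not implemented; the cutoffs are free parameters with documented defaults.

## Reflection passes and rocking-curve integration

A *pass* is one traversal of a reflection through the Ewald sphere: the
maximal contiguous run of frames on which $|S_g|$ stays below the recording
cutoff. The beam set of a pass is selected once, at the exact Bragg
crossing orientation (located by bisection), and held fixed while the
rocking curve is sampled across the pass; only the diagonal of $A$ changes
between orientations. This reflection-centric convention makes the forward
model identical wherever it is evaluated — in particular, the bundled
simulator and the refinement engine produce *exactly* the same integrated
intensities for the same parameters, which is what makes noiseless
round-trip tests meaningful at $10^{-6}$ and below.

Model integrated intensities are trapezoidal integrals of the rocking curve
over the observation's angular range, with the angle in radians — the same
convention in which the experimental counts are summed, so observed and
calculated intensities differ only by the per-OVF scale. The integration
support is the recorded sub-range of the OVF (the OVF frames that lie on
the reflection's pass): for the vast majority of observations this is the
full OVF range, and for boundary observations it matches the support of the
experimental sum exactly. The quadrature grid uses $m$ sub-intervals per
frame (default $m = 4$, about 20 orientations per 4-frame OVF and well
within the "dozens" regime; doubling the density changes fixture integrals
by less than 0.1%).

One caveat documented here because it constrains configurations: the
recording cutoff `S_record` must exceed the largest $|S_g|$ that a
filter-included observation can reach inside its OVF window, which is about
$3.2\, g_{res} \Delta\alpha_v/2$ (in radians) for $R_{Sg}^{max} = 0.65$.
The default (0.045 $\mathrm{Å^{-1}}$) satisfies this for the default
resolution and OVF width.

# Least-squares refinement

The refinement minimizes $\sum w (I_{obs} - I_{calc})^2$ with $w =
1/\sigma^2$ and $\sigma$ floored at $0.01\times$ the median $\sigma$
(weighting is not specified by the method itself; this is a standard
choice). Parameters: fractional coordinates and $U_{iso}$ per independent
atom, one thickness per data set, one scale per virtual frame (frames with
fewer than three included observations keep a fixed scale), optionally one
global $U_{iso}$ (the quick absolute-structure mode) and, on the
kinematical path, a one-parameter extinction attenuation
$E(x) = (1 + x I_{kin})^{-1/2}$.

The solver is a damped Gauss–Newton: derivatives by central finite
differences ($10^{-4}$ fractional for coordinates, $10^{-4}\ \mathrm{Å^2}$
for $U$, 1 Å for thickness; scale derivatives are analytic since the model
is linear in them, and thickness derivatives share the eigensystems of the
base evaluation, so they are nearly free), step halving while the wR would
increase, abort after three consecutively failed iterations, convergence at
max $|\mathrm{shift}/\mathrm{esd}| < 0.01$ (or a relative wR improvement
below $10^{-9}$, which catches the noiseless fixed point where the
esd-based criterion is meaningless). Esds come from the inverse normal
matrix scaled by the goodness of fit. The normal equations are solved by
SVD with column scaling; directions below $10^{-8}$ of the leading singular
value are truncated pseudoinverse-style. This matters for the kinematical
path: intensity-only kinematical least squares has a floating-origin null
space at the symmetric configuration (three near-zero singular values in
P2~1~2~1~2~1~), which dynamical intensities remove — truncation handles the
former without disturbing the latter. A parameter with no leverage at all
raises an error naming it.

Initial thickness and scales: a grid search over thickness
(100–2000 Å, 20 steps; all thickness values share one eigen-pass) with
per-OVF scales set to $\sum I_{obs} / \sum I_{calc}$, followed by one
least-squares cycle over scales and thickness only, with the structural
model fixed.

Riding hydrogens are regenerated every iteration from the parent's current
geometry: the H sits at the target distance (plus an optional offset
$\Delta l$) along the negative resultant of the parent's covalent bond
directions (idealized tetrahedral/trigonal completion), with $U_{iso}(H) =
1.2\, U_{iso}(\mathrm{parent})$. Reference distances per bond class are the
neutron-derived values (C–H 1.083 Å, N–H 1.009 Å, O–H 0.983 Å). Because
the hydrogen position is a pure function of the heavy-atom geometry, a
perturbed refinement can recover the simulation truth exactly; the
$\Delta l$ scan (`hydrogen_distance_scan`) then probes the apparent
bond-length offset, with the minimum located by a parabola through the
grid minimum.

## Kinematical comparison paths

Two kinematical modes are provided. The *classic* path mirrors conventional
processing: rotation-method Lorentz correction ($L = 1/|dS/d\alpha|$;
reflections traversing the sphere too slowly have a finite window integral
even though the point-speed factor diverges, so $L$ is capped at 50x its
median), per-frame scales optimized from the Laue-group means,
pre-refinement merging with
$\sigma(\bar I) = \sqrt{\sum(I-\bar I)^2/(n(n-1))}$
(the propagated input sigma is used at $n = 1$ or for identical
equivalents), then least squares on $I = s\,E(x)\,|F|^2$. The *frame-based*
path fits $I = s_v\,E(x)\,|F|^2 L$ against exactly the same filtered OVF
observations as the dynamical refinement, so the dynamical/kinematical
comparison sees identical data.

Merging of symmetry equivalents on the dynamical path happens only *after*
refinement (dynamical intensities of equivalents are not expected to be
equal): observed and calculated intensities are divided by their OVF scale,
grouped by Laue orbit, and averaged; R-factors of the merged values are the
MR-factors.

## Virtual-frame orientation corrections

Each OVF may carry two small correction rotations about the lab axes
normal to the beam. With the structural model fixed they are optimized by a
Nelder–Mead simplex (standard coefficients: reflection 1, expansion 2,
contraction 0.5, shrink 0.5) on that OVF's wR within ±0.5°; since each
OVF's objective is minimized independently from the zero start, the total
wR cannot increase. The corrections are *not* refined during
dual-enantiomorph comparisons: they are conditioned on the assumed
handedness and would absorb part of the signal being tested.

# Absolute structure

Both enantiomorphs (the model and its inversion through the origin, with
the space group replaced by its enantiomorphic partner where one exists —
the eleven pairs such as P6~1~22/P6~5~22 are built in) are refined
independently against the same data, filters and options; this is
equivalent to fixing a Flack parameter at 0 or 1. Two stages mirror
practice: `initial` refines only per-OVF scales, one thickness and one
global $U_{iso}$ (for unrefined solution models), `refined` also refines
coordinates and displacement parameters with riding hydrogens.

The assignment statistic counts, over the $N$ included observations with
unequal absolute residuals, the number $k$ for which enantiomorph 1 fits
better ($|I_{calc,1}-I_{obs}| < |I_{calc,2}-I_{obs}|$; exact ties are
excluded from both $k$ and $N$). Under the null, $k$ is binomial with
$p = 1/2$. The expected number of comparisons decided by experimental noise
alone is

$$w = \sum_i \left[ 1 - \Phi\!\left( \frac{|I_{calc,1} - I_{calc,2}|}
{2\sigma(I_{obs})} \right) \right],$$

and the adjusted score is $z = (2k - N)/\sqrt{N - w}$ with assignment
probability $\Phi(z)$. The unadjusted score and the exact binomial tail are
reported alongside. The magnitude-weighted variant (how much better one
model fits) is deliberately not implemented; ignoring it keeps the estimate
conservative. For multi-crystal input the statistic is also partitioned per
data set. A result with $|z| < 3$ (or a centrosymmetric model, where
inversion is a symmetry operation and the comparison is meaningless) is a
null result, flagged with its own exit code on the command line.

The null calibration test draws two candidate predictions symmetrically
perturbed about a common truth with noisy observations — the literal
"identical models" case produces only ties — and verifies that the
unadjusted $z$ is standard normal over 500 trials.

# Difference potential maps

After refinement, $|F_{obs}|$ is estimated per merged reflection by
$|F_{calc}|\sqrt{\bar I_{obs}/\bar I_{calc}}$ (observed amplitudes are not
directly available on the dynamical path; this standard rescaling estimate
is a documented choice), phases come from the model, and

$$\Delta V(\mathbf{r}) = \frac{1}{V_c} \sum_\mathbf{h}
\left(|F_{obs}| - |F_{calc}|\right) e^{i\varphi_{calc}}
e^{-2\pi i\, \mathbf{h}\cdot\mathbf{r}}$$

is evaluated by FFT on a grid with at least 4 voxels per Å, symmetry-
completed over the full sphere by computing $F_{calc}$ directly for every
orbit image (so the map carries the space-group symmetry by construction).
$F_{000}$ is omitted, hence the zero mean. The noise level
$\sigma[\Delta V]$ is the RMS voxel value over the full cell (identical to
the asymmetric-unit RMS for a symmetric map). Peaks are 26-neighbourhood
local maxima above $n\sigma$, localized by per-axis quadratic interpolation
and merged under symmetry; a fixed-width histogram export (default bin
0.0033 e/Å) supports noise-distribution comparisons.

# The simulator and what passing tests mean

`simulate_experiment` emulates a continuous-rotation acquisition on a
block crystal: frames of width $\Delta\alpha$ (default 0.5°) over a
rotation range (default 100°), dynamical per-frame intensities integrated
with the same pass machinery as the refinement, a smooth sinusoidal
per-frame scale drift (default ±10%), optional per-frame misorientations,
and Poisson-plus-Gaussian noise with reported
$\sigma = \sqrt{g I + \sigma_{add}^2 + (\sigma_{rel} I)^2}$ (the relative
component models multiplicative error sources and is the knob used for the
"2%/5% noise" experiments). The seed fully determines the output.
Fixtures: an invented chiral C/N/O molecule with riding hydrogens in
P2~1~2~1~2~1~ (6x8x10 Å), a quartz-like SiO~2~ framework in P3~2~21
(reproducing the 3~2~ screw absences kinematically), and a centrosymmetric
organic fragment in P2~1~/n. All coordinates are synthetic; no real
compound's structure is claimed.

What the simulator does *not* model — detector point spread, mosaicity and
crystal bending, beam damage, inelastic scattering, shape-transform
effects — bounds what green tests demonstrate: they validate the
reduction/refinement machinery and its statistical behaviour under the
stated noise model, not the full error budget of a real experiment. The
discrimination margins on synthetic data (e.g. wrong-hand R-factor ratios
well above the ~1.13 typical of experiments) are correspondingly larger
than real ones.

Test problem sizes (documented as the package's own choices): the recovery
and enantiomorph batteries use a 9–10° range at 1.7 Å resolution (about
300–450 filtered observations on 8–9 virtual frames, beam sets of ~15
beams), 20 seeded replicates each; the map experiments use a 16° range at
1.0 Å resolution. The kinematical-limit check runs on the quartz-like
fixture at $t = 0.02\,\xi_{min}$ with beam selection restricted so each
pass is effectively two-beam: the kinematical limit is a two-beam
statement, while multi-beam (Bethe-type) couplings shift some intensities
by a thickness-independent relative amount — a real physical effect (it is
what makes "kinematically absent" reflections visible) that no thickness
reduction removes; with multi-beam sets the *median* agreement still sits
within 2%.

# Known limitations

* No absorption/inelastic channel (Hermitian potential only) and no
  thickness-distribution shape functions.
* Beam selection has no Bethe perturbation treatment of weak beams.
* The Flack-type inversion-twin fraction is not refined; absolute structure
  is assigned by the dual-refinement statistic only, which applies to
  enantiopure crystals.
* Riding hydrogens use idealized single-H placement per parent; multiple
  hydrogens on one parent would be placed degenerately.
* The classic kinematical path caps diverging Lorentz factors instead of
  profile-modelling slow traversals.
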