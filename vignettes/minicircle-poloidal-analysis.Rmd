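---
title: "Measuring poloidal orientation in DNA minicircles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring poloidal orientation in DNA minicircles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poloidal)
```

## The problem

A DNA duplex shorter than ~150 bp, ligated end-to-end, forms a minicircle.
Base-pair-step bending is anisotropic and sequence-dependent, so the
circle does not sample all rotational registers of the helix about its own
axis equally: it prefers a *poloidal orientation*, with a particular
helical face turned toward the circle centre. This package implements the
computational machinery needed to quantify that bias from coarse-grained
minicircle trajectories and from AFM images of marker-protein/minicircle
complexes, together with synthetic-data generators that provide exact
ground truth for every estimator.

## Geometry construction

An ideal linear duplex is generated from six helical trajectories, one per
atom type (sugar, phosphate, base on each strand):

$$x_{i,n} = r_i \cos(n\,\Delta\theta + \theta_{i,0}),\quad
  y_{i,n} = r_i \sin(n\,\Delta\theta + \theta_{i,0}),\quad
  z_{i,n} = n\,\Delta z + z_{i,0}.$$

The shipped default table (`default_helix_parameters()`) is a
canonical-B-form stand-in: rise 3.4 Å, 10.5 bp/turn, sugar radius 9.2 Å,
phosphate radius 9.7 Å, base radius 4.0 Å, with the strand-2 angular
offsets 150° from strand 1 so the backbones delimit distinct major (210°)
and minor (150°) grooves, and phosphates trailing their sugar by half a
step. These values set the absolute geometry only; every downstream
statistic in the package is either parameter-free arithmetic or calibrated
against the generated reference circle, so reasonable changes to the table
move no test target. The inverse operation, `derive_helix_parameters()`,
recovers the table from an axis-aligned reference duplex by cylindrical
averaging over all base-pair indices; on ideal input the round-trip is
exact to 1e-6, and averaging over `n` means a perturbation of one site
moves the recovered parameters by less than the perturbation itself.

**Closure-compatible twist.** A covalently closed duplex must hold an
integer number of helical turns. `choose_circle_twist()` therefore adjusts
the step twist to $\Delta\theta = \mathrm{Lk}\cdot 360/N$ with
$\mathrm{Lk} = \mathrm{round}(N/h)$, $h = 10.5$ bp/turn by default: for a
105-bp circle, Lk = 10 and $\Delta\theta = 34.286^\circ$; for 90 bp,
Lk = 9 and $36^\circ$. The target twist is exposed as a parameter for
studying over/under-wound constructions, but closure always snaps the
total twist to full turns.

**Bending.** The molecule is translated so its geometric centre (unit
site masses — the translation only places the circle centre) sits at
$(0, R, 0)$ and each cross-section is rotated rigidly about the x-axis by
its arc angle: $(x, y, z) \mapsto (x,\, y\cos(z/R),\, y\sin(z/R))$. The
map preserves x and each site's distance from the bending axis exactly,
and is length-preserving on the $y = R$ centreline; sites inside/outside
the centreline are compressed/stretched along the arc, which is precisely
the physical bending strain. With the default
$R = N\,\Delta z/(2\pi)$ the arc closes after one circumference and the
seam bond length matches the intra-circle backbone bond length to ~2%.
A radius smaller than the backbone helix radius would fold sites through
the bending axis; this raises a `singular transform` error naming the
offending site (relevant for circles below ~20 bp at B-DNA rise, where an
explicit larger radius must be supplied).

**Topology closure.** The open duplex carries class-labelled bonded terms
(no force-field parameters — running dynamics is out of scope). Along each
strand's 5′→3′ order the 5′-terminal phosphate is left unbonded: it is the
free 5′-phosphate that ligation consumes. Closing the circle then adds,
per strand, exactly the seam terms a contiguous double helix needs: bonds
SP, PS, BB; angles SPS, 5PSB3, 3PSB5; dihedrals two SPSP, two PSPS and one
each of SPSB53, SPSB35, PSBB53, PSBB35 — six bonds, six angles and sixteen
dihedrals in total for any N ≥ 3, after which the closed molecule holds 8N
bonds, 6N angles and 12N dihedrals. The dihedral patterns are named in the
coarse-grained model's literature but their site assignments are not
drawn; the rules used here are the unique chemically sensible quadruples
consistent with those labels and are fixed by the unit tests.

## The poloidal angle

For a tracked nucleotide, four strand-1 phosphates are selected: P0 at the
tracked index and P1/4, P1/2, P3/4 at offsets $\mathrm{round}(Nk/4)$
(mod N), k = 1..3 (nearest-integer rounding; for N = 105 and tracked
index 0 this selects nucleotides 0, 26, 52, 79). The body frame is

* $\hat x$: unit vector from P0 toward P1/2 — pointing *into* the circle;
* $\hat z$: the P1/4→P3/4 chord, Gram–Schmidt-orthogonalized against
  $\hat x$ (the raw chords are not exactly perpendicular in distorted
  frames);
* $\hat y = \hat z \times \hat x$.

The origin O is the projection, onto the $\hat x$–$\hat y$ plane through
P0, of the centroid of all S/P/B sites of the 10 bp centred on the
tracked nucleotide (offsets −5..+4, both strands; P0, the 5′ phosphate of
the tracked nucleotide, sits at the segment midpoint). Then

$$\varphi = \mathrm{atan2}\big((P_0 - O)\cdot\hat y,\; (P_0 - O)\cdot\hat x\big),
\qquad x = (P_0 - O)\cdot\hat x,$$

with $\varphi$ in degrees wrapped to (−180, 180]. Sign conventions,
stated once and used everywhere: positive $x$ means the phosphate lies
inside the minicircle, so $\varphi = 0$ is the innermost register and
$\varphi = 180^\circ$ the outermost; $x = |P_0 - O|\cos\varphi$ holds
identically. The construction uses only internal coordinates, so both
quantities are invariant under rigid rotations and translations of the
frame (tested to 1e-6°). Degenerate geometry (coincident P0 and P1/2, or
P0 within 1e-6 Å of O) raises an error rather than returning an
arbitrary angle.

**Known anisotropy of the estimator.** On the ideal circle the 10-bp
segment spans ~34° of arc, so its centroid lies
$R\,(1 - \mathrm{sinc}(a/2)) \approx 0.8$ Å inside the centreline. The
origin O is therefore displaced radially, and the measured angle is the
polar angle about a slightly offset centre: as the tracked index advances
around the circle, the per-step advance oscillates by up to ~±4° about
the step twist, cancelling exactly over a full circuit (the mean rate is
$\mathrm{Lk}\cdot 360/N$ per bp to numerical precision). This smooth
modulation is inherent to the segment-centroid origin; tests assert the
mean rate within 2° and bound the modulation at 6°. For per-frame
statistics at a *fixed* tracked nucleotide — the estimator's actual use —
the modulation is a fixed, invertible remapping of the angle scale and
does not accumulate.

**Circular statistics.** With unit vectors $(\cos\theta_j, \sin\theta_j)$,
$\bar R$ is the mean resultant length, $\mu$ the direction of the mean
vector and $\sigma = \sqrt{-2\ln\bar R}$ the circular SD (reported in
degrees). $\bar R < 10^{-12}$ (no preferred direction) raises an
undefined-mean error. Burn-in removal defaults to 5 ns, the time
poloidal-angle distributions typically need to equilibrate in
coarse-grained runs; mean-centred histograms rotate by $-\mu$ before
binning over (−180, 180].

## Fixed-period phase fitting

Insert-position series (offset distance δ from AFM, or inverted
horizontal displacement −x from simulations, summarized per position)
are fitted with the period held at the helical repeat T = 10.5 bp:
$v_j = A\cos(2\pi(p_j - p_0)/T) + C$. Because T is fixed, the problem is
exactly linear in $(a, b, C)$ with $a = A\cos(2\pi p_0/T)$,
$b = A\sin(2\pi p_0/T)$, and is solved by weighted linear least squares —
deterministic, order-invariant, no starting values. The peak position is
reported mod T in [0, T). At least four positions are required (three
free parameters); a zero spread with weighting enabled is an error rather
than an infinite weight.

"Weighted by the standard deviation" admits two readings; inverse
variance ($1/\sigma_j^2$, the standard least-squares convention) is the
default and inverse SD is available (`weighting = "inverse-sd"`); with
equal spreads both reduce to the unweighted fit. Phase lags are reported
as $(p_{0,b} - p_{0,a}) \bmod T$ in bp and as $\mathrm{lag}/T \times 360$
degrees — a 5.5-bp lag at T = 10.5 is 188.57°, displayed as 189°. A
sequence repeating every u bp leaves a perfect circle invariant under a
poloidal rotation of $u \cdot 360/h$ (34.3° for a homopolymer, 68.6° for
a dinucleotide repeat at h = 10.5): distributions constrained by such
symmetry repeat at that angle and, when the repeats overlap, blur toward
uniformity.

## AFM image analysis

Height maps are matrices of heights in nm with a pixel size in nm/px;
pixel coordinates are 0-based at pixel centres, origin top-left, and all
reported distances are converted to nm via the pixel size.

* **Flattening** removes tilt and bow per scan line: a polynomial of
  order ≤ 2 is fitted to each row's background pixels — those below the
  row's 75th height percentile, so molecules do not bias the fit — and
  subtracted across the row. On a pure polynomial background the output
  is exactly zero; in molecule-dense synthetic scenes residuals stay
  below ~0.1 nm, small against the 0.35-nm segmentation threshold.
* **Segmentation** thresholds the flattened image, labels connected
  components (EBImage), discards sub-4-pixel noise specks, and fills
  holes so a ring mask becomes the solid connected mask on which the
  offset distance is defined — the ring interior must count toward the
  centroid.
* **Classification** applies, in order: area > `area_max` → aggregate
  (e.g. circular dimers, excluded); area < `area_min` → lone protein;
  mean height < `intensity_min` → lone DNA; else complex. The manual
  confirmation step of real analyses is modelled as a `confirmed` flag
  (FALSE → rejected). Default thresholds (30/150 nm², 0.85 nm) bracket
  the synthetic generator's feature statistics; thresholds for real data
  are configuration, not defaults, since they depend on tip, buffer and
  deposition.
* **Offset distance** $\delta = |r_\mathrm{centroid} - r_\mathrm{COM}|$:
  unweighted versus height-weighted mean of the same filled-mask pixels.
  COM weights use flattened heights with negative values clipped to zero
  (raw heights would let background curvature leak into the weights).
  δ vanishes for any radially symmetric molecule, grows monotonically as
  the marker blob moves from ring centre to rim, and is invariant to
  translation and 90° rotation to within a pixel.
* **Relative affinity** $\alpha = N_{DP}/(N_D N_P)$ from the class
  counts of one scan; proportional to an association constant under the
  assumption that surface counts mirror solution concentrations. α is
  concentration-dependent by construction — duplicating a scan halves it
  — so only ratios between scans taken under matched conditions are
  meaningful.

## Synthetic data: what it emulates, and what it does not

`make_poloidal_trajectory()` draws one angle per frame from a von Mises
distribution (mean μ*, concentration κ; κ = 0 uniform; an optional
two-component mixture emulates bimodal landscapes such as phased-adenine
repeats) and applies the corresponding rigid poloidal rotation to the
ideal circle by shifting all six angular offsets. Because the estimator
has its own zero point and the smooth anisotropy described above, the
generator calibrates the rotation→measured-angle map once on the
noiseless reference circle (1° grid, monotone interpolation) and inverts
it per frame, so the *measured* poloidal angle of frame *i* equals the
drawn ground-truth angle to better than 1e-3°. Recovery tests are
therefore limited only by sampling error: at 5,000 frames the circular
mean and SD are recovered within 2° for means spanning the circle and
SDs of 18–35°.

The model deliberately contains no bending fluctuations, no twist or
writhe dynamics, no kinks and no time correlation between frames: passing
recovery tests demonstrates the estimator chain (frame axes → angle →
circular statistics), not the physics of any particular force field.
Likewise `make_afm_scene()` composes Gaussian tubes (rings, apparent
radius defaulting to 2 nm), Gaussian blobs (4 nm peak height versus
0.7 nm for rings — globular protein images much taller than DNA), per-row
polynomial background and white noise; it has no tip convolution, no
feathered molecule edges and no correlated scan-line noise, so real-data
thresholds will differ. Ground-truth δ is computed by brute-force pixel
sums on each molecule's noiseless image, a code path independent of the
analysis pipeline. Sequence-series constructs (85-nt random core + 20-nt
insert with a marked dT, insert slid in 2-nt steps) are labelled random
stand-ins: the experimentally used sequences are not public.

All generators take explicit seeds, never touch the caller's RNG stream,
and are bit-reproducible.

## Numerical choices and degenerate inputs

* Angles are degrees in the API, radians internally, wrapped to
  (−180, 180] with a half-open floor wrap.
* Quarter-phosphate offsets use base R `round()` (round-half-even), which
  reproduces the reference offsets {0, 26, 52, 79} for N = 105.
* The von Mises sampler is the Best–Fisher (1979) rejection algorithm;
  $\sigma(\kappa) = \sqrt{-2\ln(I_1(\kappa)/I_0(\kappa))}$ uses scaled
  Bessel functions below κ = 1e4 and the asymptotic expansion above, and
  `vonmises_kappa()` inverts it by root-finding.
* Fits and summaries fail loudly on degenerate input (fewer than 4
  positions, zero spreads under weighting, vanishing resultant length,
  empty burn-in remainder, already-closed topology) instead of returning
  NA.
* Problem sizes in the tests and the acceptance script — 5,000-frame
  trajectories, 400–500-px scenes with ≤ 73 molecules, 1,000 Monte-Carlo
  replicates — were chosen so each estimator's sampling error sits well
  inside the tolerance it is tested against.

## Limitations

The geometry builder is sequence-labelled but geometrically uniform: it
encodes no sequence-dependent intrinsic curvature, so it cannot *predict*
a poloidal preference — prediction requires dynamics, which is explicitly
out of scope. The default helix-parameter table is a documented B-DNA
stand-in, not a fitted coarse-grained parameter set. The AFM module does
not parse vendor file formats, trace DNA contours or deconvolve tip
shape; and the mapping from a tracked phosphate's poloidal angle to the
position of a linker-attached marker protein is left unmodelled, as the
linker's length and flexibility make that relationship uncertain.
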