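---
title: "Ring geometry, hinge motions and complex composition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring geometry, hinge motions and complex composition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringstat)
```

# Scientific setting

Microtubules (MTs) are nucleated from γ-tubulin ring complexes
(γ-TuRCs): ring-shaped assemblies in which γ-tubulin molecules, carried
on spokes of GCP-family proteins (Spc97/Spc98 in fungi), present a
helical template onto which α/β-tubulin dimers polymerise. Whether a
given ring is an *efficient* template is largely a geometric question:
a "closed" ring exposes its γ-tubulins on the same helical lattice as
the 13-protofilament MT it seeds, while "open" conformations deviate
from it. This package provides the quantitative toolbox around that
question for atomic models of such assemblies: helical lattice
estimation and comparison, rigid-body superposition and domain-hinge
RMSD, interface-contact classification, hydrogen-exchange (HX-MS)
protection statistics, and densitometry-based stoichiometry — plus
synthetic-data generators with exact ground truth for every stage.

# The helical lattice model and its estimator

## Model

Anchors are one labelled point per spoke, in ring order. The
conventional anchor for γ-tubulin rings is the Cα of Gln12 of each
γ-tubulin copy (for an MT reference lattice, Gln15 of each α-tubulin);
any residue/atom rule can be supplied. An ideal helical lattice places
spoke $k = 0, \dots, N-1$ at

$$p_k = o + r\,(\cos(\phi_0 + k\,\Delta\theta)\,e_1 +
\sin(\phi_0 + k\,\Delta\theta)\,e_2) + (z_0 + k\,\Delta z)\,u$$

with axis direction $u$, origin $o$, radius $r$ (Å), twist
$\Delta\theta$ (degrees/spoke) and rise $\Delta z$ (Å/spoke).

## Axis fitting

`fit_axis()` estimates four parameters — two direction angles and two
in-plane origin offsets (the origin component along $u$ is immaterial)
— by minimising

$$\mathrm{Var}(r_i) + \mathrm{Var}(\Delta z_i),$$

the variance of the point–axis radial distances plus the variance of
the per-step rise. Both terms vanish on an ideal lattice. The radial
term alone is the classical objective, but it does not identify the
axis for small rings: with five anchors, several distinct axes can be
*exactly* equidistant from all points (four constraints, four degrees
of freedom, multiple discrete solutions — easy to verify numerically),
and for wide shallow arcs its valley is extremely flat. The rise term
uses the one extra piece of information a lattice fit legitimately has
— anchors are supplied in ring order — and removes both problems
without affecting the noise-free optimum. Adding a twist-uniformity
term as well would be circular (angles require the axis) and proved
unnecessary.

Initialisation is deterministic: each of the three principal components
of the centred anchors is tried as a starting direction, paired with an
in-plane origin from the algebraic (Kåsa) circle fit of the projected
points, refined with `nlminb` (relative tolerance $10^{-15}$), then
re-centred on the circle fit at the refined direction and polished
once more; the best of the three refined starts wins. On noise-free
lattices across radii 20–150 Å, twists 10–40°, rises 0–15 Å and 5–20
spokes this recovers the generating parameters to better than
$10^{-5}$ (see the test suite, which asserts exactly that grid).

The direction sign is fixed so the mean per-step rise is non-negative;
for exactly planar rings (zero rise) the sign is arbitrary and either
is accepted.

## Lattice parameters and their summaries

With the axis fixed, each anchor gets cylindrical coordinates
$(r_i, \theta_i, z_i)$. Summaries follow the descriptive conventions of
structural tables:

* **Radius** is summarised over all $N$ anchors.
* **Twist and rise** are summarised over the $N-1$ successive steps —
  for a 14-spoke ring, 13 steps, which is also how a reported
  "n = 13" for a 14-spoke ring is reconciled here. Step angles are
  wrapped into (0°, 360°) assuming spokes advance monotonically in one
  rotational sense (the rotational sense itself is taken from the sign
  of the summed raw steps); spokes must therefore be supplied in ring
  order, which is why the interface takes an explicit ordered chain
  list rather than assuming alphabetical chain naming.
* **SD** is the population standard deviation (divisor $n$): these are
  descriptive spreads of a fixed lattice, not standard errors of an
  estimate — consistent with a fixed reference lattice being quoted
  with an SD of 0.0. (Sample SD would differ by $\sqrt{n/(n-1)}$,
  about 4% at $n=13$.)
* **Handedness** is right when the ring rotates positively about the
  axis oriented along increasing rise.

`compare_lattices()` reports per-parameter absolute differences and
flags two lattices *compatible* when every difference is at most the
sum of the two SDs. This is deliberately a descriptive criterion, not
a hypothesis test: it operationalises "indistinguishable at the
reported precision" for tables quoting mean ± SD, and it reproduces
the published ring-vs-MT comparison (differences 0.7 Å, 0.0°, 0.4 Å —
compatible) from the printed values alone. The reference MT lattice
(101.8 ± 0.1 Å, 27.6 ± 0.0°, 9.6 ± 0.1 Å) ships as
`microtubule_13pf_params()`.

```{r}
ring <- make_ring(n_spokes = 14, radius = 102.5, twist = 27.6,
                  rise = 9.2, noise_sd = 1.0, seed = 11)
fit <- helix_fit(ring$model, chains = ring$chains)
compare_lattices(fit, microtubule_13pf_params())
```

# Superposition, domain RMSD and element displacement

`kabsch_superpose()` is the standard SVD least-squares rigid
superposition with the determinant correction to exclude reflections.
Cα atoms are paired by (chain, residue number, insertion code);
residues modelled in only one structure are dropped silently but
counted in the result — deposited models routinely have unmodelled
gaps, and pairing by identity rather than position keeps the measure
well-defined.

`domain_rmsd(a, b, sel, align_sel = sel)` superposes on `align_sel`
and measures RMSD over `sel` *without re-fitting*. The default (align
and measure on the same domain) gives the single per-domain number
conventionally quoted for conformational changes; passing a static
domain as `align_sel` measures how far the domain of interest moved in
the static frame — the natural readout for a hinge motion, and the one
with a closed-form value for a generated rigid hinge
($2\sin(\alpha/2)$ times the RMS perpendicular distance from the hinge
axis, asserted to $10^{-9}$ in the tests).

`displacement_after_alignment()` reports the distance between Cα
centroids of two measured elements after aligning shared elements.
Centroid distance (not per-residue RMSD) is used because the measured
elements need not pair residue-for-residue — comparing the CM1 helices
of different receptor orthologs in a shared frame is exactly such a
case — and because centroids are robust to differing modelled lengths.
The residue ranges of aligned and measured elements are always
explicit inputs: published figures rarely state them precisely enough
to hard-code.

# Interface contacts

Deposited cryo-EM models carry no hydrogens and papers name contact
pairs, not geometries, so classification is by heavy-atom distance
only, with defaults hbond ≤ 3.5 Å (donor/acceptor N/O), salt bridge
≤ 4.0 Å (side-chain N of Lys/Arg, optionally His, against side-chain
carboxylate O of Asp/Glu), hydrophobic ≤ 4.5 Å (C–C between apolar
side chains: Ala, Val, Leu, Ile, Pro, Phe, Met, Trp). Each atom pair
receives one label with precedence salt bridge > hydrogen bond >
hydrophobic, so reports are deterministic; hydrogen bonds between two
backbone N/O atoms are flagged `hbond_backbone_backbone` separately
from side-chain-mediated ones. Histidine's inclusion as a salt-bridge
donor is switchable (`his_salt_bridge = FALSE`). No angle screening,
buried-surface area or energy scoring is attempted — with distance-only
criteria those would suggest precision the inputs do not have.
`pocket_contacts()` applies the hydrophobic criterion from one probe
residue's side-chain carbons and reports the partner residue set, the
"pocket".

# HX-MS protection statistics

Peptide-level deuterium uptake is corrected for back-exchange with the
two-control formula $(m_t - m_0)/(m_{100} - m_0)$, clamped to [0, 1]
with raw values retained. Protection induced by a ligand is expressed
relative to the fraction that was exchanging at baseline:

$$\text{relative exchange} = 100\,\frac{\text{ligand}}{\text{baseline}},
\qquad
\text{relative protection} = 100\,\frac{\text{baseline} -
\text{ligand}}{\text{baseline}},$$

so full protection scores 100%, unchanged exchange 0%, and
deprotection is negative; the two always sum to 100 when baseline
exchange is positive. This scale makes regions with very different
baseline dynamics comparable — its purpose — but is unstable when the
baseline barely exchanges, hence the display filter: peptides with
baseline exchange below 10% are flagged `shown = FALSE` ("a minimum of
10%" is read as ≥ 10, inclusive, and the boundary is tested). Records
are only flagged, never deleted, and the filter is idempotent.

Documented choices where conventions vary: peptides observed in
several charge states are averaged (unweighted mean of centroid
masses, per condition) *before* correction — centroid masses are
deconvolved peptide masses, so averaging before or after the linear
correction differs only when controls differ between charge states; a
single labelling time point is assumed (kinetic modelling is out of
scope); peptides are identified by their residue span (start, end,
sequence). `residue_consolidation()` averages relative exchange over
all shown peptides covering each residue — the standard flattening for
structure colouring, exported via `set_bfactor()` +
`write_structure()` into the temperature-factor column.

# Stoichiometry from densitometry

Coomassie-type stain signal scales with protein mass, so intensity
divided by molecular weight is proportional to moles.
`molar_ratios()` computes per-replicate ratios
$(I_i/\mathrm{MW}_i)/(I_\mathrm{ref}/\mathrm{MW}_\mathrm{ref})$ and
summarises across replicates with the *sample* SD (divisor $n-1$):
unlike the lattice SDs these are few independent experiments, and
mean ± sample SD is the reporting convention for biological
replicates. Molecular weights are user-supplied construct masses
(tags included), never recomputed from database sequences — a
His-tagged fragment on a gel is not its UniProt entry. Ratios are
invariant to per-replicate scaling, so gels need no common exposure.

# Synthetic data: what it emulates and what it does not

Each generator is deterministic under its seed (one global seed is
split into per-component streams; the caller's RNG state is restored)
and returns its exact ground truth.

* `make_ring()` — anchors on an ideal helical lattice, one CA-only
  single-residue chain per spoke (Gln 12, matching the default anchor
  rule), optional rigid pose, isotropic Gaussian coordinate noise.
  Defaults are the closed-ring study conditions: 14 spokes, 102.5 Å /
  27.6° / 9.2 Å. For study-condition realisations the tests use
  noise sd 1.0 Å, a realistic coordinate scatter consistent with the
  reported per-parameter spreads (1.5 Å / 0.7° / 0.8 Å) — those
  spreads are not exactly isotropic, so no single sd reproduces all
  three; 1.0 Å was chosen once on that reasoning and not revisited.
* `make_hinge_pair()` — a smooth 3.8 Å-step Cα walk; model B rotates
  the mobile block about a hinge through the last static residue.
  Closed-form mobile-block RMSD is returned as truth.
* `make_hx_tables()` — centroid masses constructed so noise-free
  corrected uptake equals prescribed baseline/protection profiles
  exactly (about one exchangeable amide per residue), Gaussian mass
  noise optional.
* `make_gel()` — intensities $\propto$ ratio × MW with lognormal
  multiplicative noise (CV parameterised) and arbitrary per-replicate
  scale; defaults emulate a 1:1:2:2 Spc97:Spc98:γ-tubulin:receptor
  complex with realistic construct masses (91, 98, 52.5, 69 kDa).

What passing on synthetic data does and does not show: the generators
produce ideal lattices, rigid hinges and exactly-constructed uptake —
they validate the estimators' correctness, identifiability and noise
behaviour, not their robustness to real-data pathologies (anisotropic
model error, EX1 kinetics, staining nonlinearity, mis-ordered chains).
Analyses of deposited structures exercise the same code paths via
`read_structure()`, but reproducing published numbers from deposited
coordinates requires those files and is not part of the test suite.

# Numerical choices and degenerate inputs

* Axis fit: `nlminb`, relative tolerance $10^{-15}$; three
  deterministic starts; collinear or coincident anchors are rejected
  (second singular value below $10^{-8}$ of the first); fitting needs
  at least 4 anchors, parameter summaries at least 3.
* Kabsch: plain `svd`; fewer than 3 paired points or length mismatch
  are errors; reflections excluded by the determinant correction.
* Contacts: all-pairs distances are computed in one matrix product;
  zero-distance (self) pairs are excluded; reported distances are
  recomputable from the coordinates to $10^{-6}$ Å (tested).
* Structure IO is backed by bio3d (`read.pdb`, `read.cif`,
  `write.pdb`): first MODEL only, altloc "A" or blank kept, PDB
  column precision $10^{-3}$ Å, B-factors two decimals. Hydrogens,
  waters and HETATM records are read but excluded from geometric
  defaults.
* Test problem sizes: lattice-recovery grid of 36 parameter
  combinations plus 100-seed noise ensembles; 80+80-residue hinge
  pairs; 19-peptide exchange tables; 3-replicate gels. These sizes
  make every ground-truth comparison exact or tightly bounded while
  keeping the whole suite fast.

# Known limitations

* The lattice fit assumes one monotone rotational sense; rings
  supplied out of ring order give meaningless twists (the chain order
  is the user's assertion).
* The compatibility flag is descriptive, not inferential; with spreads
  estimated from a single noisy ring it is marginal when true
  differences are comparable to the spread (the tests therefore assert
  a majority over independent realisations, alongside the exact
  printed-value comparison).
* Distance-only contact criteria over-count hydrogen bonds relative to
  angle-aware definitions; the defaults are recovery-oriented, not a
  bond-validity claim.
* HX-MS handling is single-time-point and peptide-level; no spectral
  processing, replicate statistics or kinetic modelling.
* mmCIF support covers the `atom_site` loop (author numbering), not
  assemblies, symmetry expansion or sequence records.
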