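# ringstat

Quantitative structural analysis of helical protein ring assemblies,
built around the γ-tubulin ring complex (γ-TuRC) — the 14-spoked ring of
γ-tubulin small complexes (γ-TuSCs) that templates microtubule
nucleation in fungi. The package is for structural biologists who have
atomic models of such assemblies (plus the surrounding biochemistry:
hydrogen-exchange mass spectrometry and gel densitometry) and want the
standard quantitative readouts reproducibly, from R.

## What it computes

**Ring geometry.** The central question for a nucleation template is
whether its lattice matches the microtubule it seeds. Given one anchor
point per spoke (conventionally the Cα of Gln12 of each γ-tubulin copy),
`helix_fit()` estimates the helical axis and the lattice parameters

- radius *r* (distance of anchors to the helical axis, Å),
- twist Δθ (rotation per spoke, degrees),
- rise Δz (pitch increment per spoke, Å),

reported as mean ± SD (radius over all N anchors; twist and rise over
the N−1 successive steps). The axis is fitted by nonlinear least squares
minimising var(*r*) + var(Δz) — both vanish on an ideal helix — with
principal-component starts and an algebraic circle-fit origin.
`compare_lattices()` flags two lattices as compatible when every
parameter difference is within the sum of the two SDs; the reference
13-protofilament microtubule lattice (101.8 ± 0.1 Å, 27.6 ± 0.0°,
9.6 ± 0.1 Å, anchored at Gln15 of α-tubulin) ships as
`microtubule_13pf_params()`.

**Conformational changes.** `kabsch_superpose()` (SVD least squares),
`domain_rmsd()` (per-domain Cα RMSD, optionally measured in the frame of
a separate alignment domain — how hinge motions between GRIP1 and GRIP2
domains are quantified) and `displacement_after_alignment()` (centroid
shift of an element, e.g. a CM1 helix, after aligning shared elements).

**Interfaces.** `find_contacts()` enumerates inter-chain heavy-atom
contacts and classifies them (salt bridge > hydrogen bond > hydrophobic,
distance cutoffs 4.0 / 3.5 / 4.5 Å); `pocket_contacts()` reports the
hydrophobic pocket around a probe residue such as a docking
phenylalanine.

**HX-MS protection.** `uptake_fraction()` applies the two-control
back-exchange correction (m_t − m0)/(m100 − m0); `protection_table()`
scores ligand-induced protection relative to the baseline-exchanging
fraction (full protection = 100%), flags peptides under 10% baseline
exchange, and `residue_consolidation()` maps peptides to residues for
structure colouring via `set_bfactor()`.

**Stoichiometry.** `molar_ratios()` converts gel band intensities to
molar ratios via molecular-weight normalisation, (I/MW)/(I_ref/MW_ref),
mean ± SD across replicates.

**Synthetic data.** `make_ring()`, `make_hinge_pair()`,
`make_hx_tables()` and `make_gel()` generate all of the above with known
ground truth, so every stage is testable without downloading deposited
models.

## Worked example

Fit the lattice of a synthetic 14-spoke ring generated at the closed,
microtubule-compatible geometry (radius 102.5 Å, twist 27.6°, rise
9.2 Å, 1 Å coordinate scatter) and compare it to the 13-protofilament
microtubule reference:

```r
library(ringstat)

ring <- make_ring(n_spokes = 14, radius = 102.5, twist = 27.6,
                  rise = 9.2, noise_sd = 1.0, seed = 11)
fit <- helix_fit(ring$model, chains = ring$chains, residue = 12, atom = "CA")
summary(fit)
#> helical lattice parameters (14 points, 13 steps)
#>   radius:   102.25 +/- 0.59 Angstrom
#>   twist :    27.66 +/- 0.68 degrees/spoke
#>   rise  :     9.10 +/- 0.99 Angstrom/spoke
#>   handedness: right
#> residuals vs ideal lattice: RMS 1.289 Angstrom, max 2.096 Angstrom

compare_lattices(fit, microtubule_13pf_params())
#>  parameter   query reference difference sd_sum compatible
#>     radius 102.247     101.8    0.44695 0.6949       TRUE
#>      twist  27.658      27.6    0.05773 0.6805       TRUE
#>       rise   9.099       9.6    0.50148 1.0911       TRUE
#> => lattices are compatible (all |diff| <= SD_query + SD_ref)
```

The recovered parameters reproduce the generating lattice within the
per-step spread, and the ring is flagged indistinguishable from the
microtubule lattice — the geometric signature of a
nucleation-competent, closed ring. The same fit on a deposited
structure is one call: `helix_fit(read_structure("ring.pdb"),
chains = c(...ordered γ-tubulin chains...))`.

Complex composition from densitometry:

```r
gel <- make_gel(cv = 0.05, n_replicates = 3, seed = 11)
molar_ratios(gel$bands, "Spc97")
#> molar ratios relative to Spc97 (mean +/- sample SD, N = 3 replicates)
#>   Spc97           1.00 +/- 0.00
#>   Spc98           1.05 +/- 0.08
#>   gTub            2.02 +/- 0.19
#>   Spc72           2.05 +/- 0.09
```

recovering the 1:1:2:2 Spc97:Spc98:γ-tubulin:Spc72 stoichiometry of the
oligomeric complex.

A command-line interface wrapping the same functions is in
`inst/cli/ringstat.R` (subcommands `geometry`, `rmsd`, `shift`,
`contacts`, `hxms`, `stoich`, `simulate`); see `?ringstat_main`.

## Vignette

`vignettes/ring-geometry-and-composition.Rmd` describes the models,
estimators, numerical choices and limitations in detail.
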