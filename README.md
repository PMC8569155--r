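# capsidkit

Geometry, assembly and mass analysis of prolate and isometric bacteriophage
capsids, in R.

Tailed phages package their genomes into preformed procapsids built from a
major capsid protein (CP) on a quasi-equivalent lattice of pentamers and
hexamers, with a portal replacing one pentamer. Some phages build *prolate*
heads — two icosahedral end caps joined by a cylindrical hexamer midsection —
and some mobile genetic elements ("pirate" elements such as the
staphylococcal pathogenicity islands) redirect that choice: a pirate-encoded
CP homolog that preferentially occupies the pentamer positions forces
assembly into a small *isometric* shell that cannot hold the helper genome.
capsidkit is for structural virologists and phage biologists who want the
desk-scale mathematics and models around this phenomenon as reusable,
tested code:

* **Lattice accounting** — Caspar–Klug triangulation numbers
  `T = h² + hk + k²`, prolate midsection numbers
  `T_mid = h₁h₂ + h₁k₂ + h₂k₁ + k₁k₂` (a.k.a. `Q`), capsomer and subunit
  censuses with portal substitution (`30(T_end + T_mid) − 5` CP copies for
  a portal-bearing head), and the inverse problem (which architectures
  explain an observed census).
* **3D capsomer lattices** — explicit centre/normal/adjacency models of
  isometric shells (net projected onto the circumscribing sphere) and
  five-fold prolate shells (icosahedral caps + rolled hexagonal tube), with
  ring partitions, helical rise/twist, pentamer-to-pentamer lattice paths,
  inter-capsomer dihedral angles, and CSV/PDB export.
* **Assembly-decision simulation** — a seeded stochastic model of the
  pentamer-species choice (CP → prolate, homolog → isometric) with a
  closed-form oracle.
* **Intact-mass tools** — average-mass arithmetic, cleavage-site mapping
  from deconvoluted intact masses (scaffolding/delta-domain boundaries),
  and SDS-PAGE apparent-MW calibration from marker ladders.
* **Structure comparison** — global sequence alignment, Kabsch
  superposition and iterative core-RMSD trimming for capsid-protein
  subunits.
* **Synthetic data** — deterministic generators (with ground truth) for
  every input the analyses consume, so the whole pipeline is testable
  offline.

## Worked example: the prolate ϕ12-type head

The end caps are walked by `(h₁,k₁) = (2,0)` and the midsection by
`(h₂,k₂) = (7,0)`, with a portal at the bottom vertex:

```r
library(capsidkit)

arch <- architecture_counts(lattice_vectors(2, 0, 7, 0), has_portal = TRUE)
arch
#> capsid architecture: prolate, T_end = 4, T_mid (Q) = 14
#>   11 pentamers + 1 portal, 80 hexamers, 535 CP-equivalent subunits

lat <- build_prolate_lattice(lattice_vectors(2, 0, 7, 0), portal = TRUE)
lat
#> capsomer lattice: prolate, T_end = 4, T_mid = 14, a = 110.85 A
#>   92 capsomers (hexamer: 80, pentamer: 11, portal: 1), 270 adjacencies

helical_params(lat)
#> helix: 6 rings of 10 hexamers, rise 96.00 A, twist 18.000 deg, tube radius 176.4 A

shortest_pentamer_path(lat)$hexamer_count
#> [1] 7
```

Read: a `T_end = 4` cap / `T_mid = 14` midsection head carries 535 copies
of CP (the portal replaces a pentamer and contributes none) in 80 hexamers
and 11 pentamers; the tube is six rings of ten hexamers offset by 18°, and
with the default lattice constant (110.85 Å, back-derived from the 96 Å
ring rise) the rings rise 96 Å per turn. Seven hexamers separate the lowest
pentamer from the topmost one.

The size-redirection decision, at equal pentamer propensities:

```r
out <- simulate_assembly(assembly_params(rho_ccm = 1, n_trials = 20000, seed = 7))
outcome_summary(out)
#>       shape     n fraction     ci_lo     ci_hi mean_cp mean_ccm
#> 1 isometric 10053  0.50265 0.4957207 0.5095782     180       55
#> 2   prolate  9947  0.49735 0.4904218 0.5042793     535      0
```

Isometric outcomes are `T = 4` shells whose 11 pentamers are the homolog
(55 copies) over 30 CP hexamers (180 copies); prolate outcomes are the
all-CP 535-copy head. The fraction tracks the closed form
`analytic_isometric_fraction()` (here ρ/(1+ρ) = 0.5).

See `vignette("capsid-geometry-and-redirection")` for the model
conventions, parameter meanings and limitations.

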