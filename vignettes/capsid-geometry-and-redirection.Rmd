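---
title: "Prolate capsid geometry, size redirection and mass mapping: methods"
author: "capsidkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prolate capsid geometry, size redirection and mass mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidkit)
```

# The scientific setting

Tailed bacteriophages build their heads from one major capsid protein (CP)
arranged on a quasi-equivalent lattice of pentamers and hexamers. Some
phages build *prolate* heads: two icosahedral end caps joined by a
cylindrical midsection of hexamers. Mobile genetic elements that parasitize
a helper phage can redirect this choice — a pirate-encoded CP homolog that
preferentially occupies the pentamer positions forces the shell to close
with constant curvature into a small *isometric* capsid, too small for a
full phage genome. capsidkit implements the desk-scale mathematics and
models around this phenomenon: lattice accounting, explicit 3D capsomer
models, a stochastic decision simulator, intact-mass cleavage mapping for
the scaffolding (delta) domains, gel calibration, and rigid-body
superposition of subunit models.

# Lattice accounting

An isometric shell is classified by the Caspar–Klug triangulation number
$T = h^2 + hk + k^2$, where $(h, k)$ is the lattice walk between adjacent
five-fold vertices; a $T$ shell has $60T$ subunits in 12 pentamers and
$10(T-1)$ hexamers. A five-fold prolate head carries a second number
$T_{mid}$ (also written $Q$) for the elongated midsection,

$$T_{mid} = h_1 h_2 + h_1 k_2 + h_2 k_1 + k_1 k_2,$$

and the closed shell has $30\,(T_{end} + T_{mid})$ subunits. A portal
replaces one pentamer and contributes no CP copies, hence the
$30(T_{end}+T_{mid}) - 5$ accounting for a portal-bearing head:

```{r}
arch <- architecture_counts(lattice_vectors(2, 0, 7, 0), has_portal = TRUE)
arch
```

Two accounting subtleties are deliberate:

* The four-term $T_{mid}$ product does not reduce to $T$ for doubly chiral
  vectors (e.g. $(1,1,1,1)$ gives 4, not 3). The degenerate case
  $(h_2,k_2)=(h_1,k_1)$ *is* an isometric shell, so `q_number()` returns
  $T(h_1,k_1)$ there; this keeps the invariant "isometric total $= 60T$"
  for every cap vector while using the product formula for genuinely
  prolate lattices (where all printed examples have $k_1 = 0$ and the two
  conventions coincide).
* The highest possible pentamer:hexamer ratio of a $T=4$ shell is
  $12:30$, from $10(T-1)$; a ratio of $12:20$ sometimes quoted for $T=4$
  is inconsistent with subunit conservation and is not reproduced.

`enumerate_architectures()` inverts the accounting: which $(T_{end}, Q)$
explain an observed subunit or hexamer census. The tube seam constrains
achievable midsections to $Q$ a multiple of $h_1 + k_1$, so fewer pairs are
realizable than the formula alone suggests. The brute-force bound (default
component $\le 20$) is configurable.

# The 3D capsomer lattice

`build_prolate_lattice()` constructs the shell in three parts:

* **Caps.** Each end cap is the five-sector wedge of the icosahedral net
  around an apex ($T_{end}=h_1^2$; achiral caps, $k_1 = 0$). Capsomer
  centres are mapped barycentrically onto the cap pyramid and projected
  radially onto the cap sphere, whose radius $R_s = R_t/\sin(\arctan 2)$
  reproduces icosahedral-vertex geometry while meeting the tube at the
  junction ring. Dihedral angles are scale-invariant, so cap environments
  equal those of a free isometric shell built with
  `build_icosahedral_lattice()`.
* **Midsection.** A hexagonal lattice rolled so that the circumference is
  $5 h_1$ hexamer spacings ($R_t = 5h_1 a/2\pi$) and the junction pentamer
  rings are $h_2 + k_2$ lattice rows apart; $k_2$ skews the top ring
  azimuthally ($k_2=0$ is the achiral stacked-ring tube). Successive rows
  sit $a\sqrt3/2$ apart and are staggered by half a spacing, which is the
  entire content of the helical "rise and twist": with $n$ hexamers per
  ring, twist $=360/(2n)$ degrees exactly.
* **Adjacency** is derived in the flat net (with the cone seam of the caps
  identified), not from the curved embedding, so pentamer degree 5 /
  hexamer degree 6 hold exactly and all graph quantities are independent
  of projection choices and rigid motions.

The default lattice constant 110.85 Å is back-derived from the 96 Å ring
rise measured for the ϕ12-type midsection via
$a = 2\,\mathrm{rise}/\sqrt3$; it is a default, not an independent claim,
and the rise check in the tests is a consistency check of the
construction, not a reproduction.

```{r}
lat <- build_prolate_lattice(lattice_vectors(2, 0, 7, 0), portal = TRUE)
helical_params(lat)
```

## Conventions and degenerate inputs

* Frame: five-fold axis $= +z$; the portal occupies the bottom apex.
* Regions: the junction rings (5 pentamers + 5 hexamers each for
  $h_1=2$) belong to the caps — this is what makes the census come out as
  10 cap hexamers per cap and 60 midsection hexamers for the $(2,0,7,0)$
  head. Isometric
  shells have no midsection label at all (a sphere has no cylinder), so
  `ring_partition()` returns zero rings for them.
* Ring clustering tolerance: $0.25\times$ rise, configurable; a ring of
  unexpected size is a hard error, signalling a malformed lattice.
* Dihedrals: capsomer planes are perpendicular to the stored outward
  normals; coplanar $=180°$, sharper fold smaller. Under this convention
  the 12 vertex-tangent planes of a $T=1$ shell bound a dodecahedron, so
  adjacent pentamer planes meet at $180° - \arccos(1/\sqrt5) = 116.57°$
  (the dodecahedral dihedral); the icosahedral *face* dihedral
  ($138.19°$) is a different quantity and is not what this operation
  measures.
* Doubly chiral caps ($k_1 > 0$) have no consistent achiral tube seam in
  this construction and are rejected with a geometry error.

## The pentamer-to-pentamer path

The ϕ12-type head is usually described as having seven hexamers along the
shortest lattice path from a bottom pentamer to a top pentamer. That count
needs a convention, because climbing the $h_2 = 7$ lattice rows between
the junction rings passes only the six interior hexamer rings. `shortest_pentamer_path()` therefore takes as
default endpoints the axially lowest and highest *pentamers* of the shell:
with a portal at the bottom apex the lowest pentamer is on the bottom
junction ring and the highest is the top apex, and the shortest path (ties
resolved toward fewest hexamers, then smallest ids) passes exactly 7
hexamers for the $(2,0,7,0)$ head and 14 for a doubled $(2,0,14,0)$ tube.
For isometric shells there is no axial extreme worth naming; explicit
`from=`/`to=` endpoints give the adjacent-pentamer separation (one hexamer
on a $T=4$ shell).

# The assembly-decision model

The redirection observation is strictly either/or: capsids are prolate or
small-isometric, with intermediates rare. The simulator models the
decision, not the kinetics: after a portal/hexamer nucleus forms, each
pentamer site independently draws the pirate homolog (Ccm) with probability
$q = \rho/(1+\rho)$, where $\rho$ (`rho_ccm`) is the relative incorporation
propensity — a free parameter; no biological value is asserted. Two
commitment rules ship:

* `first_site` (default): the first pentamer's species decides — this
  matches the observed absence of intermediates.
* `unanimous_ring`: the five first-ring sites must agree; mixed draws give
  an "aberrant" particle. With $\rho = 1$ this yields exactly
  $1/32, 1/32, 30/32$ for isometric/prolate/aberrant.

Committed particles take the full census of their architecture: isometric
$T=4$ with Ccm pentamers and CP hexamers; prolate all-CP. Portal-free
nucleation (isometric shells can form without a portal) exposes 12 pentamer
sites instead of 11; prolate heads are always given a portal, mirroring the
observation that prolate procapsids invariably contain one. The closed form
`analytic_isometric_fraction()` is kept separate from the simulator so the
two can be compared as implementation and oracle.

```{r}
p <- assembly_params(rho_ccm = 1, n_trials = 2e4, seed = 7)
outcome_summary(simulate_assembly(p))
```

# Intact-mass cleavage mapping

HK97-type capsid proteins carry their scaffolding function as an
N-terminal delta domain that is proteolytically removed during maturation.
A deconvoluted intact mass of the mature protein therefore pins the
cleavage site: `match_cleavage()` scans contiguous fragments (default:
N-terminal truncations retaining the C-terminus) for average-mass matches
within a tolerance (default $\pm 2$ Da, the scale of typical intact-mass
deviations), and `delta_domain_report()` converts a match into the
delta/mature partition. Average (not monoisotopic) masses are used,
cysteines reduced, no modifications modelled — matching how ESI-TOF intact
masses are reported. Because the smallest residue weighs 57 Da, N-terminal
truncation matches are unique at sub-Dalton tolerance, which the tests
exercise on 100 random planted-cleavage proteins.

The ϕ12 CP and SaPIbov5 Ccm sequences themselves are not bundled: they are
external data to be retrieved from public sequence or structure
repositories. All shipped fixtures are synthetic and labelled as such; the
planted boundaries in the tests use the known delta-domain positions
(cleavage after residue 128 of a 402-residue CP-like protein, after 87 of
a 355-residue Ccm-like protein) so the machinery is exercised at exactly
the relevant problem shape.

Gel calibration follows the standard ladder practice: a least-squares
quadratic of $\log_{10}(MW)$ on migration distance (direct prediction; the
reverse direction is available behind `direction=`), with apparent MW
$=10^{poly(d)}$.

# Superposition and core RMSD

`superpose()` is a plain Kabsch fit (SVD of the cross-covariance with
reflection correction) on alpha-carbon coordinates; `align_sequences()`
(global, BLOSUM62, gap 11/1) supplies correspondences between homologs.
`core_rmsd()` iteratively discards pairs deviating more than a cutoff
(default 3.8 Å, about one CA–CA bond) and refits; pairs shed early may
rejoin when they fit the settled transform, and when a hard prune would
discard most pairs (two comparably sized rigid blocks), only the worst
decile is shed so the fit can settle onto one block deterministically.
This mirrors the common reporting of a small "core" RMSD for the conserved
fold next to a much larger all-pair RMSD driven by rearranged arms and
loops. The cutoff and iteration cap are package defaults, documented as
such — the corresponding published core-selection procedures are typically
unstated, so published core/all RMSD values are treated as qualitative
corroboration, not exact targets.

# What the synthetic generators do and do not show

Every generator is seeded, deterministic, and emits its ground truth:
noisy capsomer clouds on ideal shells, random proteins with planted
cleavages, ladders on known quadratics, structure pairs under known rigid
transforms. Passing recovery tests at zero noise shows the estimators are
exact inverses of the generators; moderate-noise tests show robustness
margins (e.g. 3 Å positional noise against a 110.85 Å lattice constant).
What they cannot show: real density maps yield capsomer centres with
correlated, non-isotropic error; real proteins are not uniform-random in
composition; real gels deviate from quadratic migration. Conclusions about
real specimens still require the real measurements.

# Problem sizes

The shipped tests build shells up to a few hundred capsomers (components
$\le 5$), run the decision simulator at $10^5$ trials per parameter point,
and use 100 planted-cleavage replicates — sizes chosen so the full suite
completes in about a minute while leaving the statistical assertions
(binomial agreement within $4\sigma$) well-powered.
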