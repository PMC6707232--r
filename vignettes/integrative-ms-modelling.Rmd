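---
title: "Integrative cross-linking and HDX-MS modelling with xlhdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative cross-linking and HDX-MS modelling with xlhdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlhdx)
```

## The problem

Large multi-subunit assemblies such as Cullin-RING ligase/COP9-signalosome
complexes are routinely solved at intermediate resolution, leaving flexible
domains (a winged-helix domain, a conjugated ubiquitin-like protein, a
substrate receptor) without interpretable density. Two mass-spectrometric
measurements complement the maps:

* **Cross-linking MS (XL-MS)** identifies residue pairs that were close in
  solution. A lysine-reactive BS3 cross-link is interpreted as an
  upper-bound distance restraint: two lysine side chains (15 Å), the BS3
  spacer (10 Å) and a 10 Å allowance for domain flexibility give the
  conventional **35 Å Cα–Cα threshold**.
* **Hydrogen-deuterium exchange MS (HDX-MS)** reports per-peptide uptake of
  deuterium, a probe of local structure. Comparing two states peptide by
  peptide (ΔHDX) maps binding interfaces and allosteric responses; titrating
  a ligand and following uptake (PLIMSTEX) turns the same signal into a
  local dissociation constant.

`xlhdx` implements the computational layer of such a study: coarse-grained
placement of mobile rigid bodies under cross-link restraints, restraint
satisfaction and two-conformer ensemble analysis, PLIMSTEX binding fits, and
blanket-interval significance classification of differential uptake — plus a
synthetic-data generator that produces every input with known ground truth.

## Cross-link restraints and satisfaction

Cross-links are unordered residue pairs with an upper bound: experimental
links default to 35 Å; pseudo-links encode covalent topology — 5 Å for chain
continuity across a dissected domain boundary, 10 Å for an isopeptide
attachment (7.5 Å lysine side chain plus ~3 Å glycine C-terminus), and a
configurable bound (default 35 Å) for interface-integrity links that hold an
adaptor subcomplex together. Distances are measured Cα–Cα (bead–bead): the
35 Å budget already contains the side-chain geometry, so no side-chain
modelling is attempted.

Conventions chosen where the field is loose:

* **Boundary**: distance equal to the bound counts as *satisfied*
  (configurable). The published threshold itself should pass.
* Links with an endpoint absent from a model are reported as *unmapped* and
  never silently dropped; satisfied + violated + unmapped always equals the
  table size.
* The **exclusive-satisfaction test** partitions a link set against two
  conformers at a common bound. Non-empty exclusive sets on both sides mean
  no single rigid structure explains the data — evidence that both
  conformations are sampled in solution.

## Monte-Carlo rigid-body placement

`mc_place()` minimises

$$ S = w_v \sum_r \max(0,\, d_r - b_r)^2 \; + \; w_e \sum_{i<j} \max(0,\, R_i + R_j - d_{ij})^2 $$

over rigid poses of the mobile bodies: a harmonic upper-bound violation term
over restraints and a soft-sphere excluded-volume term between EV spheres of
different bodies (consecutive groups of `ev_resolution` residues; sphere
radius conserves summed bead volume, \(R = 3.5\,n^{1/3}\) Å). The functional
form is an interpretation — integrative-modelling platforms default to
penalties of this family — with both weights defaulting to 1 and
configurable.

The defaults follow the published parametrisation: 1000 outer iterations of
`num_mc_steps = 10` Metropolis steps (read as an outer × inner loop, 10,000
proposals in total), `rb_max_trans = 2` Å per component, `rb_max_rot = 0.1`
rad, EV resolution 20, temperature 1 (no annealing). `bead_max_trans = 0.5`
is retained for configuration compatibility but inactive: bodies are fully
rigid here, flexible-bead moves are out of scope. Moves rotate each mobile
body about its centroid (uniform axis, angle uniform up to the cap) and
translate it componentwise; acceptance is Metropolis at fixed temperature;
the best-scoring model ever visited is returned, so the best-so-far
trajectory is non-increasing by construction. Mobile bodies start at their
input coordinates; runs are exactly reproducible given `seed`.

### What upper-bound restraints can and cannot localise

A satisfied-everywhere ("score zero") region exists around any feasible
pose, and its size is set by the restraint slack. A link of true length
$d$ under bound $b$ tolerates $b - d$ of motion along the link vector but
roughly $\sqrt{2d(b-d)}$ perpendicular to it — for $d \approx 30$ Å under
$b = 35$ Å that is ~17 Å. Consequently a handful of 35 Å links localises
even a covalently tethered domain only to within roughly 5–15 Å, and the
best model returned by any sampler is one essentially arbitrary member of
that feasible set. Placement results from this class of data should be read
at domain resolution, not residue resolution; the acceptance script reports
the measured centroid error distribution on synthetic instances rather than
assuming a tighter accuracy.

## The synthetic generator

`make_toy_complex()` builds protein-like bodies as self-avoiding bead
chains (3.8 Å Cα spacing). Stationary bodies sit on a jittered circle
(default centroid spacing 22 Å); each mobile body is grown as a **chain
continuation** of a stationary host — its first bead one Cα step beyond the
host's last bead — because that is how dissected mobile domains relate to
their scaffold, and the junction is exported as a covalent-tether topology
entry. Start models displace each mobile body by a recorded random
transform (default 15 Å translation, up to 90° rotation), comparable to the
domain-scale motions such experiments probe.

`simulate_crosslinks()` draws true links from inter-body residue pairs with
ground-truth distance in the upper part of the allowed window (default
85–100% of `max_dist = 30` Å), stratified along the mobile chain and across
partner bodies. Links near the distance budget are the informative ones — a
10 Å link under a 35 Å bound excludes almost nothing — and spreading
attachment points gives the restraints a lever arm on orientation, as
surface lysines linking a domain to several neighbours do. Decoys, when
requested, are drawn uniformly regardless of distance and flagged in the
truth record. Endpoints are drawn from all residues rather than lysines
only; the restraint mathematics is residue-agnostic.

`simulate_titration()` reproduces the published design: receptor fixed at
250 nM, ligand at molar ratios 0/0.1/0.5/1/2 (or 5), triplicate Gaussian
noise (default SD 0.05 Da, a typical peptide-level replicate spread).
`simulate_hdx_tables()` tiles a protein with overlapping peptides (lengths
8–16 within the usual 5–30 window, 5-residue stride), gives each a
saturating-exponential baseline uptake (rates 10⁻³–10⁻¹ s⁻¹ — qualitative
exchange kinetics; the differential analysis is insensitive to the baseline
shape), and adds region-localised shifts to the bound state at the standard
design of three exposures (15/300/1800 s) in triplicate.

What the generator does **not** emulate: peptide-level back-exchange,
spectral overlap, EX1 bimodality, correlated replicate error, non-lysine
cross-link chemistry, and conformational heterogeneity of the stationary
scaffold. Passing recovery tests therefore demonstrate correctness of the
computations, not robustness to every pathology of real data.

## PLIMSTEX fitting

Predicted uptake at total ligand $L$ is $D_0 + \Delta D \cdot f(L)$ with
$f = [PL]/P_{tot}$ from the **exact 1:1 mass-balance quadratic**

$$ K_a [PL]^2 - \big(K_a (P_{tot} + L) + 1\big) [PL] + K_a P_{tot} L = 0, $$

taking the physically admissible root. The hyperbolic excess-ligand
approximation is deliberately not used: at 250 nM receptor against
nanomolar affinities, ligand depletion is material. The root is evaluated
in the conjugate form $2 P L / (b + \sqrt{b^2 - 4 P L})$, which is free of
the cancellation the textbook form suffers at weak binding.

`fit_plimstex()` runs bounded Levenberg–Marquardt least squares over
$(D_0, \Delta D, \log_{10} K_a)$, with $K_a \in [10^3, 10^{12}]$ M⁻¹,
started from the zero-ligand mean, the uptake span, and a Kd at the middle
titrated concentration. Fitting is unweighted by default, matching a plain
RMS-residual quality measure; inverse-variance weighting is available. A
fit is flagged **unidentifiable** (Kd reported as `NA`) when the fitted
$|\Delta D|$ is below twice the pooled replicate SD or $K_a$ ends on an
optimiser bound; non-convergence is reported through a flag, never an
error. Multi-peptide tables are fitted per peptide and summarised as a
min–max Kd range over identifiable fits, mirroring range-style reporting of
local affinities.

## Differential HDX classification

For each peptide and exposure shared by two states,
$\Delta = \bar u_{bound} - \bar u_{apo}$ with propagated
$s_\Delta = \sqrt{s^2_{bound} + s^2_{apo}}$. The significance filter is a
**blanket confidence interval** per timepoint: $0 \pm DU$ with

$$ DU = z_{level} \cdot s_{pool} \sqrt{1/n_1 + 1/n_2}, $$

where $s^2_{pool}$ pools the replicate variances of both states across
*all* peptides of the timepoint and $z_{0.98} \approx 2.326$ (a Student-$t$
quantile is available as an option). Records are classified *stabilised*
($\Delta < -DU$), *destabilised* ($\Delta > +DU$) or *non-significant*;
the comparison is strict, a value exactly on the interval boundary being
null-consistent. Uptake values are never corrected for back exchange.
Per-timepoint classification is primary; an aggregation to one call per
peptide (significant in ≥1 timepoint, conflicts reported as mixed) is
provided as an explicit interpretation.

Under the generator's null the classifier is calibrated by construction:
$\Delta \sim N(0, \sigma^2(1/n_1+1/n_2))$ while
$DU \to z \sigma \sqrt{1/n_1+1/n_2}$ as the peptide count grows, so the
expected significant fraction approaches $1 - level$. The test suite checks
this empirically (binomial test at the 2% nominal rate) together with
near-certain detection of injected effects at ten times the noise SD.

## Geometry

Superposition is the standard Kabsch/SVD solution with the determinant
correction, so a reflection is never returned; degenerate (collinear or
under-determined) inputs are errors rather than silent garbage.
`rmsd_between()` aligns two models on one selection's Cα atoms and measures
RMSD over another without re-fitting — the idiom used to quantify how far a
subunit moves between two conformers that share a rigid core. Author
residue numbering is used throughout and `chain:start-end` strings address
residues everywhere. Coarse-graining is one bead per residue at the Cα
(centroid fallback with a warning), radius 3.5 Å, used only by the
excluded-volume term.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use: toy complexes of 3 × 20
residues with 4 links per mobile body over 10 seeded replicates at the full
default MC schedule; an exhaustive 13³ translation grid on a 5-bead
instance; 200 simulated titrations per Kd setting across 10–400 nM; and
~200-peptide HDX simulations in triplicate over three exposures. These
sizes give stable statistics while keeping a full run in the minutes range
on one core. All generators and the sampler are deterministic given seeds;
`scripts/acceptance.R --seed N --out f.json` re-derives every reported
number from scratch.

## Known limitations

* Cross-link false-discovery modelling and spectral identification are out
  of scope; tables are taken at face value.
* Homomeric ambiguity is ignored (single-copy subunits assumed).
* The placement score is an interpretation of platform defaults; absolute
  score values are not comparable across parametrisations, only restraint
  satisfaction is.
* PLIMSTEX fits are per-peptide; no global shared-Kd model, no n:1 or
  cooperative binding.
* mmCIF support covers the `atom_site` loop of standard coordinate files,
  not the full CIF grammar.
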