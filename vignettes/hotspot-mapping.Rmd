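---
title: "Physics-based interface hotspot mapping and ensemble diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-based interface hotspot mapping and ensemble diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotforge)
```

## The problem

Protein-protein interfaces bury large surfaces, but binding free energy is
typically concentrated in a handful of *hotspot* residues. Knowing which
residues carry that energy is the starting point for designing miniprotein
binders: generative design engines accept a list of target residues and
condition backbone placement on them, and the quality of that list determines
whether designs engage the functional epitope. hotforge maps hotspots from a
complex's coordinates with an explicit nonbonded energy model, quantifies how
two independent mapping engines agree, and triages the design ensembles that
come back from the generative stack.

## The energy model

For a complex split into receptor and ligand chain sets, every inter-chain
atom pair within a 4.5 Å threshold is scored as

$$E_{ij} = 4\varepsilon_{ij}\left[\left(\frac{\sigma_{ij}}{r}\right)^{12} -
\left(\frac{\sigma_{ij}}{r}\right)^{6}\right] + \frac{K\,q_i q_j}{\epsilon(r)\,r},$$

with Lorentz–Berthelot combination ($\sigma_{ij}$ arithmetic mean,
$\varepsilon_{ij}$ geometric mean), $K = 332.0636$ kcal Å mol$^{-1}$
e$^{-2}$, and either vacuum electrostatics ($\epsilon(r) = 1$) or a screened,
distance-dependent dielectric $\epsilon(r) = f\,r$ (default $f = 1$, so the
Coulomb term falls as $1/r^2$). The screened mode is the default for hotspot
aggregation; the screening factor is exposed so the $\epsilon(r) = 4r$
convention is one argument away. No switching or shifting function is applied
anywhere: energies are the bare formulas, and a `cutoff = Inf` path exists
for exhaustive all-pairs sums. Cutoff comparisons are inclusive throughout
(a pair at exactly 4.5 Å counts).

Per-residue hotspot strength is the cumulative magnitude of favorable
contributions, under two first-class qualification rules selected by
`hotspot_criteria()`:

* **atom_pair** (default): an atom pair qualifies when its total energy is
  strictly negative within 4.5 Å;
* **residue_pair**: a residue pair qualifies when its summed energy is at
  most $-1.0$ kcal/mol (inclusive) with at least one interatomic distance at
  most 3.5 Å. In this mode atom-pair energies are summed over the residue
  pair *before* thresholding.

Each qualifying contribution credits $|E|$ to one residue on each side, so
total strength is identical on the two sides — a conservation law the test
suite checks on every fixture. Ranks use descending strength with a
deterministic tie-break (chain, then residue number) so Top-N selections are
reproducible across platforms. Strengths are reported in kcal/mol because
this engine's units are known, even though hotspot bar plots are often
labelled in arbitrary units.

## Parameters without hydrogens: the folding scheme

Crystal structures usually lack hydrogens, and the usual remedy (an external
protonation tool followed by a simulation engine) drags in heavy
dependencies. hotforge instead ships an embedded parameter subset — the
published Amber ff94/ff99 partial charges retained by ff14SB, with Amber LJ
well parameters — for the 20 canonical residues plus the histidine
protonation variants (HIE is the pH-7 default; HID and HIP are shipped).
`fold_hydrogen_charges()` then adds the charge of every template hydrogen
missing from the coordinates onto its bonded heavy atom (bonding defined by
the residue templates), dropping hydrogen LJ terms. Every residue ends at
its integer formal charge, the operation is idempotent, and the whole
pipeline becomes deterministic on heavy-atom inputs.

Two consequences are worth stating plainly. Absolute energies differ from a
fully protonated calculation — a folded ammonium nitrogen carries +0.63 e at
the nitrogen position rather than three displaced proton charges. The
consumed quantity, however, is the *relative* residue ranking, which is
robust to this approximation. Second, terminal-residue charge variants are
not shipped: chain-terminal residues reuse the internal template (with a
warning when OXT is seen), so termini carry a small net-charge error.
Termini are rarely interfacial; when they are, their ranks should be read
with that caveat.

Histidine protonation is a genuine ambiguity of any such pipeline: rankings
adjacent to interfacial histidines can shift between engines that choose
tautomers differently, which is one reason the benchmarking module exists.

## Contact cartography and benchmarking

`build_contact_maps()` produces the three standard chain-aware geometric
views of a complex from Cα coordinates: the distance matrix, the
reciprocal-distance map $100/d$ (diagonal and near-zero distances masked
rather than infinite, to keep exports finite), and the binary contact matrix
at an inclusive 8 Å cutoff, with chain boundaries recorded so inter-chain
blocks can be sliced.

`concordance()` compares two per-residue rankings — e.g. this engine against
an imported contact-table export from a commercial package — using Spearman
rank correlation (average-rank ties) and Pearson correlation of strength
magnitudes over residues present in both tables, plus Top-N overlap at
N = 5, 10, 20, 30, 50: intersection size, Jaccard index, and recall defined
as $|T_a \cap T_b| / N$ (the definition is written into every report header,
since "recall relative to each method" admits several readings; residues
unique to one method are reported as a diagnostic list rather than silently
dropped). With fewer than three shared residues the correlations are
reported as undefined rather than fabricated. External tables are ingested
through a configurable column/label dialect because export headers vary
between program versions; water residues are excluded on ingestion.

## Ensemble triage and diagnostics

Designs come back from the generative stack as a unified metrics table.
`filter_designs()` applies the confidence gate — mean pLDDT ≥ 80 and
iPAE ≤ 15, both inclusive — and keeps the 100 highest-confidence rows under
a deterministic order (ascending iPAE, then descending pLDDT, then id).
iPAE is treated as an engine-reported scalar and thresholds are applied
verbatim, because upstream engines are not consistent about its units.
`helicity` and `mpnn_score` are pass-through columns: recomputing helicity
would require a secondary-structure assignment convention this package has
no authority to pick.

`per_residue_rmsd()` performs one Kabsch least-squares superposition over
all mapped backbone atoms (N, Cα, C, O) and then profiles per-residue RMSD
along the chain; the superposition is global, so a localized deformation
shows up as a peak at the deformed residue slightly diluted by the refit
(a 2 Å single-residue displacement in a 24-residue fixture recovers as
≈ 1.83 Å at that residue). Residue correspondence defaults to file order
and accepts an explicit mapping when numbering differs.

Sequence diagnostics follow the standard definitions: Needleman–Wunsch
global alignment with affine gaps (BLOSUM62, gap open 11 / extend 1, a gap
of length $L$ costing $11 + L$; implemented in-package because the traceback
tie-break — diagonal over up over left — is part of the reproducibility
contract, and cross-checked against an independent aligner in the tests),
normalized Hamming distance (mismatches over alignment length, gap columns
counting as mismatches), and per-column Shannon entropy
$H_s = -\sum_i p_i \log_2 p_i$ in bits with gaps excluded from the
frequencies. In align mode the entropy profile is computed on the first
sequence's columns via its pairwise alignments; insertions relative to that
sequence are ignored, which is the right frame when the first sequence is a
consensus or native reference.

## What the synthetic fixtures emulate — and what they do not

The generators exist so that the entire pipeline is testable with no
downloads. `make_helix_dimer()` builds two ideal α-helices (1.5 Å rise,
100°/residue, 2.3 Å Cα radius — the textbook parameters, giving the 3.8 Å
Cα-Cα virtual bond) on parallel axes, with idealized straight-arm heavy-atom
side chains and optional engineered Glu/Lys salt bridges. Bridge side chains
are oriented along the line joining the two bridge Cαs, and each helix is
phased so its bridge Cα points away from the partner; at the default 10 Å
axis separation this produces a well-formed ~2.9 Å carboxylate–ammonium
contact that any correct energy model must rank first on both sides. Note a
geometric fact that follows from the helix radius: the closest inter-chain
Cα approach of two such helices is near `separation − 4.6` Å, not the axis
separation itself.

The fixtures are deliberately not crystallographic: no alternate locations,
no anisotropy, no gaps, no rotamer library, side chains as idealized arms.
Passing tests therefore demonstrate correctness of the energy model,
aggregation logic, and statistics — not robustness to real-world structure
pathology, which enters only through the PDB parser's altloc policy (keep
`''`/`'A'`, drop the rest) and the missing-atom warnings.

The remaining generators are exact by construction where exactness is the
point: mock contact tables reproduce a planned strength profile perfectly at
zero noise (so benchmarking round-trips are testable), mock metrics tables
contain exactly the planned number of threshold-passing rows with one row
placed exactly on both thresholds (so inclusive semantics are exercised),
and sequence ensembles never mutate conserved positions (so entropy zeros
are exact). The mutation model — per-site rate $r$, uniform choice among the
19 alternatives — has closed-form pairwise expectations
($2r(1-r) + r^2 \cdot 18/19$ mismatch probability) that the tests check
against simulation at $n = 200$ designs within a 3-sigma band.

## Numerical choices

* Candidate contact pairs are screened with a fast inner-product distance
  matrix, then distances of the retained pairs are recomputed from
  coordinate differences; this keeps the enumerated table identical (to
  better than $10^{-9}$ kcal/mol) to a naive double-loop evaluation even at
  steric-clash separations where $r^{-12}$ amplifies rounding.
* Degenerate inputs return flagged results rather than NaNs: undefined
  correlations (constant vectors, < 3 shared residues) are `NA` with a
  `defined`/`correlations_defined` flag, reciprocal maps mask rather than
  emit infinities, and empty contact lists aggregate to empty tables.
* Problem sizes in the test-suite simulations (20 seeded dimers of ~130
  atoms for the energetics oracle, 100 random rigid transforms, 200-design
  ensembles, exhaustive alignment enumeration up to length 6) were chosen as
  the smallest sizes at which the checked expectations are sharp.

## Known limitations

* No bonded terms, no 1-4 scaling (all evaluated pairs are inter-chain), no
  PME/periodicity, no solvation term, no minimization: this is an interface
  *ranking* engine, not a free-energy method.
* Heavy-atom charge folding changes absolute energies; comparisons against
  fully protonated engines should be made on ranks, which is exactly what
  the benchmarking module computes.
* The asymmetric unit is analyzed as deposited; biological-assembly
  expansion is out of scope, so the chains named in the interface selection
  must be the physically interacting copies.
* mmCIF is not parsed; PDB is the contract format.
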