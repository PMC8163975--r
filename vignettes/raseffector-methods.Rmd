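---
title: "Methods: contact matrices, hotspots and quadratic Kd fitting for RAS-effector interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact matrices, hotspots and quadratic Kd fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raseffector)
```

## The problem

RAS-family GTPases signal through effector proteins that dock onto the
GTP-loaded G domain via structurally similar RA (RAS-association) and RB
(RAS-binding) domains. Which residues carry that recognition, and how a
handful of interface substitutions can re-route an effector's selectivity,
are questions that can be asked quantitatively once two ingredients are in
place: a residue-level census of the interface across all available complex
structures, and dissociation constants for the binding pairs. This package
implements both halves as a reproducible pipeline: structure-derived
residue-residue interaction matrices with hotspot calling, alignment-based
residue-swap variant design, and quadratic (ligand-depletion) fitting of
fluorescence-polarization titrations. A synthetic-data generator with known
ground truth stands in for crystal structures, curated alignments and
plate-reader output, so every stage is testable offline.

## Contact extraction

Two residues are in contact when the minimum distance over all their
heavy-atom pairs is at or below a cutoff, default 4.0 Å. Hydrogens are
excluded (crystal structures mostly lack them, and the 4 Å convention is a
heavy-atom one); waters, nucleotide analogs and ions are excluded because the
interaction matrix relates protein residues only. Alternate locations are
resolved to the highest-occupancy conformer, ties broken by altloc
identifier, and multi-model files use a manifest-specified model index.
Residues left without heavy atoms are skipped with a warning rather than
failing the complex, which tolerates sparse crystallographic models.

`extract_contacts()` prunes residue pairs by a bounding-sphere test
(centers further apart than the cutoff plus both residues' atom radii cannot
touch) before computing exact minima; the test suite holds it to exact
agreement with a brute-force all-pairs scan on 200 random complexes with up
to 60 residues per chain. Minimum distances are computed from explicit
coordinate differences rather than the expanded inner-product form, which
keeps them exact to machine precision.

## From structures to reference numbering

Published interface analyses quote residues in a reference frame (HRAS
numbering on the GTPase side; CRAF or RASSF5 numbering on the effector
side). Author numbering in structure files is unreliable, so the package
never uses it for mapping: each chain's residue sequence is matched to its
alignment row by global pairwise alignment (match +1, mismatch −1, gap open
5, gap extend 0.5), composed with the row's gap pattern to give a
residue-to-column map. A guard requiring ≥ 80% identity over aligned
positions catches wrong-row assignments. Residues aligned to row gaps are
reported as unmapped; aligned mismatches are kept, since
sequence-vs-structure discrepancies at a few positions are common and the
identity guard bounds their number.

Reference labels number the k-th non-gap reference column
`start + k − 1` with the reference amino acid (`E37`); columns gapped in
the reference become insertion labels anchored to the preceding number
(`37+1`). Insertions are retained in the matrix rather than dropped, so
contacts from effector-specific insertions are never silently discarded.

## Conservation calls

A column is conserved when at least a threshold fraction (default 0.9) of
its non-gap residues fall into one similarity group. The default groups —
{D,E}, {K,R}, {N,Q}, {S,T}, {I,V,L,M}, {F,Y,W}, {A,G}, {C}, {H}, {P} —
follow the slash pairs conventionally used when reporting homologous
interface residues (D/E, R/K, I/V, S/T, Q/N). The 0.9 default tolerates a
paralog outlier in alignments of a few dozen rows while keeping half-split
columns variable; both the groups and the threshold are arguments, since no
universal rule exists. Conservation is invariant to row order, and raising
the threshold can only shrink the conserved set.

## The interaction matrix and hotspots

Per complex, the projected contact pairs are binarized: a residue pair
counts once per complex no matter how many atom pairs qualify, and each
crystallographically independent copy of a complex is its own entry (so a
panel of 13 structure files can contribute 19 complexes). Cell values
therefore range from 0 to the number of complexes, each cell carries its
supporting complex-id list, and ingestion order cannot change the result.

A residue's hotspot support is the number of complexes in which it touches
at least one partner residue — again binarized per complex, so contacting
three partners in one structure contributes 1, not 3. The default "major
hotspot" threshold is a majority of complexes, `ceiling(n/2)`, exposed as a
parameter because published hotspot figures highlight residues without
stating a numeric rule. RA- and RB-family complexes can share one merged
effector axis or be analyzed per family via the manifest's family column
and the pipeline's `family` filter.

## Variant design

A swap proposal transplants the donor's residues onto the acceptor at
designated hotspot columns: substitutions are emitted only where the two
differ and neither is gapped; gapped columns are reported as unswappable.
Positions are given in the acceptor's construct numbering — the count of
non-gap acceptor residues up to the column plus a per-construct offset —
because different effector constructs are conventionally numbered in their
own frames (positions in the 180s for one RASSF construct, the 40s for
another). Proposals are validated to have strictly increasing positions;
input repeating a position with two wild-type residues (as one published
variant string does, evidently a typo) is rejected rather than reproduced.
Applying a proposal and re-proposing yields an empty substitution list,
which the tests exercise as a round-trip property.

## Quadratic ligand-depletion Kd fitting

With the labeled GTPase fixed at total concentration $R$ and effector
titrated at total concentration $L$, the exact 1:1 isotherm is

$$ f_b = \frac{(R + L + K_d) - \sqrt{(R + L + K_d)^2 - 4RL}}{2R}, $$

and the polarization signal is
$P = P_\mathrm{free} + (P_\mathrm{bound} - P_\mathrm{free}) f_b$. The
depletion form is required because measured affinities extend well below
the 1 µM receptor concentration, where the hyperbolic approximation
$L/(L+K_d)$ is badly biased — the tests assert that bias directly at
$K_d = 0.3$ µM. The implementation evaluates the stable equivalent
$f_b = 2L / (q + \sqrt{q^2 - 4RL})$, $q = R+L+K_d$, to avoid cancellation
in the tight-binding limit.

Fitting is Levenberg–Marquardt least squares over $(K_d, P_\mathrm{free},
P_\mathrm{bound})$: start values take $P_\mathrm{free}$/$P_\mathrm{bound}$
from the low/high concentration deciles and $K_d$ from the concentration at
half the observed dynamic range, with five log-spaced restarts on
non-convergence. Standard errors come from the fit covariance. Datasets
need at least 6 points; flat signals and fits with $K_d$ above 500 µM are
flagged `no_binding`.

Affinity bands are high 0.1–5 µM, intermediate 6–30 µM, low 31–90 µM, very
low 91–510 µM, no binding above 500 µM. The printed band edges leave gaps
(5–6, 30–31, 90–91), so classification uses half-open intervals splitting
the gaps at 5.5, 30.5 and 90.5; the no-binding rule takes precedence over
the very-low band's upper edge, and $K_d$ below 0.1 µM classifies as high.
None of the worked band examples (0.3, 27, 65 µM) is affected by these
boundary choices.

Wild-type/variant comparisons report the $K_d$ ratio and a two-sided z-test
on the log-$K_d$ difference with delta-method standard errors from the fits.
This mirrors error bars "derived from fitting errors" when replicate
titrations are unavailable; it is a reconstruction, clearly labeled in the
output, not a claim about any particular published p-value procedure.

## The synthetic-data generator

The generator defines the study conditions for every test and for the
acceptance computation:

* **Complexes.** Residues are rigid five-atom fragments (N, CA, C, O, CB,
  all within 1 Å of the residue center, randomly oriented) on a line
  lattice with 10 Å spacing; a planted contact translates an effector
  fragment so its center sits at the target distance (sampled in
  2.5–3.8 Å) from its partner's center. This guarantees planted pairs are
  within the 4 Å cutoff and all other intermolecular pairs exceed cutoff
  + 2 Å — a clean separation the contact definition needs, with no
  pretense of physical realism (no folds, rotamers or ligands). Geometry
  limits each effector residue to one planted contact and each GTPase
  residue to four (the ±y/±z placement slots); infeasible requests fail
  explicitly. Because fragments are rotation-jittered, a planted pair's
  realized minimum heavy-atom distance can fall up to 2 Å below its
  target, which the tests account for when choosing cutoffs that must
  empty the contact set.
* **Ensembles.** All complexes share chain lengths and sequences; core
  contacts appear in every complex, and one candidate peripheral pair per
  remaining effector residue (with a randomly fixed GTPase partner) is
  planted independently at the peripheral rate. The generator records its
  per-pair planting counts, which the matrix must reproduce exactly. The
  analysis scripts use 19 complexes, matching a well-populated
  single-family structure panel.
* **Alignments.** Conserved columns draw all rows from one similarity
  group; variable columns split rows as evenly as possible between two
  distinct groups, so the planted labels are recoverable exactly at the
  default threshold for any number of rows ≥ 2.
* **Titrations.** 1 µM receptor, 20 log-spaced effector concentrations
  over 0.002–300 µM, and i.i.d. Gaussian noise at 2% of the dynamic range
  — a standard noise model for polarization readouts, chosen at a level
  visually consistent with published FP scatter; the replicate count for
  recovery studies (100) is a free parameter of the harness.

What passing tests on these data do **not** show: robustness to real
crystallographic pathologies (chain breaks beyond simple deletions, symmetry
contacts, ambiguous biological units), to hand-curated alignment edits that
sequence-based mapping cannot reconstruct, or to correlated instrument
drift in titrations. Those require real inputs, which the pipeline accepts
through the same manifest/alignment/CSV interfaces.

## Problem sizes and numerical choices

The test suite verifies the contact extractor against a brute-force scan on
200 random complexes (chains of 5–60 residues), runs 100-replicate
Monte-Carlo recovery at each of the five headline affinities (65, 35, 34,
27, 0.3 µM; medians required within 10%), and checks noiseless round-trips
at 10⁻⁶ relative tolerance — sizes chosen to exercise the code thoroughly
while keeping a full run around a minute. Determinism is enforced
throughout: every stochastic routine takes a seed and restores the caller's
RNG state, and rerunning any pipeline on identical inputs produces
byte-identical files.

## Known limitations

* Contacts are purely distance-based; no backbone/side-chain
  sub-classification is applied (a contact's atom identities are available
  upstream, but no quantitative use is defined for them here).
* The merged effector axis assumes the supplied effector alignment already
  reconciles RA and RB families; the package does not structurally align
  families to each other.
* Significance from single-fit error propagation understates
  between-experiment variability; with replicate titrations, a
  replicate-based test should replace it.
* The mmCIF reader handles standard `atom_site` records via bio3d's parser,
  which is less battle-tested than its PDB path; both serializations of the
  same complex are required by the tests to yield identical contacts.
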