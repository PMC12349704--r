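---
title: "Methods: automated metabolite identification for macromolecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated metabolite identification for macromolecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macromet)
```

## The problem

Metabolite identification (MetID) asks which biotransformation products a
compound forms during incubation with enzymes or biological matrices, and
where on the molecule each transformation occurred. For therapeutic
peptides and oligonucleotides this is substantially harder than for small
molecules: the analytes carry multiple charges, their isotope envelopes
are wide, the number of conceivable products and fragments grows
combinatorially with monomer count, and the spectra are dense. `macromet`
implements an automated LC-HRMS workflow for this setting: peak targeting
by monoisotopic or most-abundant mass, monomer-level metabolite generation
and fragmentation, blank-aware peak detection, and fragment-evidence
scoring, together with a seeded synthetic-run generator so every stage is
testable without instrument files.

## Composition algebra and isotope patterns

All masses derive from an `elemcomp` multiset of element counts. Isotope
masses and abundances are pinned (NIST values, shipped as a text table);
standard atomic weights are pinned to the 2005 IUPAC table because the
reference molecular weights this package reproduces were computed with
weights of that era — newer revisions of S and C shift a somatostatin-sized
peptide by a few hundredths of a dalton, which is why downstream checks on
average masses use a ±0.03 Da band. The proton mass is fixed at
1.007276466 Da and electron mass is neglected.

The isotope pattern of a composition is computed by per-element
multinomial expansion convolved element-by-element, using
exponentiation-by-squaring for the per-element powers, with bins pruned
below an absolute abundance of 1e-10 (configurable) and renormalized to
unit sum. Isotopologues are aggregated by nominal mass shift
(M0, M+1, ...): each aggregated bin carries the abundance-weighted mean
mass of its isotopologues. Fine structure (e.g. separating the 13C from
the 15N peak within M+1) is deliberately not resolved; at the resolving
powers typical for peptide MetID the aggregated bins are what the
instrument reports. Ties for the most abundant bin break toward the lower
shift, so `most_abundant_mass()` is deterministic and never falls below
`monoisotopic_mass()`.

The monoisotopic mass (MiM) is the mass with the lightest isotope of every
element; the most abundant mass (MaM) is the mass of the strongest
aggregated bin. For compositions up to roughly 80 carbons without
S/Cl/Br the two coincide; at insulin scale the strongest bin sits three
nominal units above M0 and carries several times its abundance, which is
the entire rationale for MaM-based peak targeting: an extracted ion
chromatogram at the M0 position of a large product can sit below the
noise floor while the envelope apex is comfortably detectable.

## Polymer model

A `polymer` is an ordered list of monomers grouped into chains, with
per-chain terminal groups, disulfide linkages, optional head-to-tail
closure, in-place modification records and per-monomer representation
flags. Residue compositions are "as incorporated" (amino acid minus
water); a linear free peptide is the residue sum plus H and OH, a
C-terminal amide swaps OH for NH2, the reduced C-terminus ("-ol") is +H3
relative to the bare acyl chain, each disulfide removes H2, and a
head-to-tail cyclic chain carries no terminal groups at all.

Sequence parsing follows the dash notation used in therapeutic-peptide
tables. Conventions worth stating explicitly:

* numeric `(n)` labels pair into disulfides and must sit on thiol-bearing
  monomers; non-numeric parentheses (`Tyr(Me)`, `Met(O2)`) are part of the
  monomer code;
* a `D-` prefix resolves to the L-isomer's composition (mass-identical);
* compound tokens that a dash split breaks (`Ser-tBu`, `deamino-Cys`) are
  re-joined when the orphan fragment is not independently resolvable;
* when no explicit N-terminal token is present, a nitrogen-bearing first
  residue receives the implicit N-terminal hydrogen. This makes `Glp-`
  (pyroglutamate) sequences carry the ring N-H — without it their
  molecular weights come out one hydrogen short — while acyl starters such
  as deamino-Cys correctly receive nothing.

Expanded (atom-level) representation attaches atom graphs from registry
templates; the shipped demo set covers Gly and Ala, and
`register_monomer()` accepts templates for custom residues. Hybrid
expansion of a subset of monomers is supported; composition is invariant
under representation mode. Atom-level fragmentation is combinatorial in
bond count, so expansion of large structures is intentionally opt-in
per monomer.

## Biotransformation engine

Rules come in two kinds. *Cleave* rules hydrolyze a backbone bond; the
engine checks connectivity after removing the bond (through disulfides and
head-to-tail closures): if the molecule stays connected the product is a
single ring-opened species gaining one water (+18 nominal), otherwise two
products are formed whose compositions sum to parent + H2O, and both are
retained. This single mechanism reproduces the characteristic behaviour
of disulfide-cyclic peptides: tail cleavages outside the macrocycle give
truncations (loss of the N-terminal Ala of somatostatin is −71, loss of
Ala-Gly is −128), while any cleavage inside the macrocycle gives +18.
*Modify* rules apply an in-place composition delta at matching monomers
(O-dealkylation, aromatic deamination at −NH2+OH = +0.98402 Da,
nucleobase loss to an abasic site, and arbitrary user-defined deltas,
which cover e.g. sequential beta-oxidation of fatty-acid side monomers).

Enumeration is breadth-first over generations (default depth 2, product
cap 10,000, deterministic rule-and-site order). Candidates are
de-duplicated on (composition, surviving-monomer map, modification-site
set), keeping the lowest generation — note this means a product reachable
in two step orders records the first derivation. Every candidate carries
a map from its monomers to the parent's and a site-modification table in
parent coordinates; these two structures are what downstream fragment
shifting consumes.

## Fragmentation

Monomer-level fragmentation generates the six classic backbone series.
Neutral-species conventions: b is the residue sum plus the N-terminal
group minus H; y is the residue sum plus the C-terminal group plus H;
a = b − CO, c = b + NH3, x = y + CO − H2, and z = y − NH3 (the
even-electron convention; the radical z-dot is not modeled). These hold
the complementarity identity (b − proton) + (y − proton) = M at every
cleavage, which the test suite verifies over random peptides.
Hydrogen-rearrangement variants default to ±1 H around each fragment.

Disulfides impose topology on the fragment space: a candidate fragment
covering exactly one endpoint of an intact same-chain disulfide is a
cyclic arc that cannot physically detach and is suppressed; a fragment
whose partner endpoint lies on another chain pulls in that whole chain
minus H2 (iterated to closure), producing the two-chain fragments seen
for insulin-type molecules. This is also what makes the metmatch channel
informative for ring-opened cyclics: the linearized metabolite suddenly
produces backbone fragments that the intact parent could not.

Atom-level fragmentation enumerates every connected component obtainable
by deleting up to `max_bond_breaks` bonds (two in practice), de-duplicated
by atom set. Series fragments of a fully expanded peptide appear among
the all-bond fragments up to small hydrogen shifts.

## Peak detection against a blank

* **Noise.** Per MS1 scan, intensities are ranked descending and the elbow
  of the rank curve located as the largest discrete second difference; the
  threshold is the midpoint between that rank's intensity and the previous
  one. All-equal or near-empty spectra get threshold 0. The published
  description of the noise rule is qualitative ("change in slope between
  consecutive shortlists"); this elbow definition is the package's
  concrete reading, and the run-level noise is the median over scans.
* **Peaks.** EICs sum centroids within a ppm window per scan (10 ppm
  default, matching the acceptance gate used in practice). Local maxima
  need apex ≥ k×noise (k = 3); boundaries extend to surrounding minima or
  the baseline; overlapping peaks split at valleys dropping below half the
  smaller apex; areas are trapezoidal.
* **Blank comparison.** The blank EIC is aligned over the peak window by
  the shift maximizing the Hodgkin index 2Σxy/(Σx²+Σy²); "similar" means
  Hodgkin ≥ 0.9 AND Pearson ≥ 0.8 (a conjunctive reading of the published
  "combination" of the two indexes — conservative, because exclusion
  deletes evidence). Similar peaks with blank area ≥ sample area are
  dropped; the Negative Control Area Ratio is reported regardless and
  capped when the blank is empty. A peak whose blank EIC is all zero is
  never dropped.
* **Filtered spectrum.** Scans inside the peak are merged, centroids
  clustered within the ppm tolerance, and clusters kept only when their
  per-scan profile correlates with the EIC shape (Pearson ≥ 0.7). With
  fewer than two in-peak scans the merge is returned flagged unfiltered.
* **Isotope similarity.** Observed abundances are read at the predicted
  envelope positions (spacing divided by charge) and compared as
  1 − 0.5·Σ|obs − pred| after unit normalization.
* **Assignment.** Candidate × charge targets from MiM or MaM; a match
  needs the target within tolerance and isotope similarity ≥ 0.6. The
  composite quality is the equal-weighted mean of isotope similarity and
  ppm closeness — the relative weighting of the published criteria is not
  specified anywhere, so equal weights are used and exposed as settings.
  Among matches, the representative m/z is the highest matching m/z.
  Unexplained peaks classify as adduct/in-source when a configured delta
  on the parent explains them, otherwise "red" (unknown).

## Evidence classification and scoring

Substrate-metabolite peak pairs are formed greedily in descending parent
intensity: non-shifted pairs at equal m/z, shifted pairs at parent m/z
plus each candidate site delta over charge; each metabolite centroid is
used at most once per status. A parent centroid with an assigned fragment
then has a predicted behaviour from the fragment's covered monomer set:
fragments excluding all modified sites should pair non-shifted, fragments
covering modified sites should pair shifted by the summed site delta, and
fragments overlapping a cleavage boundary or covering lost monomers
predict nothing. Agreement is a match, contradiction a mismatch; when a
centroid admits both interpretations the one consistent with the
prediction wins (the ambiguity is unspecified in the field's published
descriptions; resolving toward match was chosen and is visible here).
Metabolite centroids with no parent counterpart but explained by directly
fragmenting the candidate structure are metmatches.

The score is Σ intensity(match) + Σ intensity(metmatch) − Σ
intensity(mismatch), using metabolite-side intensities (the score grades
the metabolite's evidence; the published formula does not name the side).
MS1-level pairs are classified but excluded from the score by default.
Candidates are ranked by score, ties broken by fewer applied rules then
lower |ppm|, and the top candidate is auto-selected. Removing a record
and re-scoring equals scoring the reduced set, and the score is monotone
in the obvious directions — both property-tested.

## Workflow

Per-sample assignment tables are consolidated across time points by
single-linkage clustering at 0.2 min and 10 ppm (no published values
exist for these; the defaults reflect typical UPLC peak widths and the
mass-accuracy gate). Filters are conjunctive — relative area ≥ 0.5%,
|ppm| ≤ 10, optional isotope-similarity and NCAR gates — with a per-entity
audit of which criterion fired; the parent row is never filtered. Kinetic
profiles (per-time relative areas) are emitted for inspection but their
shapes are not auto-classified: judging exponential versus sigmoidal
formation is left to the reviewer. The report names metabolites
`M<i><±nominal delta>` in retention-time order and includes an empty CCS
column (ion mobility is out of scope).

`paired_score_test()` is the classic paired t statistic with a two-sided
p from the t distribution; `stats::t.test` serves as an independent
cross-check in the tests, not as the implementation. The shipped
reference score table (calcitonin, insulin and an antisense
oligonucleotide under both targeting modes) exercises it end to end; of
the two readings of the two ambiguous adjacent oligonucleotide rows, the
as-printed pairing reproduces p = 0.00029 and the realigned one stays at
the same order of significance.

## The synthetic-data generator

`simulate_experiment()` emulates exactly the statistical structure the
pipeline assumes: Gaussian chromatographic profiles carrying full isotope
envelopes at configured charges, a shared matrix-background population
reproduced in the blank, log-normal intensity jitter (sdlog 0.15),
Gaussian centroid m/z jitter of 2 ppm (set deliberately below the 10 ppm
gate so the gate is exercised but not saturated), and one DDA-style MS2
scan per species near its apex built from the species' own backbone
fragments. All randomness derives from the plan seed; identical plans
give identical runs.

The fixture suite uses 3-minute gradients at 2-second scans (~90 MS1
scans per run) with two incubation time points — sizes chosen so the full
five-fixture end-to-end validation completes in well under a minute on a
single CPU while every stage still has realistic work to do. The
insulin-scale fixture plants a two-chain cleavage product whose amplitude
places its envelope apex about an order of magnitude above the noise
floor while its M0 bin (about 30% of the apex bin, times the envelope
normalization) lands below the 3×noise detection threshold; this
reproduces the qualitative headline that MaM targeting recovers large
products that MiM misses, as a deterministic property of the fixture.

What the simulator does **not** emulate — and what passing its tests
therefore does not demonstrate about real data: retention-time or
ionization-efficiency prediction, peak tailing (a tail parameter exists
but fixtures are symmetric), chimeric MS2, in-source fragmentation,
saturation, and mass-axis drift. The generator validates the logic of
the pipeline, not vendor-data robustness.

## Numerical choices and degenerate inputs

Pruning threshold 1e-10 on absolute bin abundance; MaM ties break to the
lower shift; subtraction of compositions errors rather than clamping;
empty compositions have mass 0 but no isotope pattern; spectra with < 3
centroids have noise 0; peaks need ≥ 3 scans; `detect_peaks` on an
all-zero EIC returns an empty table; blank exclusion with an empty blank
keeps the peak with capped NCAR; `filtered_spectrum` under two in-peak
scans skips the correlation filter and says so; `pair_spectra` requires
non-empty spectra; `paired_score_test` refuses n < 2 and zero-variance
differences.

## Known limitations

Monomer-level oligonucleotide fragmentation uses the same six series as
peptides; the nucleic-acid w/d series are not generated. The expanded
mode ships templates only for the demo residues. Adduct chemistry beyond
configurable mass deltas, lock-mass recalibration, profile-mode
centroiding and ion mobility are out of scope. Score weights for the
composite assignment quality are equal by construction, not fitted.
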