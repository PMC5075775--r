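---
title: "Designing and evaluating LNA/DNA oligonucleotide antigens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating LNA/DNA oligonucleotide antigens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoantigen)
```

## The problem this package addresses

Anti-dsDNA autoantibodies are a diagnostic hallmark of systemic lupus
erythematosus (SLE), but the natural DNA antigens used in clinical assays are
heterogeneous and unstable, which hurts reproducibility and specificity.
Synthetic oligonucleotides with locked nucleic acid (LNA) monomers — sugars
constrained by a 2′-O,4′-C methylene bridge — offer sequence-defined,
thermally stabilised antigens. This package implements the computational
chain for designing such antigens and evaluating them: sequence design with
secondary-structure screens and rule-based LNA placement, interface metrics
on antibody–oligonucleotide coordinate frames, 1:1 Langmuir kinetics for
surface plasmon resonance (SPR), and the plate statistics used to compare
antigens in ELISA. Seeded synthetic-data generators stand in for clinical
sera and molecular-dynamics trajectories, so every stage is testable on a
desk.

## Sequence model and notation

An `annotated_strand` is a DNA base vector plus a set of 1-based LNA
positions and an explicit 5′/3′ polarity. Positions are counted 5′→3′ along
the written strand, matching the convention of oligonucleotide vendor
datasheets. The conventional mixmer notation marks a locked base with a
preceding `+`; whitespace is presentation only:

```{r}
s1 <- parse_lna_notation("TCC + TCT CTT TCT + CTT TCT + CTT", name = "SEQ1")
s1$lna_flags
base_composition(s1)$percent
```

Integer base-content percentages round half up, the convention that turns
13/21 and 8/21 into the tabulated 62%/38%. Complements are unmodified DNA by
default — in the assays the annealing partner of an LNA mixmer is plain DNA —
and complementing flips the polarity label rather than reversing the string,
so the complement sits in the same left-to-right register as its partner.

The bundled `fixture_sequences()` panel keeps every printed reading of the
study's oligonucleotides, including two deliberate redundancies: the fourth
21-mer is stored once with the explicit position-column LNA set
{4, 10, 14, 19} (taken as authoritative) and once as the literal parse of
its `+` notation {4, 10, 13, 19}, and two printed complement variants whose
final bases are not Watson–Crick consistent with their partners are kept
verbatim under `_modelling` names. `make_duplex()` refuses inconsistent
pairings, which is how those variants are caught.

## Antigen design

The design path starts from dinucleotide repeats seeded with dTdC — the
dinucleotide the model antibody ED-10 prefers in its binding pocket — and
explores the substitutions T→A and C→T of the repeat unit. Candidates then
face three screens:

* **Self-dimer**: longest contiguous Watson–Crick run between the strand
  and an antiparallel copy of itself over all offsets; default tolerance
  4 bp.
* **Hairpin**: exhaustive enumeration of intramolecular stems, reported at
  their outermost maximal extension; defaults require flagging any stem of
  ≥ 4 bp enclosing a loop of ≥ 3 nt.
* **GC content**: strands with GC% strictly above 75 are rejected (they
  form overly stable secondary structure).

The 4 bp / 3 nt / 4 bp thresholds are conservative values in common use for
primer and probe design; the screens were originally delegated to a web
service without published thresholds, so the defaults are exposed in the
pipeline configuration. Both screens are deliberately exhaustive
(quadratic/cubic in strand length): antigen candidates are ≤ 63 nt, so an
exact enumeration is cheaper than any heuristic is worth, and it can be
verified against an independent brute force in the tests.

When a repeat fails a screen, a composition-preserving repair is attempted:
greedy swaps of two positions holding different bases, accepted only when
they reduce the violation count, under a seeded RNG recorded in the output.
Swaps preserve mononucleotide counts exactly; exact dinucleotide-frequency
preservation is not enforced, since the design intent ("keep the key
dinucleotide content") is approximated well by count preservation on these
short, low-complexity strands. GC failures are not repairable by swaps and
drop the candidate immediately.

LNA placement follows the separated rule: one LNA near the middle of the
strand and two near the termini, never adjacent (adjacent locked sugars
over-rigidify the backbone). For 21-mers the reference layout is
{4, 13, 19}; the optional binding-site variant adds position 10, the
nucleotide docked in the antibody pocket. Shorter strands scale the
reference positions proportionally (a 10-mer gets {2, 6, 9}); multiples of
21 tile the layout.

## Duplex melting temperature

`estimate_tm()` combines a standard nearest-neighbor prediction for the
unmodified DNA duplex — unified dimer enthalpies/entropies, terminal A·T
versus G·C initiation, an entropic monovalent-salt correction of
0.368·N·ln[Na⁺] cal/(mol·K) with N the number of stacking steps, and the
CT/4 concentration term for non-self-complementary strands — with an
additive increment per incorporated LNA monomer. Reported LNA increments
span roughly 2–8 °C per monomer depending on sequence context; the default
is the mid-range +4 °C and the argument is validated to stay within
[2, 8] °C. Defaults are 0.15 M monovalent salt and 0.25 µM total strand.
Under this additive model the per-LNA increment reported for a modified
duplex against its unmodified twin equals the configured increment exactly,
and predicted Tm is monotone in the number of LNAs — both properties are
asserted in the tests.

## Interface metrics on coordinate frames

`read_frames()` parses single- or multi-model PDB (via bio3d) and merges a
per-atom parameter side-table — charge, Lennard-Jones Rmin/2 and epsilon,
van der Waals radius — keyed by residue and atom name. A missing parameter
is an error naming the atom, never a silent default.

* **SASA** is Shrake–Rupley: each selected atom's sphere of radius
  (vdW + probe) is sampled at deterministic Fibonacci-spiral points, and
  points buried inside any other selected atom's expanded sphere are
  excluded. Defaults are a 1.4 Å water probe and 960 points per atom, which
  put an isolated atom within a fraction of a percent of its analytic
  sphere area; only the selection itself occludes, so a selection is always
  measured in isolation.
* **Contact area** is the buried-interface identity
  S = S_protein + S_nucleic − S_complex, computed from three SASA calls. It
  is zero for separated bodies and symmetric in its arguments by
  construction.
* **Nonbonded energy** sums cross-pair Coulomb (332.0636·q_iq_j/r
  kcal·Å/mol) and Lennard-Jones terms (Rmin by arithmetic combination of
  half-Rmins, epsilon geometric), each damped by a C¹-continuous
  quadratic–cubic switching function that is 1 below 10 Å and exactly 0 at
  and beyond the 12 Å cutoff — the conventional smooth-cutoff treatment in
  biomolecular force fields. Trajectory statistics report the per-frame
  mean, sample SD (defined as 0 for a single frame) and the frame count,
  with an explicit stride argument.
* **Hydrogen bonds** use donor–acceptor distance ≤ 3.5 Å and a
  donor–H–acceptor deviation from linearity ≤ 30°, with a heavy-atom-only
  mode when no hydrogen is resolved. **π-stacks** use ring-centroid
  distance ≤ 5.5 Å with best-fit-plane normals: interplanar angle ≤ 30° is
  parallel stacking, 60–90° is T-shaped. These are the geometric criteria in
  common use; the underlying study names the interacting residues but no
  thresholds. Occupancy is the fraction of frames in which an identified
  contact is detected.

Energies are kcal/mol and coordinates Å throughout. Absolute interface
numbers from the original 100 ns explicit-solvent trajectories are not
reproducible on a desk — that would need the full simulation system — so
the package's guarantees are structural: analytic and dense-grid oracles
for SASA, closed forms for the energy, brute-force scans for the detectors.

## SPR kinetics

The 1:1 Langmuir model dR/dt = k_a·C·(R_max − R) − k_d·R has closed forms in
both phases: an exponential approach to R_eq = k_a·C·R_max/(k_a·C + k_d)
with observed rate k_a·C + k_d during the 60 s injection, and exponential
decay at rate k_d during the following 60 s of buffer flow — the schedule
used in the assays and the generator default (0.5 s sampling). Noise is
additive Gaussian with a recorded seed.

Binding and stability levels are 4 s window means on either side of the
injection end, separated by a 1 s guard gap. One subtlety is worth stating:
for a binder still associating at injection end with negligible
dissociation, the post-injection window mean can slightly exceed the
pre-injection one, so the intuition "binding ≥ stability" holds exactly for
the instantaneous response (the response after injection end never exceeds
its value at the end) but only in the near-plateau regime for windowed
report points. The tests assert both forms in exactly those terms.

`fit_kinetics()` estimates (k_a, k_d, R_max) jointly across the
concentration series by Levenberg–Marquardt least squares on log-scale
parameters, with K_D = k_d/k_a derived exactly rather than fit. Starting
values come from a deterministic heuristic — k_d from a log-linear
regression on the dissociation tail, k_a from the initial association
slope — augmented by a decade grid of k_a starts: fast binders saturate
between samples, leaving the initial slope blind to k_a, while the plateau
levels across the dilution series still identify it from the right basin.
The best start is polished to convergence. Noiseless recovery is exact to
solver tolerance across k_a ∈ [10³, 10⁷] M⁻¹s⁻¹ and k_d ∈ [10⁻⁶, 10⁻¹] s⁻¹,
and at 1% noise the median relative error over 100 seeded replicates stays
within 5%.

Analyte concentrations in the assays are mass-based (the printed two-fold
series 2.5 → 0.16 mg/mL, half-up rounded to two decimals so 0.625 prints as
0.63); conversion to molar uses a molecular weight supplied in
configuration, defaulting to 150 kDa for a whole IgG, and that assumption is
visible in the generator config rather than buried. Rate constants far
outside the typical biological windows (k_a outside [10³, 10⁷] M⁻¹s⁻¹, k_d
outside [10⁻⁶, 10⁻¹] s⁻¹) are flagged as atypical, and positivity calls use
a strict greater-than rule against a designated cut-off sample (normal
human plasma in the assays). Bulk refractive-index jumps, drift and
bivalent-analyte effects are not modelled.

## ELISA statistics

Plate statistics operate on a samples × antigens absorbance matrix with an
antigen→group map. Dispersity — the per-sample difference between highest
and lowest absorbance — is always computed over an explicit antigen subset,
because the interesting contrast is between the LNA-modified and unmodified
antigen groups. The test battery is deliberately classical: Welch's
unequal-variance t-test with Satterthwaite degrees of freedom, one-way ANOVA
by the pooled between/within decomposition (so the two-group F equals the
squared pooled t), simple OLS with a slope test for comparing assays, and
boxplot statistics with linear-interpolation quartiles (R's default type 7;
no convention was stated for the figures) and whisker arms at Q1 − 1.5·IQR
and Q3 + 1.5·IQR. All p-values are two-sided; no multiple-testing
correction is applied, matching the original analyses, and any correction is
left to the caller.

## Synthetic data: what it emulates, and what it does not

The generators are deterministic under their seeds and produce inputs
consumable by the downstream stages without editing:

* `gen_toy_complex()` builds a minimal two-chain system — an aromatic ring
  plus N–H donor facing a stacked ring plus acceptor — with an ideal
  hydrogen bond (2.9 Å, linear) and a parallel π-stack (3.4 Å) at contact,
  and a separation dial that destroys contact area and all detections. It
  uses idealized planar hexagons and linear D–H···A triples, sufficient for
  detector contracts but nothing like real residue geometry.
* `gen_trajectory()` toggles the donor–acceptor contact in and out of
  bonding geometry by seeded Bernoulli draws, so the detection chain can be
  checked against a known occupancy; detection reproduces the draws
  exactly, and the empirical fraction obeys binomial bands.
* `gen_sensorgram_set()` simulates the five-concentration two-fold series
  on the 60 s + 60 s schedule from the closed-form model.
* `gen_elisa_plate()` draws absorbances from zero-truncated normals with
  per-group location/scale, defaulting to the reported LNA (0.44/0.46)
  versus DNA (0.67/0.24) contrast, 30 samples. Because an A450 reading
  cannot be negative while the reported LNA SD exceeds its mean, the
  reported numbers are treated as location/scale of the parent normal, not
  as realised moments; the analytic truncated mean is available as
  `truncated_normal_mean()` for calibration checks. With these defaults the
  generated LNA group is reliably more disperse than the DNA group, which is
  the qualitative structure the dispersity analysis is meant to detect.

None of the generators emulate instrument noise spectra, plate-edge
effects, patient covariates or real antibody structure, so passing tests
demonstrate correctness of the computational chain, not clinical
performance.

## Problem sizes and numerical choices

The shipped tests run the whole chain at desk scale: strands of 10–63 nt
with brute-force screen verification up to 30 nt, toy frames of ≤ 15 atoms
with a 10⁵-point dense-grid SASA oracle, 200-frame trajectories, 5-curve
sensorgram sets with 100 seeded noise replicates for the recovery study,
and plates of 30–10⁴ samples. Ties and degenerate inputs fail loudly:
empty selections, overlapping selections, mismatched duplexes, constant
regressors, sub-minimal group sizes and unknown bond identifiers are all
errors rather than silent NA.
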