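---
title: "Methods: in silico peptide discovery with pepsilico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico peptide discovery with pepsilico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepsilico)
```

# Overview

`pepsilico` implements the computational core of an in silico workflow for
discovering bioactive peptides in food proteins, of the kind used to screen
fish muscle proteins for angiotensin-converting enzyme (ACE) and dipeptidyl
peptidase-4 (DPPIV) inhibitors. The pipeline has five stages:

1. **Virtual proteolysis** of protein sequences with named protease
   specificities, with the theoretical degree of hydrolysis.
2. **Release-frequency profiling** of the resulting fragments against a
   motif database of known bioactive peptides (the AE and W statistics).
3. **Physicochemical profiling** of proteins and peptides (masses, pI,
   GRAVY, aliphatic and instability indices, extinction coefficients,
   residue-class composition).
4. **Drug-likeness evaluation** of candidate peptides from sequence-derived
   descriptors (molecular formula, hydrogen-bond donors/acceptors, additive
   logP and TPSA estimates, Lipinski rule of five).
5. **Contact-based affinity scoring** of protein–peptide complex structures
   (interfacial contacts, non-interacting surface, a linear free-energy
   model, Kd conversion and stage-weighted docking score combination).

Machine-learned predictors (general and activity-specific bioactivity
scores, ML logP, ADMET endpoints) are deliberately out of scope: their
outputs are accepted as annotation columns and thresholded, never computed.
Docking itself is likewise out of scope; only the published score
combinations and the contact-based affinity model operate here, on
structures and energy components supplied as inputs.

# Virtual proteolysis

A protease is modelled as a set of cleavage-site patterns in a (P1, P1′)
grammar: the bond C-terminal to a residue in the P1 set is cleaved,
optionally conditioned on the following residue being in the P1′ set.
Digestion is exhaustive — every matching bond is cut, with no
missed-cleavage model, which matches how database "enzyme action" tools
operate. For a chain of length $L$ with $d$ cleaved bonds out of
$D = L - 1$ total peptide bonds, the theoretical degree of hydrolysis is

$$\mathrm{DH_t} = \frac{d}{D} \times 100\%$$

A single-residue chain has $D = 0$; DH is defined as 0 there (with a
logged note) to avoid 0/0. Fragments shorter than `min_length` residues
are excluded from the retained set — the default of 3 drops single
residues and dipeptides, the usual convention for counting "produced
peptides" — but all fragments still partition the input sequence, which is
the central invariant the test suite asserts on thousands of random
digests.

The shipped rule table for ficin, papain and stem bromelain
(`default_protease_rules()`) is a documented simplification: published
specificities for these cysteine proteases involve subsite preferences
(notably P2) that the (P1, P1′) grammar cannot express, and the reference
database's exact rule definitions are versioned and not public. The
defaults are therefore an editable convenience for exploration; every
quantitative test in this package uses explicitly constructed synthetic
rules, and users with a known specificity table should supply it via
`read_protease_rules()`.

# Release-frequency statistics

For a protein of $N$ residues, a protease and an activity label, the
frequency of release of active fragments is

$$A_E = \frac{d}{N}$$

where $d$ here counts retained fragments whose sequence exactly equals a
database fragment carrying that activity (full-sequence equality, with
multiplicity: the same sequence released at two loci counts twice). The
relative release frequency is

$$W = \frac{A_E}{A}$$

where $A$ is the occurrence density of activity-bearing database fragments
in the intact sequence: occurrences are counted at every start position,
overlaps allowed, each distinct database fragment counted separately, and
the total divided by $N$. This is the standard "frequency of occurrence"
reading of the denominator; since released exact matches are a subset of
substring occurrences, $A_E \le A$ under these conventions, and $W$ is
reported as `NA` (never infinity) when $A = 0$. Summed $\sum A_E$ tables
per (protease, activity) pair are produced by `activity_summary()`.
Absolute $\sum A_E$ values from the literature depend on the holdings of
the motif database used and are not reproduction targets; the computation,
not the holdings, is what this package provides.

# Physicochemical descriptors

All descriptors operate on the 20 canonical residues only; ambiguity codes
are rejected at parse time because silently accepted placeholders would
corrupt masses downstream.

* **Masses**: residue-mass sums plus one water, with both the IUPAC
  average table (the protein-calculator convention) and the monoisotopic
  table (the peptide-descriptor convention). The two routes —
  residue-mass sum and element-count sum over the molecular formula —
  agree to 1e-4 Da and are cross-checked in the tests.
* **GRAVY**: mean Kyte–Doolittle hydropathy, bounded by the scale extremes
  $[-4.5, 4.5]$.
* **Aliphatic index**: Ikai's formula
  $X_{Ala} + 2.9\,X_{Val} + 3.9\,(X_{Ile} + X_{Leu})$ in mole-percent.
* **Instability index**: the Guruprasad dipeptide-weight statistic
  $\frac{10}{L}\sum_i \mathrm{DIWV}(x_i, x_{i+1})$, classed unstable
  strictly above 40.
* **pI**: bisection on pH ∈ [0, 14] of the Henderson–Hasselbalch net
  charge over termini and D/E/C/Y/K/R/H side chains, to |charge| < 1e-4.
  The titration curve is strictly monotone, so the root is unique and the
  bracket choice is immaterial. A single Bjellqvist-style pKa set ships as
  the default; pI values from different web tools vary by ~0.1 pH unit
  because their pKa sets differ, so no tighter agreement should be
  expected or asserted.
* **Extinction coefficients** (Gill–von Hippel), **N-end-rule half-life**
  (a static lookup), charged-residue counts, and residue fractions over
  five classes (negative D/E, positive K/R, non-polar V/P/M/L/I/G/A,
  polar T/S/Q/N/H/C, aromatic Y/W/F — a complete cover of the alphabet).

# Drug-likeness descriptors

Peptide descriptors are computed from residue templates, i.e. from the
sequence alone:

* **Molecular formula**: element counts per peptide-bonded residue plus
  one water. **HBA** is the Lipinski convention N + O; **HBD** is the
  count of hydrogens on N or O, assembled from the N-terminal amine (2 H,
  or 1 for proline), one backbone amide H per non-proline residue after
  the first, side-chain donors (thiol S–H excluded), and the carboxyl
  O–H. These conventions reproduce the published worked values for the
  candidate peptides exactly (e.g. PPPS: HBA 10, HBD 4; MQML: 11/8;
  VNPYKWL: 20/14).
* **TPSA**: Ertl fragment-additive polar surface area from per-residue
  contributions in three backbone contexts (N-terminal, internal,
  C-terminal), with proline's tertiary amide nitrogen carrying the
  no-hydrogen fragment value.
* **logP**: a transparent additive estimate — Fauchère–Pliška side-chain
  octanol/water contributions plus a fixed backbone term per residue
  (−0.53) and a terminal-ionization penalty (−0.70). This deliberately
  replaces the machine-learned logP used by web ADMET services: it is
  documented, monotone and reproducible, but its absolute values are not
  comparable to ML predictions. Rule-of-five conclusions are therefore
  only asserted for peptides whose violation count is insensitive to the
  logP method (additive and ML estimates are both far below the 5 limit
  for short hydrophilic peptides).
* **Rule of five**: violations of MW ≤ 500, HBA ≤ 10, HBD ≤ 5, logP ≤ 5
  (all limits inclusive), counted in the classic four-criterion mode by
  default; an extended five-criterion mode adds TPSA ≤ 140 Å². Both modes
  exist because published peptide tables are not always internally
  consistent about which set was counted. The canonical logP ≤ 5
  compliance direction is implemented.

# Contact-based affinity scoring

A complex is two disjoint chain groups of heavy atoms parsed from a PDB
file (first model, first alternate location, hydrogens and waters
dropped, insertion codes folded into string residue keys). An
**interfacial contact (IC)** is an unordered cross-group residue pair with
any heavy-atom distance ≤ 5.5 Å; contacts are binned by the unordered
pair of residue polarity classes. The class map (charged D/E/H/K/R, polar
C/M/N/Q/S/T/W/Y, apolar A/F/G/I/L/P/V) ships as an editable argument
because the source model's map is not printed with it; no reproduction
target depends on the class assignment.

Surface residues are those with relative solvent accessibility ≥ 5% on
the complex, computed by a Shrake–Rupley sphere-sampling algorithm with a
fixed deterministic golden-spiral point set (960 points per atom, probe
1.4 Å) against the Tien et al. maximal-ASA reference — fixed points make
the result bit-reproducible across runs and platforms. **Non-interacting
surface (NIS)** residues are surface residues in no IC; the three class
percentages are taken over the NIS residues and sum to 100.

The binding free energy is the printed linear model

$$\Delta G = -0.09459\,\mathrm{IC}_{cc} - 0.10007\,\mathrm{IC}_{ca}
+ 0.19577\,\mathrm{IC}_{pp} - 0.22671\,\mathrm{IC}_{pa}
+ 0.18681\,\%\mathrm{NIS}_{apolar} + 0.3810\,\%\mathrm{NIS}_{charged}
- 15.9433$$

in kcal/mol; charged–polar and apolar–apolar contacts carry zero weight,
exactly as printed — the zero-weight terms are carried as fields without
guessing the intent of their omission. The dissociation constant follows
from $\Delta G = RT \ln K_d$ with $R = 1.9872 \times 10^{-3}$
kcal K⁻¹ mol⁻¹ and $T = 298.15$ K by default; the conversion and its
inverse round-trip to machine precision. Published Kd tables printed next
to ΔG rounded at 0.1 kcal/mol back-calculate only to within ~5%, so
comparisons against such tables use a 10% tolerance. Stage-weighted
docking score combinations (it0/it1/itw) evaluate the printed weights on
supplied energy components; note the water-refinement stage has no
buried-surface-area term.

# Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, deterministically
under a seed:

* `generate_proteins()` draws i.i.d. residues from a specified
  composition. Real proteins have local composition structure, repeats and
  domain organization; none of that is emulated, which is irrelevant for
  the partition/counting properties under test but means release-frequency
  magnitudes on synthetic data should not be read as biologically typical.
* `generate_motif_db()` builds small motif tables, optionally sampling
  fragments out of given parent sequences so that occurrences are
  guaranteed.
* `generate_toy_complex()` lays two chains of compact 5-atom residue
  clusters (backbone N, CA, C, O plus one side-chain atom; glycine has 4)
  on a grid with 10 Å spacing, placing the first `n_contacts` chain-B
  residues at a center distance within [6, 6.8] Å of their chain-A
  counterparts and all others at ≥ 15 Å. Within that window the geometry
  guarantees — by construction, accounting for the 1.5 Å atom extent and
  for glycine's missing side-chain atom — that exactly the engineered
  pairs have a heavy-atom distance within the 5.5 Å cutoff and that no
  atoms overlap (closest approach ≥ 3.2 Å). The generator's declared
  contact list is therefore an independent ground truth for the contact
  module, not a recomputation. The clusters are not stereochemically
  realistic side chains; they exercise contact and surface logic, not
  energetics.
* `candidate_peptides()` bundles the twelve milkfish muscle-derived
  candidate peptides with their published external bioactivity score
  annotations, used by the screening stage.

# Screening thresholds and target classes

Screening uses two thresholds from the source workflow: a general
bioactivity score ≥ 0.7 for retention and an activity-specific score
≥ 0.5 for a per-activity flag; missing scores ("−" in published tables)
count as below threshold. When peptides are grouped into receptor target
classes, `exclusive_groups = TRUE` assigns each peptide to the first
listed class with a firing flag. This exists because the study grouping
assigns a peptide that is flagged for both the antihypertensive and the
antidiabetic families to the more specific antidiabetic/DPPIV class (it
was docked against DPPIV); with the DPPIV class listed first, the twelve
bundled candidates split 9 (ACE/antihypertensive) and 3
(DPPIV/antidiabetic), matching the published counts. The non-exclusive
flags remain available and are reported separately.

# Numerical choices and problem sizes

* All output tables are TSV with a header row and 4-decimal floating
  point, for reproducible diffs; the run manifest (JSON) records the
  package version, every stage parameter and MD5 digests of all inputs
  and outputs. Two runs of the same configuration are byte-identical;
  timestamps are quarantined to the log file.
* Property-based suites run at sizes chosen to give dense coverage while
  keeping the default test run fast on a single CPU: 1000 random digests
  for the partition/oracle properties, 1000 random release-statistic
  cases, 100 random toy complexes for the contact oracle, and 200
  sequence pairs for mass additivity/cross-consistency.
* The pI bisection uses 200 iterations maximum with a 1e-4 charge
  tolerance; convergence is guaranteed by monotonicity.
* SASA uses 960 sphere points; the single-atom analytic case
  $4\pi(r + r_{probe})^2$ is exact by construction since every point of
  an isolated sphere is accessible.

# Known limitations

* Cleavage specificities restricted to the (P1, P1′) grammar cannot
  express subsite (P2/P1′ combination) preferences of real cysteine
  proteases; the shipped defaults are approximations.
* The additive logP is a screening-grade estimate; do not compare its
  absolute values with ML predictors.
* The affinity model is the published protein–protein linear form applied
  to protein–peptide interfaces, inheriting whatever bias that implies;
  this package evaluates the printed model and does not refit it.
* No missed cleavages, no post-translational modifications, no
  multi-model NMR structures, no mmCIF.
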