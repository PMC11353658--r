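# pepsilico

In silico discovery and profiling of bioactive peptides from food
proteins, in R.

Food-protein hydrolysates are a rich source of short peptides with
pharmacological activity — most prominently inhibitors of
angiotensin-converting enzyme (ACE, the antihypertensive target) and of
dipeptidyl peptidase-4 (DPPIV, the antidiabetic target). Before any wet-lab
work, candidate peptides are routinely discovered on the computer: protein
sequences are digested virtually with food-grade proteases, the released
fragments are matched against databases of known bioactive peptides,
and the survivors are profiled for physicochemical suitability,
drug-likeness and predicted binding to the target enzyme. `pepsilico`
implements that workflow as a tested, reproducible R package for
bioinformaticians and food scientists running peptide-discovery screens.

## What it computes

**Virtual proteolysis.** Protease specificities are (P1, P1′) cleavage
rules; digestion is exhaustive at every matching bond. For $d$ cleaved
bonds of $D = L - 1$ total, the theoretical degree of hydrolysis is
$\mathrm{DH_t} = d/D \times 100\%$. Fragments shorter than 3 residues are
excluded from the retained peptide set by default.

**Release-frequency statistics.** For a protein of $N$ residues and an
activity label, $A_E = d/N$ (with $d$ the retained fragments exactly
matching a database fragment of that activity) and $W = A_E / A$, where
$A$ is the overlapping-occurrence density of activity-bearing database
fragments in the intact sequence.

**Physicochemical profiling.** Average/monoisotopic masses, theoretical
pI (Henderson–Hasselbalch bisection), GRAVY, aliphatic index, Guruprasad
instability index, Gill–von Hippel extinction coefficients,
charged-residue counts and five-class residue composition.

**Drug-likeness.** From residue templates: molecular formula,
monoisotopic mass, Lipinski hydrogen-bond acceptors (N + O) and donors
(H on N/O), additive logP and Ertl-fragment TPSA estimates, and
rule-of-five violation counts (MW ≤ 500, HBA ≤ 10, HBD ≤ 5, logP ≤ 5,
optionally TPSA ≤ 140).

**Contact-based affinity.** From a two-group complex structure:
interfacial contacts (heavy-atom pairs within 5.5 Å, classed
charged/polar/apolar), non-interacting-surface percentages (Shrake–Rupley
RSA ≥ 5%), the linear free-energy model

ΔG = −0.09459 IC(cc) − 0.10007 IC(ca) + 0.19577 IC(pp) − 0.22671 IC(pa)
\+ 0.18681 %NIS(apolar) + 0.3810 %NIS(charged) − 15.9433 kcal/mol,

the conversion ΔG = RT ln Kd (T = 298.15 K), and stage-weighted docking
score combinations (it0/it1/itw). Docking itself and machine-learned
bioactivity/ADMET scores are out of scope: scores are accepted as input
annotations and thresholded (general ≥ 0.7, specific ≥ 0.5), never
computed.

## Worked example

```r
library(pepsilico)

rule <- protease_rule("trypsin-like", list(p1 = c("K", "R")))
digest("AAKAARAA", rule)
#> digest of 'query' with trypsin-like: 3 fragment(s), 2 retained (length >= 3)
#>   d = 2 cleaved bonds of D = 7; DH = 28.5714%
```

The eight-residue toy protein has 7 peptide bonds; the K/R rule cuts 2 of
them (after K3 and R6), a 28.57% degree of hydrolysis, and the terminal
dipeptide `AA` is dropped from the retained set.

```r
peptide_descriptors(c("PPPS", "PPPPV", "MQML"))
#>   sequence      formula  mw_mono hba hbd logp_est tpsa_est ro5_violations
#> 1     PPPS   C18H28N4O6 396.2009  10   4    -0.70   139.28              0
#> 2    PPPPV   C25H39N5O6 505.2900  11   3     0.75   139.36              2
#> 3     MQML C21H39N5O6S2 521.2342  11   8     1.12   193.71              3
```

PPPS — a collagen-derived tetrapeptide — passes the rule of five with no
violations (396.20 Da, 10 acceptors, 4 donors, logP well under 5), which
is what makes it an orally plausible ACE-inhibitor candidate; PPPPV
violates two rules (mass over 500 Da, 11 acceptors).

```r
kd_from_dg(-12.3)
#> [1] 9.638692e-10
```

A predicted binding free energy of −12.3 kcal/mol corresponds to a
sub-nanomolar dissociation constant at 25 °C.

End-to-end runs are driven by `run_pipeline()` (or the thin CLI wrapper in
`inst/cli/pepsilico`) from a YAML config, producing per-stage TSVs and a
JSON manifest with input/output digests; identical configs give
byte-identical outputs.

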