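---
title: "Profiling voltage-sensor flexibility from sequence: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling voltage-sensor flexibility from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdflex)
```

# The model

The package estimates the *intrinsic* (composition-determined) flexibility of
voltage-sensor-domain segments from primary sequence. The underlying model is
deliberately simple and interpretable:

1. Each residue type carries a **normalized B-value** — a dimensionless
   propensity derived from crystallographic temperature factors, averaged over
   many structures and scaled so that the 20 values have mean ≈ 1. High
   values on a flexibility-oriented scale mean mobile side chains (Lys, Glu,
   Asn, Ser…); low values mean rigid ones (Trp, Phe, Ile, Val…).
2. The effective flexibility of a *position* depends on its sequence
   neighbors, so raw values are smoothed with a symmetric window
   (default: 9 residues, triangular weights peaking at the center).
3. A *segment* is summarized by the mean of its smoothed values, the mean
   B-factor `mBf`, and reported as the **flexibility index `1/mBf`**.
4. Segments are anchored at the **NxxD motif** — the conserved
   Asn-x-x-Asp at the N-half of S3 whose aspartate belongs to the charge
   transfer center — and run to annotated transmembrane boundaries:
   S3 (anchor → S3 C-end), S3–S4 (anchor → S4 C-end), S1–S4 (S1 N-start →
   S4 C-end). Some families substitute the asparagine (FxxD in CNG
   channels; Cys/Ser in KCNQ), so the anchor search supports those
   positional variants, with the aspartate always required.

The model ignores everything the sequence alone cannot see: tertiary
packing, lipid contacts, experimental B-factor artefacts, and dynamics. It is
a propensity profile, not a molecular-dynamics observable.

## Scale identity and orientation

Published channel tables label their index "1/mBf" yet assign *larger*
values to the more flexible families (CNG ≈ 1.77 vs Hv1 ≈ 1.40). For
`1/mBf` to grow with flexibility, the underlying per-residue scale must be
**rigidity-oriented** (larger raw value = more rigid). The package therefore
ships three scales (TSV files under `inst/extdata/scales/`, swappable by
path so exact published value sets can be substituted):

* `rigidity` (default) — the Vihinen-type normalized B-values reflected
  about their mean (`v' = 2·mean(v) − v`). Larger segment index = more
  flexible, matching the orientation of the published tables.
* `vihinen`, `karplus_schulz` — flexibility-oriented normalized B-value
  sets, for auditing the orientation choice.

Because every packaged scale is normalized (mean of the 20 values within
[0.9, 1.1] — enforced by `validate_scale()`), segment indices computed here
sit near 1, not near the 1.4–1.8 magnitudes of the published tables; those
magnitudes imply per-segment mean raw values around 0.6, which no normalized
scale can produce. The exact scale pair behind the published magnitudes is
not identified in the source literature, so the package treats *ordering*
(which families are more flexible) as the reproducible quantity and keeps
the published index values available as a packaged data table
(`load_functional_table()`) rather than recomputing them.

## Consensus, dispersion and logos

A family alignment is reduced to per-column frequencies
(`column_profiles()`); gaps and `X` are excluded from the frequency
normalization and tracked as `gap_fraction`. The rank-1..3 consensus
sequences take the first, second and third most frequent residue per column
(`build_consensus_set()`). The index is computed from the rank-1 consensus;
the second and third ranks contribute as a **dispersion**, the population
standard deviation of the (≤ 3) rank indices — a literal reading of
"composition enters as a standard deviation". Logo matrices
(`logo_matrix()`) use Shannon information in bits, `log2(20) − H`, with *no*
small-sample correction: the uncorrected form is depth-independent and keeps
small test alignments exactly comparable to large ones.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_length` | 9 | residues | Neighbor influence decays within ±4 positions, the classic propensity-profile window |
| `window_weights` | triangular | — | Peak at the central residue; symmetric; renormalized to sum 1 |
| salt-bridge `cutoff` | 4.0 (inclusive) | Å | The standard donor-nitrogen / carboxylate-oxygen contact criterion |
| `classify_flexibility` thresholds | (1.53, 1.63) | index units | See below |
| `k` consensus ranks | 3 | — | Rank-1 consensus plus two dispersion ranks |
| permutation `n_mc` / `exhaustive_max` | 9999 / 8 | — | Exhaustive enumeration up to 8! = 40320 permutations; seeded Monte Carlo beyond |

## Classification thresholds

With `thresholds = "tertile"` the 1/3 and 2/3 sample quantiles of the
supplied indices are used. The packaged default is instead the explicit pair
(1.53, 1.63), with boundary ties going to the lower (more rigid) class.
Rationale: the published verbal grouping (TRPV, Hv1, KCNQ rigid; CNG
flexible) is *not* a tertile cut of the printed per-channel indices — on the
24 tabulated values the lower tertile break falls at 1.51, just below
KCNQ4's 1.53, while TRPM/TRPA channels verbally grouped as flexible print
1.50–1.51. The fixed pair reproduces every named membership on the packaged
table and is what downstream users get by default; tertile mode remains
available for de-novo family sets.

# Structural geometry

`read_structure()` parses PDB and mmCIF files (first model, hydrogens
dropped, one conformer per atom: highest occupancy, then alphabetical
altloc). Donor/acceptor sets follow the charge-transfer-center chemistry:
Lys Nζ; Arg NE/NH1/NH2 (published atom lists sometimes write the arginine
set with a ζ label — arginine has no Nζ atom, so the guanidinium nitrogens
are used and the discrepancy documented rather than silently corrected);
Asp OD1/OD2; Glu OE1/OE2 (glutamate is accepted alongside aspartate because
the same measurement is applied to Glu counter-charges, e.g. in TRPV1).
`detect_salt_bridges()` reports every donor-atom × acceptor-atom distance
with `is_bridge = distance ≤ 4.0 Å`, inclusive exactly as the criterion is
stated. `superpose_motif()` performs least-squares Cα superposition
(Kabsch, via SVD with a determinant guard against reflections); the test
suite cross-checks it against an independently coded quaternion method.

# The functional table and the summary fit

`load_functional_table()` returns the packaged transcription of the
published channel comparison tables: S3/S3–S4/S1–S4 indices, charge per
channel *e₀*, Q<sub>10</sub> of activation/inactivation kinetics, and
stretch-induced ΔV<sub>1/2</sub> shifts. Interval notations
("12 – 16", "~ 9", "−8.8 ± 1.3", "> 100", "n.d.") parse to lower/upper
bounds; the **midpoint** represents an interval wherever a single number is
needed (the least-assumption choice for fitting), with the bounds retained
for reporting.

The family-level summary curve is the modified single exponential
`f(x) = a·exp[b/(x + c)]`, fitted by Levenberg–Marquardt least squares with
the pole `x = −c` box-constrained outside the data range. Default start:
`a = max(y)`, `c = 1`, `b` from the log-ratio of the two x-extreme points.
The published fit does not state its x-variable, so
`fit_flexibility_curve()` exposes both candidates and the package reports
both: **family rank** (families ordered by decreasing index — the order in
which the family distributions are plotted) and **gating-charge midpoint**.
On the packaged table the rank fit attains the published-scale goodness of
fit while the charge fit does not, which is why rank is documented as the
primary choice; `fit_flexibility_curve()` additionally polishes over a
small fixed start grid so the reported optimum does not depend on a single
initialization. R² is `1 − SSres/SStot` throughout.

Association machinery: Spearman's ρ with a two-sided permutation p-value —
exhaustive over all n! permutations for n ≤ 8, seeded Monte Carlo above —
and an exact (fixed-margin) class × trait test via `class_association()`.

# The synthetic-data generators

`generate_family_alignment()` draws every cell independently from a
per-column composition (star topology), implants the anchor motif in every
record, and applies substitution noise everywhere except the motif columns.
It emulates what the pipeline needs from real family alignments — controlled
column composition, a known anchor, known boundaries — and deliberately
omits what real alignments also contain: phylogenetic correlation between
records, indel structure beyond uniform gap columns, and covariation between
positions. Passing the recovery tests therefore demonstrates that the
pipeline is *correct* (it finds what was implanted and ranks families by
their true mean propensity), not that real families are this easy;
conservation structure in real data is handled by the same code paths but
with no ground truth to check against.

`generate_toy_structure()` writes fixed-column PDB files in which each
donor/acceptor pair sits at a prescribed minimum distance (the B-factor
column carries the residue's raw scale value, a self-documentation
convenience). `generate_functional_table()` simulates channels over the
three flexibility classes with per-class trait probabilities and an optional
deterministic index→Q<sub>10</sub> map. All generators are pure functions of
their spec and seed, and restore the caller's RNG state.

# Numerical choices and degenerate inputs

* **Window edges**: truncate-and-renormalize (mirror and drop-edge were
  rejected so that a homopolymer maps exactly to its raw residue value).
* **Sentinels**: consensus ranks that do not exist (fewer distinct residues
  than ranks) and majority-gap columns (`gap_fraction ≥ 0.5`) become `NA`
  sentinels, skipped by smoothing and excluded from rank dispersion;
  all-gap columns additionally warn.
* **Ties**: equally frequent residues rank alphabetically by one-letter
  code (deterministic, record-order independent); classification boundary
  ties go to the lower class.
* **Coordinates**: 1-based positions, half-open `[start, end)` windows
  everywhere, including the BED-like TSV export.
* **Multiple anchor matches**: the pipeline takes the first match at or
  after the annotated S1 N-start that still lies inside the annotated S3.
* **Exactness**: `index` is stored as the computed reciprocal of `mBf`, so
  the pair is consistent by construction; distances are plain Euclidean
  norms; the inclusive cutoff uses `<=` with no tolerance padding.
* **Determinism**: pipeline outputs are byte-identical under a fixed
  configuration and seed (the manifest deliberately records no timestamp).

## Null calibration of the association tests

The test suite checks calibration under the null at modest sizes: Monte-Carlo
permutation p-values of independent pairs (n = 12, 499 permutations,
200 seeded replicates) are compared to the uniform distribution by a
Kolmogorov–Smirnov test, and the exact class × trait test is required to be
valid (its rejection rate at nominal 5% may not exceed it beyond sampling
error) — exact tests on small discrete tables are conservative by
construction, so uniformity is the wrong target for them and validity is
what is asserted.

# Problem sizes used in validation

The shipped tests run entirely on data built in code: random alignments of
8–12 records × 15–21 columns (≥ 1000 random columns for the order-invariance
and monotonicity properties), synthetic families of 40–80 records × 40–50
columns, toy structures of 2–20 residues, exhaustive permutation checks at
n = 5–6, and 200-replicate calibration runs. These sizes were chosen so the
whole suite documents the pipeline's properties in well under a minute of
compute while still exercising every code path; nothing in the
implementation is specific to them, and the pipeline has no intrinsic limits
below thousands of sequences per family.

# Known limitations

* The exact published flexibility-scale pair is unidentified; packaged
  indices match published magnitudes only through the fixture table, not
  through recomputation (orderings are reproducible).
* Segment boundaries are *inputs* (UniProt-style annotations); the package
  never predicts transmembrane topology.
* The dispersion treats the three consensus ranks as equally plausible
  sequences; it is not a per-position uncertainty.
* Structure geometry is purely distance-based: no pKa, no electrostatic
  energies, no symmetry mates, no cryo-EM map handling.
* The synthetic generator's star-topology sampling understates the column
  frequency variance of phylogenetically structured families.
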