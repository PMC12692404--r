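---
title: "Multi-condition activity modeling with perturbation-theory descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-condition activity modeling with perturbation-theory descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell-based screening of anti-proliferative compounds produces GI50 values
(the concentration inhibiting 50% of cell growth) measured under
heterogeneous experimental conditions: different cell lines with different
doubling times and different microsatellite phenotypes. A conventional
QSAR model must be fit per condition, fragmenting the data. The
perturbation-theory machine-learning (PTML) approach instead trains one
classifier across all conditions by turning each raw molecular descriptor
into a *perturbation*: the deviation of the molecule from the
condition-specific expectation. ptmlfbtd implements that pipeline end to
end — descriptors, label fusion, feature selection, a shallow neural
classifier with an applicability domain, and the fragment-based
topological design (FBTD) readouts used to interpret the fitted model.

## Molecular graphs and descriptor families

SMILES are parsed through OpenBabel (ChemmineOB/ChemmineR) into
hydrogen-suppressed graphs. Three families of graph-theoretical indices
(GTIs) are computed:

1. **Weighted bond-based spectral moments** `SM(PP)o`: traces of powers of
   the bond adjacency matrix `E` (bonds are vertices; two bonds are
   adjacent when they share an atom), with the diagonal loaded by a
   physicochemical bond weight. Orders `o = 1..7` are computed. Because
   `tr(E^o)` expands as a sum over closed walks of length `o`, each moment
   aggregates contributions of molecular fragments with up to `o` bonds.
   Seven weighting schemes are available: standard bond distance (`Std`),
   bond dipole moment (`Dip`), hydrophobicity (`Hyd`), polar surface area
   (`Psa`), molar refractivity (`Mol`), Gasteiger–Marsili charges (`Gas`)
   and atomic weight (`Ato`). Atomic contributions `p_i` are spread over
   bonds by `w(i,j) = p_i/δ_i + p_j/δ_j`, the standard convention for
   bond-based spectral moments; the paper trail of every contribution
   table ships as a commented CSV under `inst/extdata`.
2. **Kier–Hall valence connectivity indices** `Xv(SG)m`: sums over
   connected `m`-edge subgraphs of a structural type of
   `Π δv^(-1/2)` over subgraph atoms, with
   `δv = Zv − h` (second period) or `(Zv − h)/(Z − Zv − 1)` beyond, and
   `Zv` adjusted by formal charge.
3. **Bond connectivity indices** `e(SG)m`: the bond-centred analogue using
   edge degrees `ε(i,j) = δ_i + δ_j − 2` taken in the whole graph.

Subgraph types follow the Kier–Hall partition: path (`P`), cluster (`C`),
path-cluster (`PC`) and ring/chain (`Ch`, any subgraph containing a
cycle). Orders `m = 1..6` are enumerated exactly by compiled code that
grows connected edge sets with a canonical anchor rule (no duplicates);
correctness is tested against brute-force subset filtering.

Every index also has a partially normalized twin (`N` prefix): the raw
value divided by the bond count `L`. The full grid is 2 × (49 + 24 + 24)
= 194 columns per molecule.

### Numerical choices

* Aromatic bonds count as single edges for all topology; bond-table
  weighting schemes carry dedicated aromatic entries (order `ar`).
* A two-heavy-atom molecule has an `ε = 0` bond; such subgraphs contribute
  zero to `e(SG)m` rather than raising an error. Real modeling datasets
  never contain them because of the 130 g/mol mass floor.
* Gasteiger charges: 8 damped iterations (factor `0.5^k`) of the partial
  equalization of orbital electronegativities over the
  hydrogen-complete graph, seeded with formal charges; hydrogen charges
  are folded back into the bearing heavy atom, so charges sum exactly to
  the net molecular charge.
* The `Hyd`/`Mol` atom typing is a deliberately coarse (~30-type)
  adaptation of the Wildman–Crippen scheme keyed on element,
  hybridization and first neighbour shell; the installed R stack has no
  SMARTS matcher and the original modeling software's tables are
  unpublished, so descriptor values are defined by — and reproducible
  against — the shipped tables, not against any external program.

## Assay curation and the 3:1 split

Raw records (`molecule_id`, `smiles`, `gi50_nm`, `condition_id`) are
curated with the usual rules: missing or multi-component SMILES dropped,
non-positive or unitless activities dropped, molar mass restricted to
130–854 g/mol, duplicates per (molecule, condition) collapsed to the
lowest GI50. A molecule–condition case is labeled active (`ACRC = +1`)
iff GI50 ≤ 1900 nM (configurable). The train/test split sorts cases by
increasing GI50, then condition, then molecule id, and walks blocks of
four: positions 1–3 train, position 4 test; a trailing partial block goes
to training. Equal-GI50 ties are broken by molecule id — the sort would
otherwise be ambiguous.

## Box–Jenkins fusion

For each condition element (doubling-time class `dt`, cell line `ct`,
microsatellite status `mc`) and each label, the reference
`avg[GTI]ej` is the mean of the descriptor over *active training cases*
carrying that label; `n(ej)` is their count, `p(ej) = n(ej)/T` with `T`
the total training-case count, and `sdv[GTI]` is the population standard
deviation over all training cases (the population form is chosen because
the training set is treated as the reference population; the choice only
rescales all fused values of a column by a common factor). The fused
perturbation descriptor is

```
D[GTI]ej = (GTI − avg[GTI]ej) / (sdv[GTI] · p(ej))
```

computed separately for `dt`, `ct` and `mc`, tripling the pool to 582
candidate inputs. Constant descriptors are excluded; labels with no
active training case make prediction for that label impossible, and the
package raises rather than imputes. By construction the mean of `D` over
active training cases of a label is zero — an identity the tests assert
to 1e−9.

## Feature selection

Each fused column is discretized by equal-width binning (Sturges' rule
over the training range) and scored by three information-theoretic
metrics: differential Shannon entropy `DSE = SE(pooled) − [SE(active) +
SE(inactive)]/2` (clamped at zero), gain ratio `GR = IG/H(X)` and
symmetric uncertainty `SU = 2·IG/(H(X)+H(C))`. Candidates are ranked by
the geometric mean `GMV = (DSE·GR·SU)^(1/3)` and filtered greedily: a
descriptor is kept only when its Pearson correlation with every
already-kept descriptor lies strictly inside (−0.7, 0.7), keeping the
higher-GMV member of any correlated pair. The first 20 survivors become
the model inputs. The binning and the DSE form are this package's
documented definitions; the original feature-ranking software does not
publish its internals.

## The classifier

A single-hidden-layer perceptron (inputs = 20 selected `D[GTI]ej`,
hidden layer 20–60 units, 2 softmax outputs) is trained by full-batch
BFGS on the cross-entropy via `nnet`. Hidden activation is logistic —
`nnet`'s fixed choice; the restart search therefore explores hidden-layer
size and weight decay instead of activation functions. `ProbAct` is the
softmax probability of the active output; a case is predicted active iff
`ProbAct > 0.5` (strict, so exactly 0.5 maps to inactive).

Model selection carves an internal monitoring fold (25%, stratified)
from the training cases. Each of `restarts` networks (package default
20, with 6 retained — desk-scale values; large-scale protocols of
1000/300 are available through `ptml_config()`) is scored on that fold by
the mean of global sensitivity/specificity averaged with the mean of all
per-label local metrics; the best network is kept. The held-out test set
plays no role in any of this.

The capacity parameter `ρ = T / [(I+1)H + (H+1)O]` is stored with the
model and a warning is issued below 2, the conventional overfitting-risk
reading. The applicability domain is a bounding box: per input, the
closed interval `[min, max]` over correctly classified training cases;
a query case scores `LSAD = 1` per input inside its interval, `TSAD =
Σ LSAD`, and is inside the domain iff `TSAD = K` (all 20). Endpoint
values count as inside.

The fitted bundle (weights, topology, selected ids, fusion statistics,
AD bounds, seed, versions) serializes to a single JSON file;
`ptml_load()` restores predictions bit-for-bit.

## FBTD interpretation

* **Sensitivity values**: per input, the column is replaced by its
  training mean and the cross-entropy error ratio to the full model is
  reported (`SV = 1` ⇒ no influence). Mean substitution rather than
  permutation keeps the measure deterministic.
* **Tendency of variation**: class-conditional means over correctly
  classified cases; an input whose active mean exceeds its inactive mean
  should *increase* to favour activity, and conversely. Ties within
  1e−12 are `Indeterminate`.
* **Subgraph census**: `subgraph_census()` reports counts per
  (type, order), the quantities through which important inputs are read
  back as molecular fragments.
* **Multi-cell verdict**: a molecule predicted active in at least
  `ceil(4/7 · n)` of `n` conditions (4 of 7 at the default registry) is
  a multi-cell active candidate.
* **Druglikeness**: Lipinski (HBA ≤ 10, HBD ≤ 5, MW < 500, logP ≤ 5) and
  Veber (RBN ≤ 10, PSA < 140 Å²) checks. The Lipinski logP is
  `AvgLogP = (MlogP + AlogP)/2` when both estimates are supplied — with a
  single estimate the check would flag borderline molecules
  inconsistently with how mixed-estimate profiles are normally read.
  Boundary semantics are exact: MW = 500 violates, HBA = 10 passes.

## The synthetic study

No public accession reproduces the original screening table, so the
package ships a generator that emulates its structure at desk scale and
makes every stage testable. Molecules are assembled from a fragment
grammar (aromatic/heteroaromatic cores, linkers, substituents — methoxy,
trifluoromethyl, tert-butyl, piperazine and friends, the moieties the
FBTD readouts care about), deduplicated and mass-filtered. Each molecule
is "assayed" under all seven registry conditions; activity is drawn from
a planted logistic model

```
logit P(active) = β0 + Σ βi·zi + γ(condition)
```

over standardized planted descriptors (defaults: `NSM(Psa)1` with
β = −2.5, `SM(Hyd)1` with β = +2.0, `Xv(P)2` with β = −1.5 — polarity
down, hydrophobicity up, accessibility down), with small per-condition
offsets γ and the intercept solved so the expected active fraction is
0.45, matching the class balance of the emulated study. GI50 is then
drawn log-normally on the matching side of the 1900 nM threshold (median
≈ 350 nM for actives, ≈ 25000 nM for inactives, sdlog 0.9), so the label
and the threshold rule agree by construction.

The default study size is 400 molecules × 7 conditions = 2800 cases
(2100 train / 700 test after the 3:1 split) — large enough for the
pipeline's statistics to stabilize while a full run (generation,
descriptors, selection, 20 training restarts) completes in a few minutes
on one core. On this dataset the trained classifier recovers the planted
signal with held-out sensitivity and specificity above 80%, and the
selected inputs track the planted descriptors.

What the generator does *not* emulate: real structure–activity
landscapes (activity cliffs, scaffold-specific effects), assay noise
correlated across conditions, and the chemical diversity of a real
screening library. Green tests on synthetic data therefore demonstrate
the correctness of the machinery, not predictive validity on real
screens.

## Known limitations

* Descriptor values are defined by the shipped contribution tables; they
  will not numerically match closed-source implementations whose tables
  are unpublished.
* Aromaticity is taken from OpenBabel's perception, restricted to bonds
  on rings.
* `MlogP` is not computed from structure; profiles built from SMILES use
  the atom-contribution logP alone for the Lipinski check.
* The MLP explores logistic hidden units only; exponential/tanh hidden
  activations would require a bespoke trainer for no expected accuracy
  gain at this depth.
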