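---
title: "Local structural similarity restraints: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local structural similarity restraints: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lssr)
```

## The model

Two NCS-related chains — or a structure under refinement and a fixed
reference ("target") structure — are similar when equivalent short-range
interatomic distances agree. For an atom pair (i, j) in one copy and the
equivalent pair (i′, j′) in the other, the quantity restrained is the
distance difference

$$\Delta_{ij} = \lvert r_{ij} - r_{i'j'} \rvert .$$

Working on distance *differences* has two consequences that distinguish the
approach from superposition-based NCS restraints: no superposition or domain
definition is ever needed (the restraint is invariant to the relative
placement of the copies), and no particular distance is favoured — only
*similarity* between the copies.

Each difference is penalised with a plateauing function

$$V(\Delta) = V_{\max}\left[1 - \exp\!\left(-\alpha\,\Delta^2/\sigma^2\right)\right],
\qquad \alpha = \ln\!\frac{V_{\max}}{V_{\max}-1},$$

where $\alpha$ is fixed by the normalisation $V(\sigma) = 1$. The functional
form is the package's own choice; what is pinned down externally is the
constraint set it satisfies: $V(0)=0$, harmonic behaviour as
$\Delta \to 0$ (the ratio $V/\Delta^2$ tends to
$V_{\max}\alpha/\sigma^2$), $V(\sigma)=1$ exactly, essential flatness above
0.7 Å ($V(0.7) \ge 0.99\,V_{\max}$ at the defaults) and saturation at
$V_{\max}$. The test suite asserts those constraints rather than any one
closed form. The plateau is the scientific point: genuine conformational
differences between copies cost a bounded constant and are otherwise left
alone, which is what makes fully automatic NCS restraints tolerable without
manual exception lists.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `sigma`   | 0.2 | Å | similarity scale; $V(\sigma) = 1$; harmonic region below |
| `v_max`   | 3   | — | plateau height; must exceed 1 for the normalisation |
| `cutoff`  | 5.5 | Å | pair included iff closer than this in *either* copy (strict `<`) |
| `weight`  | 1   | — | per-list weight $w$ multiplying the summed penalty |

The 5.5 Å cutoff keeps the restraints local while still spanning the
hydrogen-bonding geometry of helices and sheets. Whether the cutoff is
strict or inclusive is not externally specified; "closer than" is read as
strict `<` and tested as such.

The total over a restraint list is $w \sum_k V(\Delta_k)$. With $N$
NCS-related chains, every unordered chain pair gets its own independent
list, so each chain belongs to $N-1$ lists; the automatic weight rule
`autoncs_weight(W, N) = W/(N-1)` keeps the aggregate pull on an atom
roughly constant as the group grows. The exact published adjustment formula
is not legible in the source material; the $1/(N-1)$ rule is this package's
choice, motivated by that pair-count argument, and reduces to no adjustment
for a single pair.

## Building restraint lists

**Selection.** Waters are excluded (equivalent waters would need identical
numbering to pair at all); hydrogens are excluded by default (heavy-atom
X-ray regime); hetero groups such as haems and ligands are kept. Alternate
locations are reduced to one conformer per atom — first-listed by default,
highest-occupancy optionally. The altloc policy is a documented choice, not
an externally specified one.

**NCS detection.** Equivalence is purely nomenclature-based: paired atoms
share atom name and residue number (plus insertion code); for target
restraints also the chain id. Two chains are NCS-related when more than
80 % of residues with matching residue numbers share a residue name; the
denominator is the count of residue numbers present in both chains
(unmatched numbers cannot vote), and hetero residues participate. Groups
are connected components of the pair graph. No sequence alignment is
attempted — chains with incompatible numbering are out of scope.

**Pair rules.** An unordered pair (i, j) enters the list iff both atoms are
matched, the bond-path separation is at least 3 bonds (1–2 and 1–3 pairs
belong to bond/angle terms; 1–4 pairs *are* restrained), and the pair is
closer than the cutoff in either copy. Covalent topology comes from
standard amino-acid connectivity plus peptide links (consecutive residues,
C–N ≤ 2.5 Å), disulfides (SG–SG ≤ 2.3 Å) and, for residue types without a
table entry (haems, ligands), distance-based bonding at ≤ 1.9 Å with a
warning. Pair inclusion is decided once at build time, giving a stable
objective during minimisation; enumeration is validated against an
all-pairs brute-force oracle in the tests.

## Pruning

Plateauing reduces but does not eliminate the need to remove restraints for
residues with genuinely distinct conformations: completely distinct regions
still have some distances close by chance, and coupling those is harmful.
Two rules operate per residue (a restraint "belongs" to a residue through
either of its copy-1 atoms):

1. **Plateau ratio.** $\rho = \sum V(\Delta) / (V_{\max} N)$ over the
   restraints touching the residue. $\rho > 0.5$ (strictly) means the
   residue's environments are mostly in the plateau — distinct — and every
   restraint touching it is turned off. The ratio uses unweighted
   penalties, so it is independent of the list weight.
2. **Gradient rule** (optional). Residues that are *distinct but similar*
   sit on the penalty's shoulder: ratios below 0.5 but large gradients, the
   signature of restraints fighting the data. No absolute gradient
   threshold is externally given, so a relative rule is used: a surviving
   residue is removed when its mean per-atom gradient magnitude exceeds
   `gradient_k` (default 5) times the structure-wide median. When the
   median is numerically zero (exact copies) the rule is a no-op. In a
   pure-LSSR toy, a shoulder-displaced residue also raises the gradients of
   the neighbours that share its restraints, so those may be caught too;
   the tests assert containment rather than exact single-residue pruning.

Pruning is a per-invocation action at fixed coordinates (the
`autoncs`-style workflow applies it once per cycle; `autoncs_noprune`
skips it); it never increases the total energy, and re-pruning the pruned
lists in the shipped scenarios removes nothing further. Previously pruned
residues are never automatically re-admitted — rebuild the lists instead.

## Equivalent-atom swapping

Chemically equivalent side-chain atoms are often labelled inconsistently
between copies (a phenylalanine ring recorded with CD1/CD2 and CE1/CE2
exchanged). Taken literally, such a residue looks conformationally distinct
and disrupts restraints around it. `swap_equivalent_atoms` evaluates each
candidate residue's summed penalty under the original and the exchanged
labelling — coordinates fixed, the restraint pair set held fixed — and
keeps the cheaper one. A swap is applied only on strict improvement, which
makes the procedure idempotent, and it never increases the adjusted
residue's penalty by construction.

Standard mode covers ASP (OD1/OD2), GLU (OE1/OE2), PHE and TYR
(CD1/CD2 + CE1/CE2 together — one ring flip), ARG (NH1/NH2): pure
nomenclature. "Plus" mode adds HIS (the imidazole ring flip
ND1↔CD2, CE1↔NE2), ASN (OD1/ND2) and GLN (OE1/NE2), which exchange
chemically *non*-equivalent atoms and can disrupt hydrogen-bond networks —
enabled only on request. With more than two copies the first chain of the
group is the fixed reference; the decision metric is the package's own
similarity measure (the LSSR sum), both being deliberate design choices
where the external description is silent.

## The synthetic world

All quantitative tests run on generated fixtures: an idealised extended
polypeptide (bond lengths ~1.3–1.8 Å from a documented toy template; angles
approximate) duplicated into NCS copies 40 Å apart, with three controlled
deviations —

* per-atom Gaussian coordinate noise (default experiments use
  0.02–0.3 Å, bracketing the "most Δ below 0.1 Å plus a tail" regime seen
  in real medium-resolution NCS);
* rigid displacement of listed residues (3 Å for plateau/pruning
  scenarios; ~0.5 Å for shoulder/gradient scenarios);
* side-chain label flips for the swap machinery.

Fixtures are bit-reproducible given the seed. What a green test does *not*
establish: behaviour on real crystallographic models (altloc-rich regions,
chain breaks, non-ideal geometry interacting with the distance-based hetero
bonding), and the package's full-scale counts against deposited entries.
The one acceptance criterion requiring a deposited haemoglobin tetramer
(5578 protein + haem atoms, ≈29 600 restraints, ≈21 per atom) cannot run
without that ~0.5 MB file: it is implemented and fails with an explanatory
message in offline environments rather than being skipped.

## Numerical choices

* $\Delta$ enters the penalty as $\Delta^2 = (r_1 - r_2)^2$, so the energy
  is smooth through $\Delta = 0$ despite the absolute value; gradients are
  exact analytic chain-rule expressions, and the four per-restraint vectors
  sum to zero for NCS restraints (translation invariance). Coincident atoms
  ($r = 0$) contribute zero gradient for that distance term.
* The finite-difference validator uses central differences (default
  $h = 10^{-5}$ Å) and reports the worst error relative to the largest
  analytic gradient component (floored at $10^{-6}$); the strict
  $10^{-5}$ tolerance applies away from all-plateau configurations, where
  both gradients are asserted to be near zero instead.
* Strict inequalities follow the prose they implement: cutoff `<` 5.5 Å,
  plateau ratio `>` 0.5, NCS match fraction `>` 0.8.
* The demo minimiser is plain gradient descent with backtracking; the
  energy trace is non-increasing by construction and divergence (NaN)
  aborts with the trace attached. It exists to exercise gradients,
  plateaus and pruning — not to refine structures.
* Exported tables print numerics with 17 significant digits (TSV) or
  `digits = I(17)` (JSON) so that write → read round-trips are bit-exact.
* In the contact report, distances are rounded to 3 d.p. and the
  difference is computed on unrounded values, then rounded to 2 d.p. —
  the convention that reproduces the published per-atom comparison table.

## Known limitations

* No X-ray (maximum-likelihood) term, no B-factor restraints or coupling,
  no TLS, no rigid-body machinery: this package builds and evaluates the
  similarity geometry term only.
* No crystallographic symmetry expansion; distances are computed within
  the deposited asymmetric unit as given.
* No sequence-alignment-based matching; equivalence requires consistent
  author numbering.
* The toy fixture geometry is adequate for exercising every rule but is
  not Engh–Huber stereochemistry; quantitative results on fixtures should
  not be read as refinement benchmarks.
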