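---
title: "Sequence bundles and MSA exploration: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence bundles and MSA exploration: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundlekit)
```

bundlekit draws multiple sequence alignments as *sequence bundles* —
one semi-opaque Bezier thread per sequence through a residue-by-position
grid — and surrounds the drawing with the numerical machinery needed to
explore an alignment: selection queries, a Fisher-score embedding, joint
ordination of sequences and sites, supervised site screening, covariation
tests and kernel-distance phylogenetics. This vignette records the models
behind each piece, the parameters that matter, and the design decisions
taken where more than one reasonable construction exists.

## Why a non-aggregative view

Columnwise summaries (logos, frequency plots) integrate out the identity
of individual sequences, so statistical dependence *between* columns is
invisible to them. The package ships a minimal pair of alignments that
demonstrate the failure mode: `make_fig1a()` (500 copies each of `AAAAA`
and `TTTTT`) and `make_fig1b()` (500 each of `AATTT` and `TTAAA`) have
*identical* columnwise counts — 500 A and 500 T at every one of the five
sites — yet entirely different two-motif structure. Any aggregative
summary of the two is the same picture; in a bundle the two motifs appear
as two visibly distinct thread families. These fixtures double as the
package's primary test bed because every downstream result on them
(query counts, CA geometry, LOOCV errors) is known exactly by
construction.

## The data model

An `msa` is a rectangular block of single-character symbols over an
`alphabet` (symbols, a gap character, and named orderings used for the
y-axis). Invariants — equal row lengths, alphabet membership, unique
labels — are enforced at construction, so downstream code never
re-validates. Columns are addressed 1-based at every interface. Parsing
upper-cases symbols and normalises `.` to `-` (tolerating the Stockholm
insert-gap convention); FASTA labels are the first whitespace-delimited
token of the header, and duplicate labels are an error rather than being
renamed, because selections and groupings are keyed by label identity.
Ambiguity codes (N, X) are deliberately rejected by the two built-in
nucleotide/protein alphabets; data that needs them can declare a custom
`alphabet()` containing them.

The protein alphabet carries three orderings: alphabetical;
Kyte–Doolittle hydrophobicity (descending, ties at −3.5 — D, E, N, Q —
broken alphabetically, since the published scale gives no order within
ties); and a chemical-class grouping (hydrophobic, aromatic, polar,
positively and negatively charged residues adjacent). Ordering by
physical property makes conservative substitutions appear as *nearby*
rows, so functional conservation reads as a tight band of threads.

## The bundle drawing

`layout_threads()` computes one anchor per (sequence, column): x at the
column centre, y at the centre of the symbol's row plus a stacking
offset. Sequences sharing a cell are stacked into lanes — lane = rank of
the sequence among the sharers (by row index) modulo `max_lanes`
(default 32) — spaced evenly inside a band occupying `stack_band`
(default 0.6) of the cell height. The stacking discipline is a package
design choice: it is deterministic, bounds ink density, and guarantees
that two identical sequences remain two distinguishable threads.

Threads are cubic Bezier chains. The single curvature knob c ∈ [0, 0.5]
(default 0.35) places the control points of each inter-column segment at
horizontal offsets ±c·`cell_width` from its endpoints; c = 0 makes the
control points collinear with the endpoints and the thread degenerates
to a polyline. Gaps get a dedicated row below the alphabet, separated by
a half-cell gutter, because gap patterns carry real evolutionary signal
and hiding them misrepresents divergent alignments; `show_gap_row =
FALSE` switches to interpolating across gap columns instead.

Thread opacity defaults to `min(1, max(0.02, 8/n_seq))`, chosen so that
a handful of sequences render solid while a thousand-sequence bundle
stays readable as a density; it is a display default, not a claim about
any particular optimum. Colour precedence is selection colour over group
colour over default. Rendering is a pure function: identical inputs give
byte-identical SVG (numbers formatted to fixed precision) and
byte-identical PNG (same geometry rasterized on a cairo device at
`dpi/72` scale). The SVG classes (`thread`, `site-marker`,
`grid-row`/`grid-col`, `axis-*`) and the `data-label` attribute are part
of the public contract, so scripts can post-process the output.

## Selection queries

The query grammar is `expr := term (OR term)*`, `term := factor (AND
factor)*`, `factor := NOT factor | (expr) | atom`, with atoms
`label ~ /re/`, `seq ~ /re/` and `site(i) = X`; keywords are
case-insensitive and AND binds tighter than OR. Regexes are unanchored
searches (write `^…$` to anchor), matching the expectation set by search
boxes. Sequence regexes see the full aligned row *including* gaps —
gap-aware patterns are useful, and a `degap:` flag before the regex
matches against the degapped row when alignment columns should not
matter. The `site()` atom exists because selecting by residue-at-position
is the dominant operation in subfamily analysis. Queries select
sequences; sites are selected directly through `selection()`.

## Profile HMM and the Fisher-score embedding

With pre-aligned input the HMM state path is fixed, so the model reduces
to match-state emission distributions; insert and transition parameters
would contribute no per-sequence gradient of interest, and the embedding
deliberately uses match emissions only. Match columns are those with gap
fraction ≤ `gap_threshold` (default 0.5, the usual profile-construction
heuristic). Emissions are Laplace-smoothed, `e_k(b) = (n_k(b) + α) /
(n_k + α|A|)` with α = 1 by default; α = 0 is allowed for the model
itself but rejected when scores are requested, since the score is
undefined at zero probabilities.

The embedding is the gradient of the per-sequence emission
log-likelihood under the natural (softmax) parameterization of each
categorical emission: `u_kb(x) = 1[x_k = b] − e_k(b)·1[x_k ≠ gap]`. This
parameterization is used rather than the gradient in raw probabilities
because the latter is unbounded as e → 0; the softmax score is bounded,
zero-sum across symbols at each non-gap position, and exactly zero at
gap positions, so all-gap sequences embed at the origin. The test suite
verifies the closed form against central finite differences of
`emission_loglik()` to 10⁻⁶. No Fisher-information whitening or length
normalization is applied by default (the raw scores are the embedding);
`normalize = "length"` divides each row by its non-gap match count for
alignments with very uneven gap content.

## Correspondence analysis

CA operates on the 0/1 indicator coding of the alignment — one category
per (column, observed symbol), the gap counting as a symbol — in the
style of multiple correspondence analysis. Coding indicators rather than
Fisher scores is deliberate: the chi-square metric requires a
nonnegative table, and the natural objects to plot next to sequences are
site-residue categories ("Met-241"), which are exactly the indicator
columns. Constant columns are dropped with a notice (they have zero
inertia and a degenerate margin). The decomposition is the standard one:
`S = Dr^{−1/2}(P − rcᵀ)Dc^{−1/2}`, SVD, principal coordinates
`F = Dr^{−1/2}UΣ` and `G = Dc^{−1/2}VΣ`. Axis signs are fixed by
orienting each axis so its largest-magnitude row coordinate is positive —
an arbitrary but deterministic convention that makes results
reproducible across platforms. Requested axes beyond the numerical rank
(singular values ≤ 10⁻¹⁰) are truncated with a notice; a zero-rank
(perfectly independent) table returns a single axis of exact zeros so
that plotting code stays total. `nearest_categories()` ranks categories
by Euclidean distance in principal coordinates from the centroid of a
selected sequence set — the computational reading of "which sites sit
next to this cluster in the biplot", with ties broken by (column,
symbol) order.

## Supervised site screening

`detect_sites()` trains one linear SVM per column on the one-hot coding
of the column's symbol (gap included) and scores the column by
leave-one-out cross-validation against the supplied grouping, using
one-vs-rest with argmax over decision values for more than two groups
(ties by group declaration order). One-hot features are used rather than
Fisher scores because the per-site Fisher block is an affine function of
the same indicators, and raw indicators keep the classifier exactly
deterministic. The cost parameter C defaults to 1; with categorical
one-hot features the problem is effectively scale-free and results are
insensitive to C over a wide range.

LOOCV is computed exactly but not naively: at a single column, a
sequence's feature vector is determined by its symbol, so all held-out
sequences with the same (symbol, group) pair face the identical training
set and receive the identical prediction. One SVM is therefore fitted
per occupied (symbol, group) cell — at most |symbols|·|groups| fits per
column instead of one per sequence — and each prediction is weighted by
its cell count. The baseline is the leave-one-out majority-class error
(note its known artifact: with two exactly balanced groups the left-out
sequence always faces a majority of the other group, so the baseline is
1, not 0.5 — the opacity mapping only needs baseline > loocv to light
up). Marker opacity is `clamp((baseline − loocv)/baseline, 0, 1)`: 1 for
a perfectly discriminating site, 0 for an uninformative one. No
multiple-testing correction is applied across columns; the screen is
explorative and reports raw errors.

## Covariation tests

`binomial_covariation_test()` conditions on a selection (for instance
"all sequences with D at site 10") and tests the count of a target
residue at another site against its null frequency, estimated either
from all sequences (default) or from the complement of the selection —
both nulls are defensible and the choice is exposed. Tails are exact
binomial; the two-sided default is the *minlike* convention (total
probability of outcomes no more likely than observed, the convention of
`binom.test`), with *central* (twice the smaller tail, capped at 1)
available. Degenerate nulls (frequency 0 or 1 contradicted by the
observation) produce a warning but still return defined p-values.

## Kernel, trees, clustering

The sequence kernel is the columnwise mean substitution score:
`s(x,y) = (1/n_col) Σ σ(x_i, y_i)` with σ from BLOSUM62 by default (any
Biostrings BLOSUM/PAM matrix can be named), gap-vs-residue scored −4 and
gap-vs-gap 0 — gaps must move distances, not vanish. Nucleotide
alphabets use identity scores. The induced distance is the feature-space
norm `d = max(0, s_xx + s_yy − 2 s_xy)`; substitution-score matrices are
not positive definite, so negative values can occur and are clamped and
counted, and triangle-inequality violations are counted (at small n)
rather than hidden. This mean-score kernel is the package's own
construction: it is simple, symmetric, alignment-length normalized, and
satisfies the only contract downstream code needs (similarity →
nonnegative distance → NJ).

Neighbour joining is the canonical Saitou–Nei algorithm, implemented in
the package with an explicit tie-break (pairs minimizing Q are resolved
by lexicographic order of the subtrees' smallest leaf labels) so
topologies are reproducible; negative branch estimates are clamped to 0
with a notice. On additive matrices NJ provably recovers the generating
tree, and the tests exercise exactly that property against random trees,
with `ape`'s independent NJ as a cross-check. Trees are `ape` "phylo"
objects throughout; a two-taxon input is represented as two root edges
of d/2 each (the container has no bare-edge representation), preserving
the total path length.

Spectral clustering follows the normalized-Laplacian construction:
Gaussian affinity `exp(−d²/2σ²)` with σ defaulting to the median
off-diagonal distance (a standard, scale-free bandwidth), zero diagonal,
row-normalized bottom-k eigenvectors, k-means with 10 restarts under a
caller-supplied seed, clusters renumbered by first occurrence so the
labelling is deterministic.

`motif_clade_status()` evaluates monophyly on the *unrooted* tree via
edge bipartitions — a motif's carriers are a synapomorphy exactly when
they form one side of some edge split — because rooted monophyly would
change under rerooting while the data do not. The implementation walks
the clade table; tests compare it against an independent cut-every-edge
enumeration.

## Synthetic data

`make_planted_msa()` generates grouped alignments with known ground
truth: i.i.d. background symbols (uniform over the alphabet unless a
distribution is given), planted columns whose symbol is fixed per group,
and covariant pairs jointly overwritten in a random half of the rows.
One integer seed controls everything through a local RNG (the global
random state is restored afterwards), and labels encode the group for
readable test failures. The generator emulates the *structure* of real
subfamily data — discrete, perfectly clean group-specific sites on an
exchangeable background — and deliberately not its confounders:
phylogenetic autocorrelation between rows, alignment errors, unequal
column occupancy. Passing tests on planted data therefore demonstrate
algorithmic correctness (the planted site is the LOOCV argmin; the
covariant rows are recoverable), not field performance on real protein
families.

## Problem sizes and numerical choices

The bundled analyses are exact or deterministic, so the test suite can
pin results tightly: Fisher scores against finite differences at 10⁻⁶;
CA singular values against a dense generalized-SVD oracle at 10⁻¹⁰; NJ
path distances on additive matrices at 10⁻⁹; binomial tails against
explicit enumeration at 10⁻¹². Randomized checks use fixed seeds and
desk-scale problems — alignments up to 1000 × 5, random trees of 6–12
leaves (100 replicates for NJ recovery), 20 planted alignments of 20 ×
12, 200 motif/clade cases — sizes chosen so each property is exercised
across many random instances while the whole suite runs in well under a
minute. Numerical edge cases are handled explicitly rather than by
accident: zero-rank CA tables, α = 0 emissions, degenerate binomial
nulls, constant columns under LOOCV, negative kernel distances and NJ
branch estimates, and k = 1 or k = n clustering.

## Known limitations

* The per-site screen treats columns independently; interactions that
  are only visible jointly (and methods like evolutionary trace) are out
  of scope.
* The kernel is columnwise and alignment-dependent; it is not a string
  kernel and inherits any alignment errors.
* CA on indicator codings inherits MCA's inertia inflation; axis
  percentages should be read comparatively, not absolutely.
* Rendering emits static SVG/PNG; there is no interactive brushing or
  linked-view machinery.
* No multiple-testing correction is applied in `detect_sites()` or
  across repeated covariation tests; treat p-values and errors as
  explorative scores.
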