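# bundlekit

Sequence bundles and explorative analysis of multiple sequence alignments
in R.

Sequence logos and their relatives summarise a multiple sequence alignment
(MSA) column by column, so any dependency *between* columns — covariant
sites, subfamily-specific motifs, compensating substitutions — is invisible
by construction. A **sequence bundle** keeps every sequence intact: the
alignment is drawn as a grid with the alphabet on the y-axis (optionally
ordered by a biochemical property such as Kyte–Doolittle hydrophobicity)
and alignment positions on the x-axis, and each sequence becomes one
semi-opaque Bezier *thread* through the cells of its residues. Because a
thread stays connected across columns, multi-site motifs pop out even when
the columnwise frequencies of two alignments are identical.

Around that visualization, bundlekit provides the analysis toolkit such a
view needs:

* **Selection queries** — boolean combinations of regular expressions over
  labels and rows, plus residue-at-position atoms:
  `label ~ /Ciona/ AND site(241) = M`.
* **Profile-HMM Fisher scores** — match-state emissions are estimated with
  Laplace pseudocounts, `e_k(b) = (n_k(b) + α) / (n_k + α|A|)`, and each
  sequence is embedded by the gradient of its emission log-likelihood
  under the softmax parameterization, `u_kb(x) = 1[x_k = b] − e_k(b)·1[x_k ≠ gap]`.
* **Correspondence analysis** — the chi-square SVD of the 0/1
  sequence-by-(site, residue) indicator table, giving a joint map in which
  a cluster of sequences sits next to the site-residue categories that
  define it.
* **Site detection** — one linear SVM per column on one-hot residue
  features, scored by exact leave-one-out cross-validation against a
  grouping; marker opacity = clamp((baseline − loocv)/baseline, 0, 1).
* **Covariation tests** — exact binomial tail tests of whether a selected
  set of sequences over- or under-uses a residue at another site.
* **Phylogenetics** — a columnwise BLOSUM62 kernel, the induced
  feature-space distance `d(x,y) = s(x,x) + s(y,y) − 2 s(x,y)`, Saitou–Nei
  neighbour joining, Newick I/O, spectral clustering of sequences, and
  classification of a motif against a tree as synapomorphy or homoplasy.

## Worked example

Two built-in toy alignments make the point of the method: 500 copies of
`AAAAA` plus 500 of `TTTTT`, versus 500 of `AATTT` plus 500 of `TTAAA`.
Their columnwise nucleotide counts are identical (500/500 at every site),
so any aggregative view of the two is the same picture; the row-level
motifs are completely different.

```r
library(bundlekit)

b <- make_fig1b()
b
#> MSA: 1000 sequences x 5 columns (alphabet 'dna')
#>   A0001        AATTT
#>   A0002        AATTT
#>   ...

sel <- evaluate_query("seq ~ /^AATTT$/", b)
length(sel$seq_indices)
#> [1] 500

groups <- group_assignment(
  setNames(ifelse(b$rows == "AATTT", "motifA", "motifT"), b$labels))
detect_sites(b, groups)
#>   column loocv_error baseline_error marker_opacity n_used
#> 1      1           0              1              1   1000
#> 2      2           0              1              1   1000
#> 3      3           0              1              1   1000
#> 4      4           0              1              1   1000
#> 5      5           0              1              1   1000
```

Every column separates the two motifs perfectly (LOOCV error 0, marker
opacity 1). The covariation between site 1 and site 3 is confirmed by the
exact binomial test — all 500 `A`-at-site-1 sequences carry `T` at site 3
against a null frequency of 0.5:

```r
binomial_covariation_test(b, sel, 3, "T")
#> Binomial covariation test: 500/500 conditioned sequences carry 'T' at site 3
#> null p = 0.5 (all_sequences)
#> P(<=k) = 1  P(>=k) = 3.05494e-151  two-sided (minlike) = 6.10987e-151
```

Correspondence analysis collapses the 1000 sequences onto exactly two
points (one per motif, separated by axis 1, which carries all of the
inertia), and the categories nearest the selected cluster are precisely
its defining residues:

```r
ca <- correspondence_analysis(build_indicator(b))
nearest_categories(ca, sel$seq_indices, k = 3)
#>   column symbol     distance
#> 1      2      A 2.220446e-16
#> 2      3      T 2.220446e-16
#> 3      4      T 2.220446e-16

svg <- render_svg(layout_threads(b, render_spec()), selection = sel)
```

The SVG contains one `<path class="thread">` per sequence — 1000 threads,
500 of them in the selection colour.

A command-line wrapper is installed with the package (`exec/bundlekit`)
with subcommands `render`, `query`, `embed`, `ca`, `detect-sites`,
`binom`, `tree`, `cluster` and `fixtures`, e.g.

```sh
bundlekit fixtures --name fig1b --out fig1b.fasta
bundlekit render --msa fig1b.fasta --select "seq ~ /^AATTT$/" --out bundle.svg
```

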