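---
title: "Detecting highly divergent tandem repeats in proteins with divrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting highly divergent tandem repeats in proteins with divrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divrep)
```

## The problem

Roughly a quarter of proteins contain tandem repeats (TRs): consecutive,
approximately repeated copies of a short unit. Repetitive regions evolve
faster than the rest of the protein, so ancient repeats accumulate
substitutions and indels until conventional similarity-based repeat finders
no longer see them, even though the underlying periodicity — and often the
fold it supports — is still there. divrep implements a detector aimed
specifically at this highly divergent regime (divergence degree S above
0.5, i.e. fewer than half of the aligned residues match their column
consensus), together with the simulation benchmark used to characterize it.

## The method

**Five-group re-coding.** Each sequence is first re-coded from the 20-letter
alphabet into five physicochemical groups: non-polar K = {G, A, V, I, L, P},
polar N = {S, T, C, M, Q, N}, aromatic I = {F, Y, W}, positively charged
M = {K, R, H} and negatively charged T = {D, E}. Substitutions inside a
group — the most frequent kind in diverged repeats — become invisible, and
five symbols make pair statistics estimable. Group symbols are fixed
integers K=1, N=2, I=3, M=4, T=5 throughout the package. Non-standard
residues (X, B, Z, U, O, J, '*') are skipped by default with their positions
recorded, so output coordinates always refer to the original string;
skipping (rather than aborting) preserves the local periodic phase.

**Pair-correlation scoring.** The detector scores not single symbols but
ordered adjacent pairs: with 5 groups there are 25 pair categories, and a
weight matrix for consensus length n has n rows (one per consensus
position) and 25 columns. Column k encodes the pair (previous, current) via
k = prev + 5·(current − 1). This captures the correlation of neighboring
residues inside repeat units, which survives heavy substitution loads
longer than positional composition does.

**Cyclic probe alignment.** Periodicity of length n is converted into an
alignment problem against an artificial periodic probe 1, 2, …, n, 1, 2, …
A Smith–Waterman-style local alignment (`local_align`) is computed between
the probe (length equal to the sequence) and the re-coded sequence, where a
diagonal move onto probe position j and sequence position i scores
`MT[probe[j], t(i)]` with t(i) the pair category of sequence positions
(i−1, i), and gaps cost del = 25 score units. The similarity matrix is
floored at zero and the traceback runs from the maximal cell back to the
first zero cell.

One convention deserves a note. The pair category of a diagonal move is
defined here from the *raw sequence predecessor* i−1, which for every
column except the first of a path is also the last position included in
the alignment. At the first column there is no preceding aligned residue
at all; scoring it zero is appealing but makes the plain two-state
recurrence ill-posed (a freshly started path and an empty path are then
indistinguishable at score zero, and the traceback convention "stop at the
first zero cell" would amputate the path's own first column). Using the raw
predecessor everywhere (with a zero contribution only at i = 1, where no
predecessor exists) makes the dynamic program exactly equivalent to
enumeration over all monotone local paths — a property the test suite
verifies by brute force — and can change a score by at most one cell's
contribution relative to the alternative.

**Random matrix sets and normalization.** For each n a set Q(n) of 1000
random weight matrices is generated: a uniform random 5-symbol sequence of
length 1000·n is counted against the probe (`count_pairs`), counts are
standardized cell-by-cell against their independent-margin expectation,

$$M(i,j) = \frac{M_1(i,j) - N\,p(i,j)}{\sqrt{N\,p(i,j)\,(1-p(i,j))}},
\qquad p(i,j) = \frac{x(i)\,y(j)}{N^2},$$

and each matrix is then brought to a common scale: sum of squares
R² = 110·n and probability-weighted sum K_d = −1 (with p₁ = 1/n, p₂ = 1/25).
The normalization is the two-parameter affine map m′ = a(m − b) solved in
closed form — b from the K_d constraint, a > 0 from the resulting quadratic
in the R² constraint — which is the minimal transformation meeting both
targets and has already-normalized matrices as fixed points. Fixing both
moments gives all matrices approximately the same null score distribution,
so the best-scoring matrix can be selected as the most significant without
per-matrix calibration. The uniform p₂ = 1/25 is kept during refinement as
well (the pair categories of the generating model are equiprobable by
construction).

**Iterative refinement and selection.** Starting from each member of Q(n),
the matrix is refined against the sequence itself: align, count adjacent
pairs along the aligned (gap-free) columns of the path, re-standardize,
re-normalize, re-align — as long as the score mF strictly increases; the
loop stops on a non-increase, a previously seen score (cyclic
fluctuation), or a degenerate count matrix. The best refined score over
the set is F_max(n) with its matrix M_max(n, 25) and alignment.

**Monte-Carlo significance.** The sequence is shuffled (200 times at full
scale), each shuffle re-aligned with the same refinement starting from
M_max, and the null scores V_n summarized into

$$Z(n) = \frac{F_{max}(n) - \bar V_n}{\sqrt{D(V_n)}}.$$

The denominator is the standard deviation (sample variance under the square
root): a Z-score on the threshold scale Z₀ = 6 only makes sense in standard
deviation units. Refinement of shuffled replicates starts from M_max rather
than from a fresh Q(n) search, which matches how the null is used (how well
can *this* matrix do on shuffled material?) and keeps the cost linear in
the number of shuffles.

**Spectrum filtering.** Scanning n = 2..100 yields a spectrum of Z(n) with
overlapping calls at multiples and near-multiples of the true period. Calls
with Z < Z₀ are dropped; the largest-Z period is kept and every remaining
period whose alignment overlaps it by more than 50% of the shorter
sequence-side span is removed; the procedure repeats on the remainder.
Surviving spans must cover at least 14 residues. The shorter-span basis for
the overlap fraction is the symmetric, strictest reading of "over 50% of
the length".

**Divergence degree.** For each call the sequence side of the alignment is
cut at probe-period boundaries into a repeat multiple alignment (insertions
open extra columns, so the width n₁ can exceed n). Columns occupied by
fewer than k/2 residues are disregarded (exactly k/2 is retained); the
consensus takes each column's modal symbol (ties to the smaller fixed
index), and S = 1 − v/v₁ with v the consensus-matching cells and v₁ all
retained cells. S is reported in 20-letter residue space by default — the
coincidence matrix is defined over amino-acid types, and the original
residues are recovered through the re-coding provenance — with the
five-group space available as an option (`symbol_space = "groups5"`),
since printed repeat alignments use the group code.

**Classifying repeat matrices.** M_max matrices of a common n are compared
by the cyclic Euclidean distance: the root-sum-of-squares difference
minimized over all n cyclic row rotations (the repeat phase is arbitrary).
Matrices are clustered by complete linkage; the cut height B₀ is chosen
where the mean class size of the real set separates from that of a
randomized twin set (each matrix's cells permuted) by more than 10 standard
errors (Z_n(B) > 10, with class-size variances computed across classes as
population variances and the default grid of 40 levels spanning the
1st–99th percentile of the real pairwise distances). Each class is
summarized by a consensus matrix: the member minimizing the summed distance
to the rest is the phase reference, other members are rotated to their
best phase against it, and cells are averaged. The square root in the
distance follows from it being called Euclidean; orderings are unaffected,
but reported cut heights live on the rooted scale.

## The simulator

`make_artificial_tr_sequence` builds ground-truth test material: a random
unit of length n is drawn from the average Swiss-Prot residue composition
(shipped as a fixed, documented frequency table; homo-repeat units are
rejected), repeated k times, mutated, and embedded at a random position in
600 residues of random flanking sequence, with the true boundaries
recorded. The mutation model is deliberately simple:

* substitutions: floor(i/100 · nk) events at uniform positions drawn *with
  replacement*, each replacing the residue by one of the 20 uniformly.
  A position can mutate repeatedly and a substitution can silently restore
  the residue — the only reading under which substitution loads of
  110–150% are meaningful;
* indels: round(nk/100) single-residue events inside the repeat region,
  insertion or deletion with probability ½ each, at uniform positions.

The full benchmark design is the Cartesian grid n ∈ {2, 5, 7, 10, 20, 40,
60, 80, 100} × 100 units × k ∈ {4, 8, 16, 24, 32, 50} (5400 sequences per
divergence level), scalable down through `n_values`, `k_values` and
`units_per_n`. A detection is scored correct when the consensus length
exactly matches the true n and the called region (summing non-overlapping
same-n calls) covers at least 50% of the true repeat region.

What the simulator does *not* emulate: realistic substitution preferences
(no residue-exchange matrix), rate heterogeneity along the unit, unit-count
evolution (duplication/contraction), or compositional drift of flanks.
Passing the benchmark therefore demonstrates sensitivity to periodicity
under uniform mutational noise, not performance on any particular protein
family.

## Desk-scale problem sizes

The package defaults follow the full-scale protocol (set_size = 1000,
shuffles = 200, n = 2..100, Z₀ = 6, del = 25, minimum span 14). The test
suite and the acceptance script run deliberately reduced configurations,
chosen once as sensible desk-scale equivalents:

* single-sequence checks: n scanned over 5..9 with set_size = 100 and
  shuffles = 50 for the 7-residue/100-copy regime;
* benchmark subset: n ∈ {5, 7, 10}, k ∈ {16, 32}, 10 units per cell,
  scanned over n = 4..11 (bracketing every true period and containing the
  5/10 divisor–multiple pair) with set_size = 100, shuffles = 50.

Reducing set_size and shuffles lowers F_max slightly and widens the Z
estimate's own sampling error, but preserves the decisive margin between
periodic and shuffled material (a clean tandem of ≥ 8 copies scores far
above any shuffled control at a fixed seed). One consequence of the
benchmark subset is worth stating plainly: the published full-grid
detection percentages average over many cells that are undetectable by
construction (e.g. nk = 8), so the subset — whose cells all have
nk ≥ 80 — sits at or above the full-grid percentage at low divergence. The
subset detection rates are reported as computed; they are expected to
bracket the published column from above at i = 25% and to degrade
monotonically with i.

## Numerical choices and degenerate inputs

* Cells with zero marginal probability in the standardization get weight 0
  (no evidence), and a count matrix with fewer than two non-zero rows or
  columns is treated as degenerate (refinement stops; direct calls error).
* Normalization requires non-zero variance across cells; constant matrices
  error.
* Alignment tie-breaks are fixed (restart, diagonal, gap-in-sequence,
  gap-in-probe; smallest (i, j) cell for the global maximum), so identical
  inputs give identical paths on any platform.
* Consensus ties take the smaller fixed symbol index; the k/2 column filter
  retains columns at exactly k/2.
* Zero variance across Monte-Carlo shuffles raises an error rather than an
  infinite Z.
* All randomness derives from one user seed through fixed per-work-unit
  substreams keyed by (seed, n, replicate); results are independent of
  scheduling and of whether a matrix set is enlarged later.

## Limitations

* The refinement loop is greedy and the pair category of the first aligned
  column of a path is scored from the raw preceding residue; both are
  documented conventions of this implementation, not uniquely determined
  by the method's description.
* Sensitivity requires many repeat copies: short arrays (nk below roughly
  50–60 residues) are better served by similarity-based finders, which is
  the published division of labour.
* The full-databank operating points (15k-region catalogues, class counts
  at specific cut heights) depend on scanning an entire protein databank
  and are out of scope for the package's test surface.
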