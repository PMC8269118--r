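# divrep — highly divergent tandem repeats in protein sequences

Tandem repeats (TRs) in proteins evolve fast: ancient repeat arrays
accumulate so many substitutions and indels that similarity-based finders
(T-REKS/XSTREAM-style) no longer recognize them, even though the
periodicity — and the fold it scaffolds — persists. `divrep` detects
repeats in exactly this regime: divergence degree *S* > 0.5, i.e. fewer
than half of the aligned repeat residues match their column consensus.

For whom: anyone annotating repeat architecture in protein sequences or
studying low-complexity / intrinsically disordered regions, where heavily
diverged periodicities hide.

## The method in brief

1. **Five-group re-coding.** Residues are mapped to five physicochemical
   groups — non-polar **K** (G,A,V,I,L,P), polar **N** (S,T,C,M,Q,N),
   aromatic **I** (F,Y,W), positively charged **M** (K,R,H), negatively
   charged **T** (D,E) — so within-group substitutions vanish.
2. **Pair-correlation weight matrices.** A candidate consensus length *n*
   is represented by an *n* × 25 position-weight matrix over ordered
   adjacent-pair categories (5 × 5 groups), capturing neighbour
   correlations that outlive positional similarity.
3. **Cyclic probe alignment.** The sequence is locally aligned
   (Smith–Waterman-style dynamic programming, gap penalty *del* = 25)
   against the periodic probe 1,2,…,*n*,1,2,… under each matrix of a
   random normalized set *Q*(*n*) (1000 matrices, each with
   *R*² = 110·*n*, *K_d* = −1), and every matrix is refined iteratively
   against its own alignment until the score *mF* stops increasing. The
   best refined score over the set is *F_max*(*n*) with matrix
   *M_max*(*n*, 25).
4. **Monte-Carlo significance.**
   *Z*(*n*) = (*F_max*(*n*) − V̄) / √D(V) against scores of 200 shuffled
   copies of the sequence; calls require *Z* ≥ *Z*₀ = 6 and ≥ 14 residues.
5. **Filtering, divergence, classes.** Overlapping period calls (>50 % of
   the shorter span) collapse to the most significant; each call gets a
   divergence degree *S* = 1 − *v*/*v*₁ from its repeat multiple
   alignment; *M_max* matrices can be clustered by cyclic Euclidean
   distance (complete linkage, randomization-calibrated cut) into repeat
   pattern classes.

The package also ships the artificial-TR benchmark generator (random
units from Swiss-Prot average composition, *k* tandem copies, *i* %
substitutions with replacement, 1 indel per 100 residues, 600-residue
flanks) and the exact-length / ≥50 %-overlap correctness rule used to
score detections.

## Worked example

Simulate a repeat array (7-residue unit, 30 copies, 75 % substitutions,
1 indel / 100 residues) inside 200 residues of random flank, then detect:

```r
library(divrep)

spec <- artificial_tr_spec(n = 7, k = 30, substitution_pct = 75,
                           indel_rate = 1, flank = 200, seed = 42)
tr <- make_artificial_tr_sequence(spec)
c(tr$l0, tr$r0)                  # true repeat region: 156 365

hits <- detect_repeats(tr$sequence, id = "sim1", n_min = 5, n_max = 9,
                       set_size = 50, shuffles = 30, seed = 1)
hits
#>     id n0   l   r       Z   S    F_max
#> 1 sim1  7 163 365 11.2244 0.5 314.9183
```

The detector recovers the exact consensus length (`n0 = 7`), covers the
true region 156–365 almost completely (163–365), and the call is highly
significant (`Z = 11.2`, i.e. *F_max* sits 11 standard deviations above
the shuffled-sequence null). `S = 0.5` says half of the aligned residues
differ from their column consensus — already at the edge of what
similarity-based tools report. The repeat multiple alignment behind the
call uses the five-letter code with `.` for gaps:

```r
d <- attr(hits, "details")[[1]]
rma <- repeats_from_alignment(d$local, recode_sequence(tr$sequence, id = "sim1"))
cat(head(format_repeat_alignment(rma, "groups5"), 5), sep = "\n")
#> 1    ....IMKN
#> 2    K.MNIKKN
#> 3    T.NKINNN
#> 4    T.NKKNMT
#> 5    K.KNMNIN
divergence_degree(rma, "groups5")
#> <divergence_result> S = 0.4208 (v = 117 / v1 = 202, 7 columns, groups5)
#>   consensus: TMKINKN
```

A thin command-line wrapper is installed as `exec/divrep`
(`divrep scan|simulate|evaluate|fdr`), e.g.
`divrep scan --fasta in.fa --nmin 2 --nmax 100 --seed 1 --out hits`.

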