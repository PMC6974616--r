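---
title: "Methods: coherent promoter epigenetics across cancer types and marks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coherent promoter epigenetics across cancer types and marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitriclust)
```

## The problem

Histone modifications measured by ChIP-seq (H3K4me1, H3K4me3, H3K27ac,
H3K27me3, H3K9me3, H3K36me3, ...) shape gene regulation, and cancers that
share promoter-level modification patterns may share regulatory mechanisms
— and potentially treatments. Given genome-wide signal tracks for a set of
cancer types \(T\) and a set of epigenetic marks \(E\), epitriclust asks:
*which gene sets show a coherent promoter signal across which subset of
cancer types and which subset of marks?* The answer is a set of maximal
**tri-clusters** \((G', T', E')\) with \(G' \subseteq G\), \(T' \subseteq T\),
\(E' \subseteq E\), each supported by at least a minimum fraction of the
investigated genes.

The search proceeds in three stages: (1) preprocessing of signal tracks into
per-mark promoter profile matrices, (2) per-mark bi-cluster discovery via
Pearson-correlation itemsets and FP-growth frequent-itemset mining, and
(3) cross-mark intersection with anti-monotone pruning and maximality
filtering.

## Stage 1 — preprocessing

Each raw track is an interval/count list (bedGraph). The genome is divided
into consecutive segments of `bin_size` bp (default **200 bp**, the
conventional resolution for histone ChIP-seq segmentation) and each interval
contributes its count to exactly one bin — the one containing its midpoint.
Midpoint assignment conserves total mass: an interval is never split or
double-counted, and `sum(bins) == sum(counts)` always holds.

Counts are then depth-normalized:
\[ v \mapsto \operatorname{asinh}\!\left(v \cdot \frac{s}{N}\right), \]
where \(N\) is the track's total read count and \(s\) the
`normalization_scale` (default \(10^7\)). The inverse hyperbolic sine is the
variance-stabilizing transform we use for scaled read counts: it behaves
like \(\log(2x)\) for large values, is linear near zero, maps zero to zero,
and — unlike \(\arcsin\) — is defined for all non-negative scaled counts,
which routinely exceed 1. Because Pearson correlation is invariant to
monotone rescaling only approximately, the scale constant matters in
principle; in practice downstream correlations are insensitive to it, and
the transform is exactly invariant to multiplying counts and depth by a
common factor.

Promoters are windows around annotated TSSs: `[TSS - upstream,
TSS + downstream)` on the `+` strand, mirrored on `-`. The defaults
(**±2 kb**) are a conventional promoter definition; the window is
configurable and its length must be a multiple of the bin size. Windows
clipped by a chromosome end are dropped (and reported) rather than padded,
so every profile has the same length \(L\) = window / bin size. `-`-strand
profiles are reversed so that position 1 is always the most upstream
position; reversing twice is the identity, and tests pin this down.

For each mark \(e_k\), the profiles form the matrix
\(D^k = \{t^k_{i,j}\}\) over types \(i\) and genes \(j\), each entry a
length-\(L\) signal vector.

## Stage 2 — coherence itemsets and FP-growth

For every gene and every unordered pair of cancer types, the sample Pearson
correlation of the two promoter profiles is computed. A pair is **coherent**
iff \(r > \theta\) (strict), with \(\theta = 0.7\) by default — a value at
which correlated promoter shapes are visibly similar while the null tail
for length-20 Gaussian profiles is well below 1 %. A profile with zero
variance has no defined correlation; such profiles are treated as
never-coherent rather than as errors, so all-flat promoters degrade
gracefully. An optional `min_profile_sd` floor (default 0 = off) extends
the same rule to near-flat profiles.

The gene's **transaction** is the union of all types appearing in at least
one coherent pair; the pair set itself is also retained (see bi-cluster
modes below). Transactions are monotone in \(\theta\): lowering the
threshold never removes a type.

Frequent cancer-type itemsets are mined with an FP-growth implementation
written for this package: items are ranked by descending global frequency
(ties broken lexicographically), infrequent items are removed before
insertion, transactions are inserted along shared prefixes, and a header
table chains all nodes per item. Mining recurses over conditional pattern
bases and conditional trees, with the classical single-path shortcut
(enumerate all subsets of a single-path tree). The miner returns *all*
itemsets of size ≥ 2 with support ≥ `ceiling(min_support × n_genes)`
(default 10 % of genes), each with its exact support; its output is
verified in the test suite against an exhaustive enumeration of every
subset of the item alphabet on hundreds of random databases. A minimum
itemset size of 2 is built in: a pattern over one cancer type says nothing
about cross-cancer similarity.

**Bi-cluster modes.** A transaction records *pairwise-evidenced*
membership: a type joins the itemset as soon as it is coherent with some
other type at that promoter. A frequent itemset \(\{A,B,C\}\) can therefore
be supported by a gene where \(A\!\sim\!B\) and \(B\!\sim\!C\) but
\(A\not\sim C\). The package exposes both readings:

* `loose` — genes whose transaction contains the itemset (the literal
  construction);
* `clique` (default) — genes whose coherent-pair set contains *every* pair
  of the itemset, so member types are mutually coherent.

For 2-type itemsets the modes coincide; clique gene sets are always subsets
of loose gene sets; a clique-filtered bi-cluster that falls below the
support count is dropped. The default is `clique` because "types sharing a
similar pattern" is most naturally read as mutual similarity; `loose`
remains available for the literal semantics.

## Stage 3 — tri-cluster mining

A tri-cluster candidate is a pair (type set \(T'\), mark set \(E'\)) with
induced gene set \(\bigcap_{k \in E'} \mathrm{genes}(T', k)\), where
\(\mathrm{genes}(T', k)\) is the (loose or clique) gene rule of stage 2
under mark \(k\). Support is the size of the induced gene set and is
**anti-monotone in both dimensions**: growing \(T'\) or \(E'\) can only
shrink the genes.

Candidate type sets for a mark set are the type sets frequent under every
mark involved. One could instead intersect arbitrary per-mark frequent
sets (\(T' = A \cap B\), \(A\) frequent under \(k\), \(B\) under \(l\)),
but the two candidate spaces are provably identical: frequency is downward
closed, so any such intersection is itself frequent under both marks and
already enumerated. This equivalence lets the package keep a single code
path for what would otherwise be two candidate-generation switches.

Enumeration is levelwise over mark-set size, Apriori-style: candidates with
\(m+1\) marks are generated only from surviving candidates with \(m\)
marks, gene sets are intersected incrementally, and per-(type set, mark)
gene lookups are memoized. By anti-monotonicity this pruning changes cost
only, never results — the suite asserts that every returned gene list
equals its direct recomputation. Finally, only **maximal** candidates are
kept: \((T', E')\) is removed if another candidate \((T'', E'')\) satisfies
\(T' \subseteq T''\), \(E' \subseteq E''\) with \((T', E') \ne (T'', E'')\).
Maximality is defined over the (types, marks) pair; gene sets are induced,
so containment of the gene dimension follows automatically. Both
\(|T'| \ge 2\) and \(|E'| \ge 2\) are required — a tri-cluster must
genuinely span multiple types and marks.

Per cluster the package reports the support and the **fold enrichment**
\(|G'| / n\), the fraction of all investigated genes carrying the pattern.

Tri-cluster enumeration is inherently expensive (the candidate space is the
product of two power sets); exact anti-monotone pruning is the only
search-space reduction used, and heuristic pruning is deliberately out of
scope.

## The synthetic benchmark

Because real pan-cancer epigenome stacks are large external datasets, the
package ships a simulator that generates per-mark profile matrices directly
at the post-normalization level — the representation the mining core
actually consumes — so the algorithm is isolated from preprocessing.
Background profiles are i.i.d. Gaussian \(N(0, \sigma_b^2)\) vectors,
independent across genes, types and marks. A planted pattern
\((G', T', E')\) shares one template per (gene, mark) across its types,
each type receiving independent \(N(0, \sigma_n^2)\) noise, so
within-pattern pairwise correlation approaches 1 as
\(\sigma_n \rightarrow 0\) and equals
\(\sigma_t^2 / (\sigma_t^2 + \sigma_n^2)\) in expectation otherwise.
Templates are drawn at the background magnitude by default, so planted
cells are not distinguishable by amplitude — only by cross-type coherence.

Reference conditions used throughout the tests: 500 genes × 5 types ×
4 marks, \(L = 20\), one planted 80-gene × 3-type × 3-mark block,
\(\sigma_b = 1\). \(L = 20\) keeps the null probability of a background
pair exceeding \(\theta = 0.7\) around \(3 \times 10^{-4}\) (checked
against a Monte-Carlo estimate of the Pearson null tail), so an 80-gene
block clears the 10 % support threshold while chance background clusters
essentially never do. At \(\sigma_n = 0\) the pipeline recovers the planted
block exactly; recovery is scored per planted pattern as the maximum over
found clusters of the *minimum* of the three per-dimension Jaccard indices,
and degrades monotonically along a noise ladder
\(\sigma_n \in \{0, 0.25, 0.5, 1\}\).

What the simulator does *not* emulate: read-count noise characteristics of
real ChIP-seq (fragment-length effects, GC bias, input contamination),
correlated backgrounds between biologically related cancer types, and
partially overlapping patterns. A separate count-level fixture (Poisson-like
integer counts → binning → normalization) exercises the preprocessing path
end to end in the test suite, but passing the planted-pattern benchmark
demonstrates correctness of the mining procedure, not performance on real
epigenomes.

```{r benchmark, eval = TRUE}
stack <- simulate_profiles(
  n_genes = 150, n_types = 5, n_marks = 4, profile_length = 20,
  patterns = list(planted_pattern(1:40, 1:3, 1:3, noise_sd = 0.25)),
  seed = 11
)
tc <- mine_epitriclusters(stack)
tidy(tc)
glance(score_recovery(tc, stack))
```

## Parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| `bin_size` | 200 | bp | standard histone ChIP-seq segment size |
| `promoter_upstream` / `downstream` | 2000 / 2000 | bp | conventional promoter window; must sum to a multiple of `bin_size` |
| `normalization_scale` | 1e7 | reads | fixes the asinh argument scale; correlations are insensitive to it |
| `corr_threshold` | 0.7 | – | coherence is strict `r > theta`; null tail at L = 20 is ~0.03 % |
| `min_profile_sd` | 0 | signal units | optional noise floor; 0 excludes only exactly-flat profiles |
| `min_support` | 0.10 | fraction of genes | support count is `ceiling(0.10 n)` |
| `min_types`, `min_marks` | 2, 2 | – | clusters must span several types and marks |
| `mode` | `"clique"` | – | mutual coherence; `"loose"` gives the literal itemset semantics |

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open (BED convention) throughout; GFF3 input
  is converted on read; the BED TSS is `start` (`+`) or `end - 1` (`-`).
* Interval-to-bin assignment uses the integer midpoint
  `floor((start + end)/2)`; an interval beyond its chromosome is an error.
* Promoter windows need not align to bin boundaries; the `L` consecutive
  bins starting at `floor(start / bin_size)` are used.
* Zero-variance profiles yield `NA` correlations that can never pass any
  threshold; a track with zero total reads cannot be normalized (error).
* FP-growth item order breaks frequency ties lexicographically; results are
  order-invariant as sets, and serialization is canonical (itemset size,
  then lexicographic), making every output byte-reproducible.
* All randomness lives in the simulator, which requires an explicit seed
  and restores the caller's RNG state; the pipeline itself is
  deterministic, and identical inputs give byte-identical output trees.
* Problem sizes in the test suite (up to 500 × 5 × 4 with L = 20, 100-fold
  randomized miner cross-checks) were chosen as the smallest stacks that
  exercise every pruning path while keeping the whole suite fast enough to
  run on every change.

## Known limitations

* The tri-cluster candidate space grows exponentially with |T| and |E|;
  exact enumeration is intended for the small mark/type panels typical of
  pan-cancer epigenome comparisons (≤ ~8 of each), not for atlas-scale
  inputs.
* Coherence is linear (Pearson); profiles related by nonlinear monotone
  warps score lower. No alternative similarity measures are included.
* Gene lists are exported for external enrichment tools; the package
  performs no GO/pathway enrichment itself.
* No peak calling, input subtraction or alignment: tracks are taken as
  given, and DNA methylation is out of scope.
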