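---
title: "Scaled MinHash sketching and search: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaled MinHash sketching and search: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minhashr)
```

This vignette explains the statistical model behind the package, the
parameters that matter and why their defaults are what they are, the
numerical choices made where the design was genuinely open, and what the
synthetic benchmarks do — and do not — demonstrate about real data.

## The sketching model

A sequence is decomposed into its overlapping k-mers. For DNA each k-mer is
*canonicalized* — replaced by the lexicographically smaller of itself and
its reverse complement — so that sketches are strand-neutral; protein
k-mers are used as-is. Each canonical k-mer is hashed to a 64-bit value
with MurmurHash3 (x64 variant, low 64 bits of the 128-bit digest, seed 42).
The hash is treated as a uniform draw from $[0, 2^{64})$.

Two retention modes exist:

* **Scaled mode** (the default working mode). With scaling factor $s$, the
  hash space is divided into $s$ equal bands and a k-mer is retained iff
  its hash lies in the minimum band, i.e. strictly below
  $\lfloor 2^{64}/s \rfloor$. The sketch keeps an expected fraction $1/s$
  of *distinct* k-mers, so `length(mins) * s` (`estimated_bp()`) is an
  unbiased estimate of the distinct-k-mer count. Because the bands nest
  ($s_2 \ge s_1$ implies band$(s_2) \subseteq$ band$(s_1)$, with the strict
  `<` cutoff), `downsample()` to a coarser scale reproduces *exactly* the
  sketch that direct construction at that scale would give. That exact
  nesting is a tested invariant, and it is why sketches at different
  scales are comparable after aligning to the coarser one.
* **Bottom-n mode** (classic MinHash): the $n$ smallest hashes ever seen.
  A scaled sketch converts losslessly to bottom-n whenever
  $n \le$ the number of retained hashes, since the retained hashes are by
  construction the smallest ones of the whole input.

For a query and subject sketched at the same scale, the retained union is
a uniform random subsample of the true k-mer union, so the observed
intersection fraction estimates Jaccard with approximately binomial error:
with $m$ union hashes retained, the standard error is about
$\sqrt{J(1-J)/m}$. The accuracy tests hold the estimator to three times
that bound.

**Abundance tracking.** Optionally each retained hash carries an
occurrence count, incremented per k-mer occurrence after hashing. Counted
sketches compare by cosine similarity over the sparse count vectors; the
flatten operation (or an ignore-abundance flag in the comparison layer)
reduces them to plain sets. Cosine over a hash-subsampled vector is an
approximation that degrades for highly skewed abundance distributions;
for fine-grained quantitative comparisons a dedicated quantification
method should be preferred.

**Invalid characters.** A window containing any character outside the
alphabet (an `N`, a stop codon `*` from translation, an ambiguous residue
`X`) is skipped entirely rather than substituted, so sketches are
insensitive to soft-masking case but sensitive to Ns, and no fabricated
k-mer is ever hashed. Stop codons are deliberately treated as window
breakers, not residues: six-frame translation emits them as `*` and no
protein k-mer spans one.

## Parameters

| Parameter | Default | Meaning and guidance |
|---|---|---|
| `ksize` | 31 (CLI) | k-mer length in bases/residues. 21 is sensitive across genera, 31 about species-specific, 51 about strain-specific; 4 with `scaled = 1` gives tetranucleotide-frequency profiles for binning/contamination screens. |
| `scaled` | 1000 (CLI) | Fraction denominator $s$. Precision scales with retained sketch size: target at least a few hundred hashes for the comparisons you care about (a 5-Mb genome at `scaled = 1000` keeps ~5000). |
| `num` | unset | Bottom-n size, mutually exclusive with `scaled`. Only for interoperation with fixed-size MinHash workflows. |
| `seed` | 42 | Hash seed. All compared sketches must share it. |
| `track_abundance` | FALSE | Keep per-hash counts; enables cosine comparison and `avg_abund` in gather output. |
| `fp_target` (SBT) | 0.05 | Bloom-filter false-positive target at design load. Filters are sized with a 2x headroom for later inserts and never resized; saturation only costs extra node visits, never correctness (tested with filters forced to FP ≈ 0.5). |
| `arity` (SBT) | 2 | Maximum children per internal node. |
| `threshold` (search) | 0.08 | Minimum similarity/containment to report. |
| `threshold_bp` (gather) | `3 * scaled` | Stop when the best remaining overlap represents fewer estimated bp than this — i.e. fewer than 3 hashes at the working scale, where estimates are dominated by noise. |
| `majority` (LCA classify) | 1.0 | Required support fraction $F$: the reported lineage is the deepest one supported by at least $F$ of the classifiable hashes. 1.0 is a strict consensus; lowering it trades specificity for depth. |

## Search and its pruning bound

The Sequence Bloom Tree stores sketches at the leaves; every internal node
holds a Bloom filter containing each hash of every descendant leaf, plus
`min_leaf_n`, the smallest descendant leaf cardinality. For a query $Q$
and node $v$, let $m_v$ be the number of query hashes the filter reports
present. Bloom filters have no false negatives, so for every descendant
leaf $L$: $|Q \cap L| \le m_v$ and $|L| \ge \text{min\_leaf\_n}(v)$, hence

$$ J(Q, L) \le \frac{m_v}{|Q| + \text{min\_leaf\_n}(v) - m_v}, \qquad
   C(Q, L) \le \frac{m_v}{|Q|}. $$

A subtree is pruned only when its bound falls below the threshold (with a
$10^{-9}$ slack so floating-point rounding can never prune a boundary
case), which makes pruned search provably identical to an exhaustive scan
— an equivalence the test suite checks literally, against adversarially
undersized filters as well. False positives inflate $m_v$ and therefore
only weaken pruning.

`gather()` runs best-first: each round finds the leaf with the maximum
overlap with the *remaining* query (branch-and-bound over the tree, with
$m_v$ as the overlap bound), reports overlap, `p_query` (relative to the
original query, so the column sums to the recovered fraction), `p_match`
(relative to the leaf) and mean query abundance over the overlap, then
subtracts the leaf's hashes and repeats until the best overlap is below
`threshold_bp`. The greedy loop is made deterministic by an explicit
tie-break: equal overlap goes to the smaller reference (higher `p_match`),
then to the lexicographically smaller name. Per-step overlap and
`p_match` are also this package's operationalization of "percent identity
and unique identity per match": `p_match` is identity over the match, and
the per-step intersection (after subtraction) is the unique overlap.

When the query is sketched coarser than the index, the tree's stored
`min_leaf_n` values no longer describe the leaves after downsampling, so
similarity search falls back to an exhaustive leaf scan rather than risk
over-pruning; the (small) cost is correctness-neutral.

The LCA database is the in-memory alternative backend: two named lists
keyed by sample — hashes and lineages. Search and gather over it are
linear scans and are tested to agree exactly with the SBT backend.
Classification assigns each query hash the lowest common ancestor (longest
common lineage prefix) of the samples containing it, then reports the
deepest lineage whose cumulative support reaches `majority`;
summarization counts each hash at its LCA and aggregates the counts up
every prefix. Where several lineages at the same depth tie, the tie-break
is larger support, then lexicographic order — both the threshold and the
tie handling are configuration, since a bare "consensus" underdetermines
them.

## Serialization

Signatures are stored as a top-level JSON list with fixed key order and
ascending hashes, so serialization is canonical: saving the same
signatures twice yields byte-identical files, and each sketch carries an
integrity digest over (k, seed, molecule, sorted hashes) verified on load.
Hash values are serialized as decimal strings, not JSON numbers: standard
JSON parsers read numbers as doubles, which cannot represent all 64-bit
integers, and an exact round trip was judged more important than numeric
encoding. For the same reason hashes are decimal strings inside R; all
arithmetic on them (thresholding, ordering, Bloom indexing) happens in
C++ on `uint64_t`, and the retention cutoff $\lfloor 2^{64}/s\rfloor$ is
computed by exact long division in R. SBT indexes persist as a directory
(JSON manifest plus one file per node) so individual nodes remain
inspectable; LCA databases persist as a single JSON file.

## What the synthetic benchmarks show

The generators produce uniform i.i.d. ACGT genomes, independent per-base
substitutions (no indels), uniformly positioned error-free reads with
fixed quality, and consistent ranked taxonomies with controllable
sharing. Under that model the test suite verifies, among others:

* exact agreement of scaled-1 sketch Jaccard with brute-force k-mer-set
  Jaccard (20 pairs of 5-kb sequences, k in {4, 21, 31});
* the 3-sigma accuracy bound above on 100 mutated 100-kb pairs at
  mutation rates 0.001–0.05 (k = 21, `scaled = 250`, ≥ 200 retained
  hashes per sketch);
* k-mer survival under 1% mutation within ±0.03 of $(0.99)^{21} ≈ 0.810$;
* literal SBT/linear-scan and LCA/SBT result equivalence;
* recovery of a five-genome 40/25/15/12/8% read mixture by `gather`
  (2500 reads of 100 bp over 1-Mb genomes, `scaled = 50` — coverage is
  kept low, ~0.05x, so that distinct-k-mer counts stay proportional to
  read counts and per-genome `p_query` is binomial around its weight);
* exact 70/30 species fractions for a mixture assembled from disjoint
  hash sets, and exact lineage recovery for pure genomes.

These sizes were chosen so the full suite runs in minutes on one CPU
while keeping every estimator in the regime its error model assumes.
What passing them does *not* show: robustness to sequencing error
profiles, indels, repeats, biased base composition, or real taxonomic
structure — uniform random genomes are the easiest case for MinHash
(near-zero background similarity), so the benchmarks validate the
*implementation* (estimators, bounds, equivalences, determinism), not
biological performance on hard datasets.

## Known limitations

* Containment is unweighted; abundance-aware containment and
  Jaccard-to-ANI conversion are out of scope.
* Cosine similarity over subsampled counts is a coarse instrument; see
  above.
* Cross-tool signature compatibility is not claimed: the hash function
  and seed are documented, but other MinHash implementations may differ.
* The LCA backend holds everything in memory; it is smaller on disk but
  costlier in RAM than the SBT directory layout.
* Non-standard genetic codes and IUPAC ambiguity expansion are not
  supported; ambiguous symbols always break windows.
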