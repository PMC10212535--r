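---
title: "Indexing k-mer abundances through s-mer decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing k-mer abundances through s-mer decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(kamq)
```

## The problem

Large sequencing collections are routinely queried through their k-mer
content: a dataset is represented by the set of its length-k substrings, and
a query sequence is matched by the fraction of its k-mers present in the
index. Many applications — metagenomics and metatranscriptomics in
particular — also need each k-mer's *abundance*, not just its presence.
Hash-table solutions that store (k-mer, count) pairs explicitly do not scale
to the billions of distinct k-mers in, say, a seawater metagenome, so
practical indexes fall back on counting approximate-membership-query (cAMQ)
structures: fixed-size arrays of small counters addressed by hashing, whose
responses are always either correct or overestimated, never underestimated.
The price is a substantial false positive rate — at the memory budgets used
for large collections, a single-hash counting Bloom filter is typically
sized around a 25% per-query false positive rate.

`kamq` implements a wrapping strategy that improves any such counting
filter without touching its layout or memory use. Instead of indexing
k-mers, it indexes their constituent **s-mers**, with `s = k - z` for a
small shrinkage `z`:

* **Build.** Every s-mer of every counted k-mer is inserted into the filter
  with the *s-abundance* `s_ab(m)` — the maximum abundance over all indexed
  k-mers containing the s-mer `m`. Collisions store the maximum of the
  colliding values.
* **Query.** A sequence is scanned once: the filter response of each of its
  s-mer windows is gathered, and the reported abundance of the k-mer
  starting at position `p` is the **minimum** response over the `z + 1`
  windows `p .. p + z`.

Because `s_ab(m) >= abundance(d)` for every s-mer `m` of an indexed k-mer
`d`, and the filter itself never underestimates, the minimum over a k-mer's
windows is always `>= abundance(d)`: there are **no false negatives and no
underestimates**, the same one-sided guarantee the bare filter offers. A
false positive now requires *all* `z + 1` s-mer lookups to fail
simultaneously; under an independence model the false positive rate drops
from `p` to roughly `p^(z+1)`:

```{r}
kmer_fpr(0.25, z = 3)   # a 25% filter queried through 4 s-mers
```

`z = 0` is an exact degeneration to the plain counting Bloom filter — same
bits, same answers — which the test suite asserts bit-for-bit.

## Errors the wrapping itself introduces

Two error modes are created by the decomposition, independently of the
filter, and the evaluation module separates them from hash collisions using
an exact oracle:

* **Construction false positives**: a k-mer absent from the indexed set
  whose s-mers all truly occur in it (in other k-mers). These exist no
  matter how large the filter is.
* **Construction overestimation**: a true-positive k-mer overlapping more
  abundant neighbors on both flanks, so that *every* s-mer in its minimal
  window carries an inflated `s_ab`. These errors are bounded by the
  neighbors' abundance, which keeps them close to the truth.

Both modes explode when `s` becomes so small that random sequences contain
essentially every s-mer. The probability that a fixed s-mer occurs in `n`
indexed characters is about `1 - (1 - 1/4^s)^n`:

```{r}
smer_saturation_prob(11, 2e7)  # s = 11 against 20 Mb: near-certain presence
```

Keeping `s` in the high twenties for `k = 31` (i.e. `z` of a few units)
stays far from this regime; the default is `z = 3`.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `k` | query/indexing word length (bases) | 31 | fixed by the k-mer counter used upstream |
| `z` | shrinkage; `s = k - z` | 3 | `z = 0` is the bare filter; results are robust for `z` up to ~9 at `k = 31`, collapse at extreme values |
| `b` | bits per counter slot | 5 | caps stored codes at `2^b - 1`; `b = 1` is a plain Bloom filter |
| `nb_slots` | filter slots; total size is `nb_slots * b` bits | — | sizes the per-s-mer false positive rate `1 - (1 - 1/m)^n` |
| `discretization` | abundance-to-rank map | `log2` | `min(floor(log2 x), 2^b - 1)`; also `log10`, `identity` |
| `canonical` | strand-insensitive indexing | off | lexicographic min of word and reverse complement |
| `abundance_mode` | `sab` derives s-abundances from counted k-mers; `raw` indexes a counted s-mer table as-is | `sab` | |

### Numerical and encoding choices

* **Absence sentinel.** A filter value of 0 must unambiguously mean
  "absent", but `floor(log2 1) = 0` is a legitimate rank. Under the log
  discretizations, stored codes are therefore ranks shifted up by one,
  saturating at `2^b - 1`; the largest reportable rank is `2^b - 2`, with
  the top bin open-ended. Identity mode stores `min(x, 2^b - 1)` directly
  and needs no shift. Queries expose both scales: `report = "rank"`
  (user-facing; rank 0 then conflates absence with the lowest bin) and
  `report = "stored"` (0 = absent, exactly the underlying filter's
  response). All evaluation is done on the stored scale.
* **Hashing.** One seed-free hash per word — FNV-1a over the 2-bit base
  encoding finalized with a splitmix64 mixer, reduced modulo `nb_slots` —
  so indexes are reproducible across runs and platforms; the hash name is
  recorded in the serialized index header. Uniformity is tested by
  chi-square on slot occupancy.
* **Canonicalization level.** The canonical flag is applied at the *s-mer*
  level on both build and query paths. Canonicalizing whole k-mers instead
  would break s-mer sharing across strand flips: the s-mers of a canonical
  k-mer are not the canonical s-mers of its reverse complement.
* **Non-ACGT characters.** Windows containing them are kept, flagged
  invalid, and respond 0, so every covering k-mer reports absent and
  positional alignment along reads is preserved. Truth lookups treat such
  k-mers as absent.
* **Ties and degenerate inputs.** Window minima over equal values need no
  tie-breaking; reads shorter than `k` yield empty rank vectors and are
  tallied as skipped; an empty table builds an empty (all-zero) filter.

## The fixed-window sliding minimum

Step two of the query is a sliding-window minimum with `W = z + 1`,
computed by the fixed-window algorithm: split the response vector into
non-overlapping blocks of size `W`; keep the running prefix minimum
(`minL`) of the current block in one scalar; when a block completes, write
its suffix minima (`minR`) backward *into the vector itself* — safe because
`r[i] <= minR[i] <= v[i]` — and emit `r[i] = min(minL[i+W-1], minR[i])`
over positions already consumed. Each element is touched at most twice:
linear time with no dependence on `W` and constant auxiliary storage, with
an `in_place` mode that avoids even the output allocation. A trailing block
shorter than `W` is handled as a shorter fixed window.

```{r}
sliding_window_min(c(5, 3, 7, 1, 4, 5, 3, 2, 2, 3), W = 3)
```

The test suite checks the algorithm exhaustively against a naive scan on
all small instances (every vector of length at most 8 over three values,
every window), on random instances, and via the max/min negation duality;
an instrumented reference verifies the comparison count stays below `3 |v|`
for every window size.

The absent-s-mer skipping optimization exploits the same structure at query
time: a response of 0 zeroes every k-mer window spanning it, so those
windows are emitted without inspection and trailing lookups can be elided.
The optimized path is asserted bit-identical to the two-step path.

## The synthetic harness

Evaluation needs index/query pairs with known ground truth at desk scale,
so the package generates them instead of downloading metagenomic samples:

* a uniform i.i.d. random genome (default 20 kb) supplies the indexed
  k-mers; counts are planted by an abundance profile — by default geometric
  with mean 3, capped at `2^b - 1 = 31`, a right-skewed profile in which
  low-abundance k-mers dominate, as in sequencing data;
* a second random genome, regenerated until it shares no k-mer with the
  first, supplies guaranteed-absent query material; reads (default 100 of
  100 bp) are sampled from both in a configurable mixture;
* absent k-mer probes for false-positive-rate estimation are drawn i.i.d.
  uniform and verified absent, which makes the `p^(z+1)` independence model
  applicable to them;
* the filter is sized from the distinct s-mer count to a target per-s-mer
  false positive rate (default 25%), mirroring how production filters are
  quoted.

Everything derives from one scenario seed through fixed per-operation
substreams, so artifacts are bit-reproducible and adding an operation never
perturbs earlier draws.

What the generator does *not* emulate: sequencing errors and quality
models, real abundance distributions, and — most importantly — the strong
abundance correlation between overlapping k-mers of real data. Because
counts are drawn independently per k-mer, adjacent k-mers differ in
abundance far more often than in a real sample, which makes construction
overestimation much more frequent here than in practice. Passing tests
therefore demonstrate the structural guarantees (no underestimation, exact
degeneration at `z = 0`, rate laws on absent probes) rather than the
absolute abundance-accuracy levels achievable on real data.

```{r}
sc <- synthetic_scenario(seed = 7, genome_length = 2000, k = 21, z = 3,
                         b = 5, read_count = 20, read_length = 60)
fpr_experiment(sc, z_values = 0:3, n_probes = 5000)
```

The `z = 0` row is the bare counting Bloom filter (same code path,
asserted identical to direct filter lookups); the false positive rate then
falls roughly geometrically with `z`, while the incorrect-abundance rate
among true positives *rises* with `z` — the construction-overestimation
cost of sharing s-mers, amplified by the uncorrelated synthetic counts.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data: genomes of 2–20 kb, filters of 10^3–10^6 slots, 10^4–10^6 probes.
These sizes were chosen so the whole suite completes in a few minutes on
one core while keeping binomial sampling error well below the effect sizes
being checked (3-standard-error bands are asserted explicitly). The same
code paths scale to production sizes — slot counts are doubles internally
and the filter is bit-packed — but multi-gigabyte indexes are outside what
the tests exercise.

## Known limitations

* Single index, single sample: no BIGSI/COBS-style multi-dataset matrices,
  and no online insertion after build.
* Only the counting-Bloom-filter backend ships; the build/query surface is
  backend-agnostic (any structure with max-insert/lookup semantics fits),
  but no quotient-filter implementation is provided.
* FASTQ parsing is strict 4-line records; multi-line FASTQ is rejected.
* The per-read mean rank averages over all k-mer positions, including
  invalid (non-ACGT) windows, which contribute 0.
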