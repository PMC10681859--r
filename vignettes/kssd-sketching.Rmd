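---
title: "Genome distance estimation by substring-space-decomposition sketching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome distance estimation by substring-space-decomposition sketching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kssdr)
```

## The model

A genome is reduced to the set of its canonical k-mers: every window of
`k` consecutive unambiguous bases, encoded in 2 bits per base
(A=0, C=1, G=2, T=3) and replaced by the smaller of its code and its
reverse-complement code so that strand does not matter. Windows containing
any non-ACGT symbol are skipped; input is case-insensitive.

Rather than hashing k-mers and keeping the smallest values (the MinHash
family), sketching here decomposes the *substring space*. Fix an even
substring length `s` and shuffle all `4^s` substring codes with a seeded
uniform permutation. The shuffled rank partitions the space into
`N = 16^L` equal subspaces; a k-mer is kept exactly when the rank of its
center substring falls below `4^s / N` (subspace 0). Because the center
substring of a random k-mer is uniform over the shuffled space, an
expected `1/N` fraction of distinct k-mers is kept, and — unlike MinHash —
membership of a k-mer in the sketch depends only on the k-mer itself, not
on the rest of the genome. That is what makes sketches of different
genomes directly intersectable and makes set algebra on sketches
meaningful.

A kept k-mer is encoded invertibly. With left flank length
`floor((k−s)/2)` (left-biased for odd `k−s`) and the remaining bases as
the right flank, the hash is

```
hash = (left_flank , right_flank) << (2s − 4L)  |  rank
```

`2(k−s)` flank bits above `2s − 4L` rank bits, `2k − 4L` bits in total.
The permutation is a bijection, so the map k-mer → hash is one-to-one and
`decode_hash()` recovers the k-mer exactly. Collision-freeness is not a
convenience: it is the property that makes sketch union, intersection and
subtraction *exact* set operations on the underlying k-mer sets, which the
variant-enrichment workflow (subtracting a reference pan-sketch from
sample sketches) relies on.

From two sketches, with `i = |S(A) ∩ S(B)|`:

* Jaccard `J = i / (|S(A)| + |S(B)| − i)`,
* containment `C = i / min(|S(A)|, |S(B)|)`,
* Mash distance `Dm = −(1/k) ln(2J/(1+J))`,
* AAF distance `Da = −(1/k) ln C`.

`Dm` estimates the per-base substitution rate under a Poisson model of
independent point mutations: a mutation destroys the k-mers covering it,
and inverting the expected surviving fraction gives the formula. The same
inversion gives `expected_jaccard(d, k) = e^{−kd} / (2 − e^{−kd})`, the
Jaccard at which `Dm` equals `d` exactly — the target used by the
parameter-recovery tests.

## Parameters and defaults

* `k` (k-mer length, default 21, `s ≤ k ≤ 32`): the usual genome-sketching
  compromise — long enough that random 21-mer collisions between unrelated
  bacterial-sized genomes are rare, short enough to tolerate divergence.
* `s` (substring length, default 12, even, ≤ 13): sets the table size
  `4^s` (16.7 M entries at `s = 12`, the practical ceiling for memory).
* `L` (reduction level, default 3): each level divides the kept fraction
  by 16; `L = 3` keeps 1/4096 of distinct k-mers, the default sampling
  rate. The constraint `2s ≥ 4L` keeps the rank width nonnegative.
* `max_dist` (default 1.0): emit every pair with a nonempty intersection.
  0.05 is the conventional screening threshold for "same-species"
  neighbours and must be requested explicitly.
* `threads` / `shards`: performance knobs only; every result is identical
  for any worker or shard count, which the test suite asserts.

Hash geometry follows from these: `hash_bits = 2k − 4L`, stored in 32-bit
records, switching to 64-bit records automatically when `hash_bits > 32`.

## Numerical and design choices

* **PRNG.** The shuffle is an in-place Fisher–Yates pass driven by
  splitmix64 with unbiased bounded draws (rejection sampling), so the
  permutation is uniform and reproducible from `(s, L, seed)`. The
  generator is part of the file-format contract only in the weak sense:
  portability comes from shipping the shuffle *file* (checksummed,
  magic-tagged), not from the generator, so tables written by any version
  remain usable.
* **Level convention.** The reduction level `L` and the subspace count
  `N = 16^L` are both recorded; `N` is derived from `L` (a 16-fold
  reduction per level). Any single subspace is statistically equivalent,
  so subspace 0 is fixed as the selected one and the within-subspace rank
  doubles as the invertible identifier — no per-subspace offset needed.
* **Center offset.** The center substring starts at `floor((k−s)/2)`,
  left-biased when `k − s` is odd. Any fixed offset works; it only has to
  be identical across all sketches compared.
* **Distance caps.** Both distance formulas diverge as the similarity
  approaches 0; `J = 0` and `C = 0` are reported as exactly 1.0 and all
  distances are clamped to `[0, 1]`. Pairs with an empty intersection are
  suppressed entirely unless `report_all = TRUE`.
* **Containment orientation.** `C` uses the `min` form, so it is symmetric
  as reported; records carry both sketch sizes so either directional
  containment can be recovered.
* **Thresholding filters on `Dm`.** The screening threshold applies to the
  Mash distance (the distance most tools screen on); filtering on `Da`
  instead can be emulated by post-filtering the unthresholded output.
* **Hash width limit.** Hash values cross the R boundary as doubles, which
  are exact integers up to 2^53. `sketch_params()` therefore rejects
  `2k − 4L > 53`. Every practically used geometry (defaults give 30 bits;
  `k = 32` with the default `s = 12, L = 3` gives 52) is far below the
  limit; the 32→64-bit storage switch happens at 33 bits as specified by
  the format.
* **Big/small task split.** Files at least `max(64 MiB, total/(4P))` are
  classified big and scheduled first. The contract that matters — no
  worker idles while a big file is unparsed, and results are independent
  of scheduling — is what the tests pin down; the constant is a
  reasonable default, not a tuned value.
* **Sharding.** Output shard = query index modulo shard count; each
  worker buffers its rows and flushes per shard in one unit; the global
  index maps every query to `(shard, byte offset, record count)` so a
  single query's rows can be read with one seek.
* **Degenerate inputs.** A file with no valid k-mer window yields an
  empty sketch and a warning, not an error; empty sketches survive set
  operations (with a warning) so genome ordering stays stable; empty
  reference sets are rejected when building the dictionary; corrupt or
  truncated binary files are caught by length checks and FNV-1a
  checksums.

## The memory contract

All-vs-all comparison never materializes an `m × n` intersection matrix.
The inverted index (hash → sorted reference IDs, covering exactly the
hashes present in the references) is built once; each in-flight query owns
a single `m`-length counter row that is acquired before streaming its
hashes through the postings and released immediately after. With `P`
workers the peak is `P · m` counters. The package instruments this
honestly: an allocation registry (`counter_reset()` / `counter_stats()`)
counts live and peak rows per process, each forked worker reports its own
peak (1), and `all_vs_all()` aggregates them into
`stats$peak_counters = P · m` — a measured value the tests compare against
both `P · m` and `m · n`.

## What the synthetic data does and does not show

`random_genome()` draws i.i.d. bases at a chosen GC fraction;
`mutate_genome()` applies independent per-site substitutions (uniform over
the three alternatives, no indels). This matches the assumptions of the
Mash-distance derivation, so the recovery target for a pair at rate `d`
is `Dm = d` itself, and it exercises every module: parsing, filtering,
hashing, the dictionary, distances, and set algebra.

It deliberately does *not* emulate repeats, GC gradients, indels, or
rearrangements. Passing parameter recovery on these genomes shows the
estimator and its implementation are correct under the model; on real
genomes, repeats and indels bias `Dm` relative to true ANI in the same
way they do for any k-mer sketching tool. Validation problem sizes were
chosen to make sampling noise small relative to the tolerances while
keeping the suite quick: recovery uses 1 Mb pairs at `k = 21, s = 12,
L = 2` (≈ 3,900-hash sketches) over five seeds per rate with a 10% median
relative-error budget; the sampling-fraction check uses a 100 kb genome
at the default 1/4096 rate against the central 99.99% binomial interval;
exactness checks (hash invertibility, full-space Jaccard, set algebra)
use exhaustive or brute-force oracles where exact equality, not a
tolerance, is asserted.

## Limitations

* One genome per file; multi-record files are concatenated (no per-contig
  sketches).
* No quality-aware FASTQ filtering or abundance thresholding: every valid
  window of every record counts.
* The hash space is capped at 53 bits (see above).
* Shuffle files and sketch archives use this package's own checksummed
  formats; they are self-describing but not interchangeable with other
  tools' binary formats.
* No p-values on shared-hash counts; distances are point estimates.
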