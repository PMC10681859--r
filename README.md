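# kssdr

Sketch-based genome distance estimation by **k-mer substring space
decomposition**, in R.

Comparing thousands of genomes k-mer by k-mer is infeasible; sketching
tools compare small, carefully chosen subsets of k-mer hashes instead.
`kssdr` implements the substring-space-decomposition flavour of sketching:
the space of all `4^s` length-`s` substrings is shuffled with a seeded
random permutation and partitioned into `N = 16^L` subspaces, and a k-mer
is kept for the sketch exactly when the length-`s` substring at its center
falls in the selected subspace. Roughly `1/N` of the distinct canonical
k-mers of a genome survive, and — crucially — the kept k-mers are encoded
with an **invertible (one-to-one) hash**: `2(k−s)` flank bits concatenated
with the `2s − 4L` within-subspace rank bits. No collisions means sketch
set algebra (union, intersection, subtraction) is *exact*, which is what
makes reference-based variant enrichment by k-mer subtraction sound.

For sketches `S(A)` and `S(B)` built from `k`-mers, the package estimates

- Jaccard index `J(A,B) ≈ |S(A) ∩ S(B)| / |S(A) ∪ S(B)|`
- containment `C(A,B) ≈ |S(A) ∩ S(B)| / min(|S(A)|, |S(B)|)`
- Mash distance `Dm = −(1/k) · ln( 2J / (1+J) )` (≈ per-base mutation
  distance, i.e. ≈ 1 − ANI)
- alignment-and-assembly-free (AAF) distance `Da = −(1/k) · ln C`

All-vs-all comparisons run through a single **unified inverted-index
dictionary** mapping each hash to the references containing it, holding
only `P·m` intersection counters for `P` workers and `m` references (never
an `m × n` matrix), and write sharded TSV output with a global index file
for random access. A synthetic-genome module generates mutated genome
pairs at a known substitution rate so the whole pipeline can be validated
by parameter recovery, without downloading anything.

## Worked example

Sketch a 100 kb genome and a mutant diverged at a substitution rate of
`d = 0.02`, then estimate their distance:

```r
library(kssdr)

tab <- generate_shuffle(shuffle_params(s = 8, L = 1, seed = 42))
#> substring-space shuffle: s = 8, L = 1 (N = 16 subspaces), seed = 42
#>   65536 codes, 4096 selected (fraction 1/16), id 3578e2e132385873

params <- sketch_params(16, tab)
dir <- tempfile(); dir.create(dir)
fx <- make_pair_fixture(100000, d = 0.02, seed = 1, out_dir = dir, k = 16)
set <- sketch_files(c(fx$fasta_a, fx$fasta_b), tab, params)
sketch_info(set)
#>      name sketch_size total_kmers distinct_kmers
#> 1 genomeA        6371       99985          99982
#> 2 genomeB        6350       99985          99983

run <- all_vs_all(set, set, file.path(dir, "dist"), max_dist = 0.05)
recs <- read_distances(file.path(dir, "dist"))
recs[recs$query != recs$reference, ]
#>     query reference shared size_q size_r  jaccard containment mash_dist aaf_dist
#> 2 genomeA   genomeB   4593   6371   6350 0.565084    0.723307  0.020348 0.020245
#> 3 genomeB   genomeA   4593   6350   6371 0.565084    0.723307  0.020348 0.020245
```

Each genome keeps about 1/16 of its ~100,000 distinct canonical 16-mers
(sketch sizes ~6,400). The two sketches share 4,593 hashes, giving
`J = 0.565`, and the Mash distance estimate `Dm = 0.0203` recovers the
simulated substitution rate of 0.02 to within 2%. `max_dist = 0.05` is
the conventional screening threshold: pairs farther apart are not
written.

The same pipeline is available from the shell via the installed
`exec/kssd` script: `kssd shuffle`, `kssd sketch`, `kssd dist`,
`kssd union`, `kssd sub`, `kssd intersect`, `kssd info`, and
`kssd fixtures`.

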