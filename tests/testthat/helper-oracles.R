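# Independent oracles, deliberately naive: string/matrix arithmetic in R,
# sharing no code with the compiled scanning/encoding path they check.

BASES4 <- c("A", "C", "G", "T")

# Canonical 2-bit code of every valid window, by explicit digit arithmetic.
naive_window_codes <- function(seq, k) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  d <- match(chars, BASES4) - 1L
  if (length(d) < k) return(numeric(0))
  m <- embed(d, k)[, k:1, drop = FALSE]  # one row per window, left to right
  valid <- rowSums(is.na(m)) == 0
  m <- m[valid, , drop = FALSE]
  pw <- 4^((k - 1):0)
  fwd <- as.vector(m %*% pw)
  rc <- as.vector((3 - m[, k:1, drop = FALSE]) %*% pw)
  pmin(fwd, rc)
}

naive_canonical_set <- function(seq, k) sort(unique(naive_window_codes(seq, k)))

# O(n^2) membership set algebra.
oracle_member <- function(x, set) vapply(x, function(v) any(set == v), logical(1L))
oracle_diff <- function(a, b) a[!oracle_member(a, b)]
oracle_intersect <- function(a, b) a[oracle_member(a, b)]
oracle_union <- function(a, b) c(a, b[!oracle_member(b, a)])
oracle_jaccard <- function(a, b) {
  u <- length(oracle_union(a, b))
  if (u == 0) 0 else length(oracle_intersect(a, b)) / u
}

# Large-set variants via base R's hash-table primitives, for oracle checks
# where the quadratic versions are too slow.
big_jaccard <- function(a, b) {
  u <- length(base::union(a, b))
  if (u == 0) 0 else length(base::intersect(a, b)) / u
}

# Code of a k-mer string, for spelling out expected values.
kmer_code <- function(kmer) {
  d <- match(strsplit(kmer, "", fixed = TRUE)[[1L]], BASES4) - 1L
  sum(d * 4^((length(d) - 1):0))
}

# Shared shuffle tables, built once per test run.
.table_cache <- new.env(parent = emptyenv())
get_table <- function(s, L, seed) {
  key <- sprintf("s%d_L%d_seed%.0f", s, L, seed)
  if (is.null(.table_cache[[key]]))
    .table_cache[[key]] <- generate_shuffle(shuffle_params(s = s, L = L,
                                                           seed = seed))
  .table_cache[[key]]
}

# Identity-permutation table for degenerate-case tests.
identity_table <- function(s, L) {
  kssdr:::new_shuffle_table(shuffle_params(s = s, L = L, seed = 0),
                            seq.int(0L, 4L^s - 1L))
}

write_genome_fasta <- function(seq, path, name = "genome") {
  kssdr:::write_fasta(name, seq, path)
  path
}

# A small family of related genomes: one ancestor plus mutants at the
# given substitution rates.
mutant_family_files <- function(dir, length, rates, seed, prefix = "g") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anc <- random_genome(length, seed = seed)
  paths <- character(length(rates) + 1L)
  paths[1L] <- file.path(dir, sprintf("%s00.fasta", prefix))
  write_genome_fasta(anc, paths[1L], sprintf("%s00", prefix))
  for (i in seq_along(rates)) {
    mut <- mutate_genome(anc, d = rates[i], seed = seed + i)
    paths[i + 1L] <- file.path(dir, sprintf("%s%02d.fasta", prefix, i))
    write_genome_fasta(mut, paths[i + 1L], sprintf("%s%02d", prefix, i))
  }
  paths
}

# Canonical comparable form of a distance-record data.frame.
normalize_records <- function(df) {
  df <- df[order(df$query, df$reference), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Hand-built sketch sets over a small 12-bit hash space (k=8, s=4, L=1),
# shared by the dictionary, set-operation and acceptance tests.
toy_params <- function() sketch_params(8, get_table(4, 1, 1))
setop_params <- toy_params

toy_set <- function(hash_lists, params = toy_params(),
                    names = sprintf("g%d", seq_along(hash_lists))) {
  sketch_set(params, Map(function(nm, h) {
    h <- sort(as.numeric(h))
    genome_sketch(nm, h, 2 * length(h) + 10, max(length(h), 1), params)
  }, names, hash_lists))
}
hash_set <- toy_set

pan_of <- function(hash_lists) union_sketches(hash_set(hash_lists))
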