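# Synthetic genomes with a known substitution rate. The point is parameter
# recovery: a pair diverged by per-base rate d should be estimated at Mash
# distance ~ d, so every downstream module is testable without downloads.

BASES <- c("A", "C", "G", "T")

# Run `expr` under a local RNG state so package randomness never disturbs
# the caller's .Random.seed.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random genome
#'
#' I.i.d. bases with a given GC fraction; deterministic per seed.
#'
#' @param length Genome length in bases, `>= 1`.
#' @param seed PRNG seed.
#' @param gc Target GC fraction, strictly between 0 and 1 (split evenly
#'   between G and C; AT likewise).
#' @return A single nucleotide string.
#' @examples
#' random_genome(30, seed = 1)
#' @export
random_genome <- function(length, seed, gc = 0.5) {
  if (!is.numeric(length) || length(length) != 1L || length < 1 ||
      length != trunc(length))
    stop("`length` must be a positive whole number", call. = FALSE)
  if (!is.numeric(gc) || length(gc) != 1L || gc <= 0 || gc >= 1)
    stop("`gc` must be strictly between 0 and 1", call. = FALSE)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_local_seed(seed, {
    paste(sample(BASES, length, replace = TRUE, prob = probs), collapse = "")
  })
}

#' Mutate a genome with i.i.d. substitutions
#'
#' Each site is independently substituted with probability `d`; a
#' substituted base is replaced by one of the three other bases uniformly.
#' No indels, so the Mash-distance derivation's point-mutation assumption
#' holds and the expected estimated distance is `d` itself.
#'
#' @param genome Nucleotide string over ACGT.
#' @param d Per-base substitution probability in `[0, 1]`.
#' @param seed PRNG seed.
#' @return The mutated string (same length).
#' @export
mutate_genome <- function(genome, d, seed) {
  stopifnot(is.character(genome), length(genome) == 1L)
  if (!is.numeric(d) || length(d) != 1L || d < 0 || d > 1)
    stop("`d` must be in [0, 1]", call. = FALSE)
  n <- nchar(genome)
  if (n == 0L || d == 0) return(genome)
  bases <- strsplit(genome, "", fixed = TRUE)[[1L]]
  code <- match(bases, BASES)
  if (anyNA(code)) stop("genome contains non-ACGT symbols", call. = FALSE)
  with_local_seed(seed, {
    hit <- which(stats::runif(n) < d)
    if (length(hit)) {
      # offset 1..3 cycles to one of the three other bases, uniformly
      offs <- sample.int(3L, length(hit), replace = TRUE)
      code[hit] <- (code[hit] - 1L + offs) %% 4L + 1L
    }
  })
  paste(BASES[code], collapse = "")
}

#' Expected sketch Jaccard at a substitution rate
#'
#' Inverts the Mash-distance formula: returns the Jaccard index `J` for
#' which `mash_distance(J, k) == d`, i.e.
#' `J = exp(-k d) / (2 - exp(-k d))`.
#'
#' @param d Per-base substitution rate in `[0, 1)`.
#' @param k K-mer length.
#' @return Expected Jaccard index.
#' @examples
#' expected_jaccard(0.02, 21)
#' mash_distance(expected_jaccard(0.05, 21), 21)  # 0.05
#' @export
expected_jaccard <- function(d, k) {
  if (any(d < 0) || any(d >= 1))
    stop("`d` must be in [0, 1)", call. = FALSE)
  stopifnot(k >= 1)
  e <- exp(-k * d)
  e / (2 - e)
}

# Write one sequence as wrapped FASTA.
write_fasta <- function(name, seq, path, width = 70L) {
  n <- nchar(seq)
  starts <- seq.int(1L, n, by = width)
  writeLines(c(paste0(">", name),
               substring(seq, starts, pmin(starts + width - 1L, n))),
             path)
  invisible(path)
}

#' Write a mutated genome pair fixture
#'
#' Generates genome A, its mutant B at substitution rate `d`, writes both
#' as FASTA plus a TSV manifest recording the parameters, the expected
#' sketch Jaccard at `k`, and the expected Mash distance (which is `d` by
#' construction). Byte-identical for fixed seeds.
#'
#' @param length Genome length.
#' @param d Per-base substitution rate.
#' @param seed Base seed; the genome uses `seed` and the mutation
#'   `seed + 1`.
#' @param out_dir Output directory (created if missing).
#' @param k K-mer length recorded in the manifest.
#' @param gc GC fraction of genome A.
#' @return Invisibly, a list with `fasta_a`, `fasta_b`, `manifest` paths
#'   and the manifest data.frame.
#' @export
make_pair_fixture <- function(length, d, seed, out_dir, k = 21L, gc = 0.5) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create fixture directory: ", out_dir, call. = FALSE)
  a <- random_genome(length, seed = seed, gc = gc)
  b <- mutate_genome(a, d = d, seed = seed + 1)
  fa <- file.path(out_dir, "genomeA.fasta")
  fb <- file.path(out_dir, "genomeB.fasta")
  write_fasta("genomeA", a, fa)
  write_fasta("genomeB", b, fb)
  manifest <- data.frame(
    length = length, d = d, seed_genome = seed, seed_mutation = seed + 1,
    gc = gc, k = k,
    expected_jaccard = expected_jaccard(d, k),
    expected_mash_dist = d)
  mf <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta_a = fa, fasta_b = fb, manifest = mf,
                 manifest_df = manifest))
}

#' Write a size-skewed multi-genome fixture
#'
#' Emits FASTA files with deliberately skewed sizes (one large genome plus
#' several small ones) for exercising big/small task partitioning and
#' load-balanced sketching.
#'
#' @param out_dir Output directory.
#' @param sizes Integer vector of genome lengths, one file per entry.
#' @param seed Base seed; file `i` uses `seed + i`.
#' @return Invisibly, the vector of written paths.
#' @export
make_size_skew_fixture <- function(out_dir,
                                   sizes = c(200000L, rep(10000L, 6L)),
                                   seed = 1L) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create fixture directory: ", out_dir, call. = FALSE)
  paths <- character(length(sizes))
  for (i in seq_along(sizes)) {
    g <- random_genome(sizes[i], seed = seed + i)
    paths[i] <- file.path(out_dir, sprintf("genome%02d.fasta", i))
    write_fasta(sprintf("genome%02d", i), g, paths[i])
  }
  invisible(paths)
}
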