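test_that("extract_kmers slides over valid windows and canonicalizes", {
  # "ACGTNACGT", k=4: six windows, the four touching N are skipped,
  # leaving the two "ACGT" windows; ACGT is its own reverse complement
  km <- extract_kmers("ACGTNACGT", 4)
  expect_identical(km, rep(kmer_code("ACGT"), 2))
  expect_length(unique(km), 1L)

  # forced by the canonical rule: min("AAAA", "TTTT") = "AAAA" = code 0
  expect_identical(extract_kmers("AAAA", 4), 0)

  # window count is length - k + 1 on a clean sequence
  g <- random_genome(1000, seed = 3)
  expect_length(extract_kmers(g, 4), 997L)

  # case-insensitive, and agrees with the naive scanner on messy input
  messy <- "acgtNNacGTtgcaXacgggtttNacacgt"
  for (k in c(3, 5, 8))
    expect_identical(extract_kmers(messy, k), naive_window_codes(messy, k))

  expect_length(extract_kmers("ACG", 4), 0L)
  expect_error(extract_kmers("ACGT", 0), "k")
})

test_that("canonicalize is idempotent and strand-invariant (exhaustive k=4)", {
  codes <- 0:255
  canon <- canonicalize(codes, 4)
  rc <- kssdr:::cpp_revcomp(codes, 4)
  expect_identical(canon, canonicalize(rc, 4))        # revcomp-invariant
  expect_identical(canon, canonicalize(canon, 4))     # idempotent
  expect_true(all(canon <= codes))
  # against the naive digit oracle
  naive <- vapply(codes, function(cd) {
    d <- (cd %/% 4^(3:0)) %% 4
    min(cd, sum((3 - rev(d)) * 4^(3:0)))
  }, numeric(1))
  expect_identical(canon, naive)
  expect_identical(canonicalize(kmer_code("TTTT"), 4), 0)
  expect_error(canonicalize(256, 4), "out of range")
})

test_that("hashing is one-to-one: exhaustive encode/decode on k=6, s=4, L=1", {
  tab <- get_table(4, 1, 1)
  p <- sketch_params(6, tab)
  codes <- as.numeric(0:4095)
  h <- encode_hash(codes, tab, p)
  kept <- !is.na(h)
  # exactly 1/16 of the substring space is selected, so 1/16 of codes kept
  expect_identical(sum(kept), 4096L %/% 16L)
  # injective on kept codes
  expect_identical(length(unique(h[kept])), sum(kept))
  expect_true(all(h[kept] < 2^p$hash_bits))
  # exact inverse on the image
  expect_identical(decode_hash(h[kept], tab, p), codes[kept])
})

test_that("degenerate full-space hashing reduces to the permutation", {
  # identity permutation, N=1, s=k: hash == perm[code] == code
  idt <- identity_table(s = 4, L = 0)
  p <- sketch_params(4, idt)
  codes <- as.numeric(0:255)
  expect_identical(encode_hash(codes, idt, p), codes)
  expect_identical(decode_hash(codes, idt, p), codes)

  # random permutation, N=1, s=k: hash == perm[code]
  tab <- get_table(4, 0, 5)
  p2 <- sketch_params(4, tab)
  expect_identical(encode_hash(codes, tab, p2), as.numeric(tab$perm))

  # hash one past the subspace (s=k so hash == rank) is invalid
  idt16 <- identity_table(s = 4, L = 1)
  p3 <- sketch_params(4, idt16)
  expect_error(decode_hash(16, idt16, p3), "invalid hash")
})

test_that("decode inverts encode on random kept k-mers at production scale", {
  tab <- get_table(12, 3, 11)
  p <- sketch_params(21, tab)
  set.seed(42)
  codes <- canonicalize(floor(runif(1e5) * 4^21), 21)
  h <- encode_hash(codes, tab, p)
  kept <- !is.na(h)
  expect_gt(sum(kept), 0)
  expect_identical(decode_hash(h[kept], tab, p), codes[kept])
})

test_that("sketch parameters derive hash geometry and validate k", {
  tab <- get_table(12, 3, 11)
  p <- sketch_params(21, tab)
  expect_identical(p$hash_bits, 30L)
  expect_identical(p$hash_width, 32L)
  expect_identical(p$shuffle_id, tab$id)
  # 64-bit storage exactly when 2k - 4L > 32
  expect_identical(sketch_params(22, tab)$hash_width, 32L)  # 32 bits
  expect_identical(sketch_params(23, tab)$hash_width, 64L)  # 34 bits
  expect_identical(sketch_params(25, tab)$hash_bits, 38L)
  expect_identical(sketch_params(25, tab)$hash_width, 64L)
  expect_error(sketch_params(11, tab), "out of range")       # k < s
  expect_error(sketch_params(33, tab), "out of range")
})

test_that("sketch_file handles degenerate inputs", {
  tab <- get_table(4, 1, 1)
  p <- sketch_params(6, tab)
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">allN", strrep("N", 100)), f)
  expect_warning(sk <- sketch_file(f, tab, p), "no valid k-mer")
  expect_length(sk$hashes, 0L)
  expect_identical(sk$total_kmers, 0)

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(sketch_file(empty, tab, p), "empty genome file")
  expect_error(sketch_file(file.path(tempdir(), "nope.fa"), tab, p),
               "cannot read")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("just text", bad)
  expect_error(sketch_file(bad, tab, p), "FASTA or FASTQ")
})

test_that("full-space sketches equal the naive distinct canonical k-mer set", {
  # L=0, s=k=8: the whole substring space is selected, so the decoded
  # sketch must be exactly the distinct canonical 8-mer set
  tab <- get_table(8, 0, 2)
  p <- sketch_params(8, tab)
  g <- random_genome(5000, seed = 9)
  f <- write_genome_fasta(g, withr::local_tempfile(fileext = ".fasta"))
  sk <- sketch_file(f, tab, p)
  expect_identical(sort(decode_hash(sk$hashes, tab, p)),
                   naive_canonical_set(g, 8))
  expect_identical(sk$total_kmers, 5000 - 8 + 1)
  expect_identical(sk$distinct_kmers, as.double(length(sk$hashes)))
})

test_that("gzip and FASTQ inputs yield the same sketch as plain FASTA", {
  tab <- get_table(4, 1, 1)
  p <- sketch_params(8, tab)
  g <- random_genome(2000, seed = 4)
  fa <- write_genome_fasta(g, withr::local_tempfile(fileext = ".fasta"))
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@read1", g, "+", strrep("I", nchar(g))), fq)
  gz <- withr::local_tempfile(fileext = ".fasta.gz")
  con <- gzfile(gz, "wt"); writeLines(c(">genome", g), con); close(con)

  ref <- sketch_file(fa, tab, p)
  expect_identical(sketch_file(fq, tab, p)$hashes, ref$hashes)
  expect_identical(sketch_file(gz, tab, p)$hashes, ref$hashes)
})

test_that("multi-record files are concatenated as one genome", {
  tab <- get_table(4, 1, 1)
  p <- sketch_params(8, tab)
  a <- random_genome(1500, seed = 5)
  b <- random_genome(1500, seed = 6)
  two <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", a, ">r2", b), two)
  sk <- sketch_file(two, tab, p)
  ha <- sketch_file(write_genome_fasta(a, withr::local_tempfile(fileext = ".fa")),
                    tab, p)$hashes
  hb <- sketch_file(write_genome_fasta(b, withr::local_tempfile(fileext = ".fa")),
                    tab, p)$hashes
  # no window spans the record boundary; hash set is the union
  expect_identical(sk$hashes, sort(unique(c(ha, hb))))
  expect_identical(sk$total_kmers, 2 * (1500 - 8 + 1))
})

test_that("kept fraction of distinct k-mers is binomially consistent with 1/N", {
  tab <- get_table(8, 1, 3)  # N = 16
  p <- sketch_params(16, tab)
  g <- random_genome(50000, seed = 12)
  f <- write_genome_fasta(g, withr::local_tempfile(fileext = ".fasta"))
  sk <- sketch_file(f, tab, p)
  n <- sk$distinct_kmers
  bounds <- qbinom(c(5e-5, 1 - 5e-5), n, 1 / 16)
  expect_gte(length(sk$hashes), bounds[1])
  expect_lte(length(sk$hashes), bounds[2])
})

test_that("task partitioning follows the big-file rule and covers every file", {
  MiB <- 1024^2
  files <- data.frame(path = sprintf("g%02d.fa", 1:11),
                      size = c(100 * MiB, rep(1 * MiB, 10)))
  plan <- partition_tasks(files, workers = 8)
  expect_identical(plan$big$path, "g01.fa")
  expect_identical(nrow(plan$small), 10L)
  expect_setequal(c(plan$big$path, plan$small$path), files$path)
  expect_identical(nrow(plan$big) + nrow(plan$small), nrow(files))

  all_small <- partition_tasks(data.frame(path = letters[1:4],
                                          size = rep(MiB, 4)), workers = 4)
  expect_identical(nrow(all_small$big), 0L)

  one_big <- partition_tasks(data.frame(path = "x", size = 200 * MiB),
                             workers = 1)
  expect_identical(nrow(one_big$big), 1L)

  empty <- partition_tasks(data.frame(path = character(), size = numeric()),
                           workers = 2)
  expect_identical(nrow(empty$big) + nrow(empty$small), 0L)
  expect_error(partition_tasks(files, workers = 0), ">= 1")
})

test_that("sketching a file list is deterministic for any worker count", {
  tab <- get_table(8, 1, 3)
  p <- sketch_params(16, tab)
  dir <- withr::local_tempdir()
  paths <- mutant_family_files(dir, length = 5000,
                               rates = rep(c(0.01, 0.05), 3), seed = 21)
  s1 <- sketch_files(paths, tab, p, threads = 1)
  s4 <- sketch_files(paths, tab, p, threads = 4)
  expect_identical(s1, s4)
  expect_identical(kssdr:::sketch_names(s1),
                   vapply(paths, kssdr:::genome_label, character(1),
                          USE.NAMES = FALSE))
})

test_that("sketch archives round-trip bit-exactly with the right record width", {
  tab <- get_table(8, 1, 3)
  p <- sketch_params(16, tab)
  dir <- withr::local_tempdir()
  paths <- mutant_family_files(dir, length = 3000, rates = c(0.02, 0.1),
                               seed = 31)
  set <- sketch_files(paths, tab, p)
  f <- withr::local_tempfile(fileext = ".sk")
  write_sketch_set(set, f)
  back <- read_sketch_set(f, table = tab)
  expect_identical(back$params, set$params)
  expect_equal(back$sketches, set$sketches, ignore_attr = FALSE)

  # rewriting gives byte-identical archives
  f2 <- withr::local_tempfile(fileext = ".sk")
  write_sketch_set(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))

  # 64-bit records exactly when hash_bits > 32: k=25, L=3 -> 38 bits
  tab12 <- get_table(12, 3, 11)
  p64 <- sketch_params(25, tab12)
  hashes <- c(0, 2^33, 2^38 - 1)
  wide <- sketch_set(p64, list(genome_sketch("w", hashes, 10, 5, p64)))
  f64 <- withr::local_tempfile(fileext = ".sk")
  write_sketch_set(wide, f64)
  # header 6 + body(6 + 8 + 4) + genome(2 + 1 + 24 + 3*8) + checksum 8
  expect_identical(file.size(f64), 6 + 18 + (2 + 1 + 24 + 3 * 8) + 8)
  expect_identical(read_sketch_set(f64)$sketches[[1]]$hashes, hashes)

  # corruption and mismatch diagnostics
  bytes <- readBin(f, "raw", file.size(f))
  bad <- withr::local_tempfile()
  writeBin(bytes[-length(bytes)], bad)
  expect_error(read_sketch_set(bad), "checksum|truncated")
  junk <- withr::local_tempfile()
  writeBin(charToRaw("KSWRONGMAGICFILE"), junk)
  expect_error(read_sketch_set(junk), "magic|truncated")
  other <- get_table(8, 1, 99)
  expect_error(read_sketch_set(f, table = other), "shuffle id mismatch")
})

test_that("programmatic sketch constructors validate their invariants", {
  tab <- get_table(4, 1, 1)
  p <- sketch_params(6, tab)
  expect_error(genome_sketch("x", c(3, 1, 2), 10, 5, p), "strictly increasing")
  expect_error(genome_sketch("x", c(1, 1), 10, 5, p), "strictly increasing")
  expect_error(genome_sketch("x", 2^p$hash_bits, 10, 5, p), "outside")
  expect_error(genome_sketch("x", c(1, 2, 3), 10, 2, p), "counter invariant")
  expect_error(sketch_set(p, list(genome_sketch("a", 1, 5, 3, p),
                                  genome_sketch("a", 2, 5, 3, p))),
               "duplicate")
})
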