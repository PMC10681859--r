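#' Sketching parameters
#'
#' Binds a k-mer length to a shuffle table and derives the hash geometry.
#' A kept k-mer is encoded as `2*(k - s)` flank bits concatenated with its
#' `2*s - 4*L` within-subspace rank bits, so the hash is `2*k - 4*L` bits
#' wide and one-to-one (no collisions, exact set algebra). Storage width is
#' 32 bits, switching to 64 bits automatically whenever `2*k - 4*L > 32`.
#'
#' @param k K-mer length in bases, `s <= k <= 32`.
#' @param table The `kssd_shuffle` table the sketches will be built against.
#' @return An object of class `kssd_sketch_params` with fields `k`, `s`,
#'   `L`, `hash_bits`, `hash_width` (32 or 64), and `shuffle_id`.
#' @examples
#' tab <- generate_shuffle(shuffle_params(s = 4, L = 1, seed = 1))
#' sketch_params(6, tab)
#' @export
sketch_params <- function(k, table) {
  stopifnot(inherits(table, "kssd_shuffle"))
  s <- table$params$s
  L <- table$params$L
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k))
    stop("`k` must be a single integer", call. = FALSE)
  k <- as.integer(k)
  if (k < s || k > 32L)
    stop("`k` out of range: need s <= k <= 32 (s = ", s, ", k = ", k, ")",
         call. = FALSE)
  hash_bits <- 2L * k - 4L * L
  if (hash_bits > 64L)
    stop("hash width 2*k - 4*L = ", hash_bits, " exceeds 64 bits", call. = FALSE)
  if (hash_bits > 53L)
    stop("hash width 2*k - 4*L = ", hash_bits,
         " bits is not exactly representable as an R double; ",
         "use a larger L or smaller k (limit 53 bits)", call. = FALSE)
  structure(
    list(k = k, s = s, L = L, hash_bits = hash_bits,
         hash_width = if (hash_bits > 32L) 64L else 32L,
         shuffle_id = table$id),
    class = "kssd_sketch_params"
  )
}

#' @export
print.kssd_sketch_params <- function(x, ...) {
  cat(sprintf(
    "sketch parameters: k = %d, s = %d, L = %d; hash %d bits (%d-bit storage)\n",
    x$k, x$s, x$L, x$hash_bits, x$hash_width))
  cat("  shuffle id ", x$shuffle_id, "\n", sep = "")
  invisible(x)
}

params_compatible <- function(a, b) {
  identical(a$k, b$k) && identical(a$s, b$s) && identical(a$L, b$L) &&
    identical(a$shuffle_id, b$shuffle_id)
}

check_table_params <- function(table, params) {
  if (table$params$s != params$s || table$params$L != params$L ||
      !identical(table$id, params$shuffle_id))
    stop("shuffle table does not match sketch parameters ",
         "(different s, L, or shuffle id)", call. = FALSE)
}

#' Canonical k-mers of a sequence
#'
#' Slides a window of `k` bases (step 1) over the sequence and emits the
#' canonical 2-bit code of every valid window. A window is valid when all
#' its bases are A/C/G/T (case-insensitive); windows containing any other
#' symbol are skipped. The canonical code is the smaller of the window's
#' code and its reverse complement under A=0, C=1, G=2, T=3, which makes
#' sketches strand-independent.
#'
#' @param sequence A single nucleotide string.
#' @param k K-mer length, `1 <= k <= 32`.
#' @return Numeric vector of canonical codes, one per valid window, in
#'   window order (possibly empty).
#' @examples
#' extract_kmers("ACGTNACGT", 4)  # two windows, both the code of "ACGT"
#' @export
extract_kmers <- function(sequence, k) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 32L)
    stop("`k` must be in [1, 32]", call. = FALSE)
  cpp_extract_kmers(sequence, k)
}

#' Canonicalize 2-bit k-mer codes
#'
#' Returns `min(code, revcomp(code))` under the encoding A=0, C=1, G=2,
#' T=3. Idempotent, and invariant under reverse complement.
#'
#' @param code Vector of 2-bit k-mer codes in `[0, 4^k)`.
#' @param k K-mer length.
#' @return Numeric vector of canonical codes.
#' @export
canonicalize <- function(code, k) {
  k <- as.integer(k)
  if (any(is.na(code)) || any(code < 0) || any(code >= 4^k))
    stop("k-mer code out of range [0, 4^", k, ")", call. = FALSE)
  cpp_canonicalize(as.double(code), k)
}

#' Invertible hash of canonical k-mers
#'
#' Extracts the center substring of length `s` (offset `floor((k-s)/2)`
#' from the left, left-biased for odd `k - s`), looks up its shuffled rank,
#' and, for k-mers in the selected subspace, packs flank bits above rank
#' bits: `hash = flank << (2s - 4L) | rank`, with the left flank above the
#' right flank. The mapping is one-to-one on kept k-mers, so
#' [decode_hash()] recovers the k-mer exactly.
#'
#' @param code Vector of canonical 2-bit k-mer codes.
#' @param table The `kssd_shuffle` table.
#' @param params A [sketch_params()] object consistent with `table`.
#' @return `encode_hash()`: numeric hashes, `NA` for rejected k-mers.
#'   `decode_hash()`: the canonical codes.
#' @examples
#' tab <- generate_shuffle(shuffle_params(s = 4, L = 1, seed = 1))
#' p <- sketch_params(6, tab)
#' h <- encode_hash(extract_kmers("ACGTACGTAC", 6), tab, p)
#' decode_hash(h[!is.na(h)], tab, p)
#' @export
encode_hash <- function(code, table, params) {
  stopifnot(inherits(table, "kssd_shuffle"))
  check_table_params(table, params)
  k <- params$k
  if (any(is.na(code)) || any(code < 0) || any(code >= 4^k))
    stop("k-mer code out of range [0, 4^", k, ")", call. = FALSE)
  cpp_encode_hash(as.double(code), k, params$s, params$L, table$perm)
}

#' @rdname encode_hash
#' @param hash Vector of hash values in `[0, 2^hash_bits)`.
#' @export
decode_hash <- function(hash, table, params) {
  stopifnot(inherits(table, "kssd_shuffle"))
  check_table_params(table, params)
  if (any(is.na(hash)))
    stop("invalid hash: NA", call. = FALSE)
  cpp_decode_hash(as.double(hash), params$k, params$s, params$L, table$perm)
}

#' Construct a genome sketch
#'
#' Low-level constructor for one genome's sketch: the sorted, deduplicated
#' set of kept k-mer hashes plus scan counters. [sketch_file()] builds these
#' from sequence files; this constructor is exported so sketches can also be
#' assembled programmatically (e.g. in simulations).
#'
#' @param name Genome label.
#' @param hashes Strictly increasing numeric vector of hash values.
#' @param total_kmers Number of valid k-mer windows scanned.
#' @param distinct_kmers Number of distinct canonical k-mers seen.
#' @param params A `kssd_sketch_params` object (used for range validation).
#' @return An object of class `kssd_sketch`.
#' @export
genome_sketch <- function(name, hashes, total_kmers, distinct_kmers, params) {
  hashes <- as.double(hashes)
  if (is.unsorted(hashes, strictly = TRUE))
    stop("`hashes` must be strictly increasing (sorted, deduplicated)",
         call. = FALSE)
  if (length(hashes) && (hashes[1L] < 0 || hashes[length(hashes)] >= 2^params$hash_bits))
    stop("hash value outside [0, 2^", params$hash_bits, ")", call. = FALSE)
  if (length(hashes) > distinct_kmers || distinct_kmers > total_kmers)
    stop("counter invariant violated: need |hashes| <= distinct_kmers <= total_kmers",
         call. = FALSE)
  structure(
    list(name = as.character(name), hashes = hashes,
         total_kmers = as.double(total_kmers),
         distinct_kmers = as.double(distinct_kmers)),
    class = "kssd_sketch"
  )
}

#' @export
print.kssd_sketch <- function(x, ...) {
  cat(sprintf("genome sketch '%s': %d hashes (%.0f windows, %.0f distinct k-mers)\n",
              x$name, length(x$hashes), x$total_kmers, x$distinct_kmers))
  invisible(x)
}

#' Construct a sketch set
#'
#' A collection of genome sketches sharing one parameter set and shuffle
#' table. Names must be unique; order is the input order and is preserved
#' by every operation.
#'
#' @param params A `kssd_sketch_params` object.
#' @param sketches List of `kssd_sketch` objects.
#' @return An object of class `kssd_sketch_set`.
#' @export
sketch_set <- function(params, sketches) {
  stopifnot(inherits(params, "kssd_sketch_params"))
  nm <- vapply(sketches, function(x) x$name, character(1L))
  if (anyDuplicated(nm))
    stop("duplicate genome names in sketch set: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  structure(list(params = params, sketches = sketches),
            class = "kssd_sketch_set")
}

#' @export
print.kssd_sketch_set <- function(x, ...) {
  cat(sprintf("sketch set: %d genomes, k = %d, s = %d, L = %d (%d-bit hashes)\n",
              length(x$sketches), x$params$k, x$params$s, x$params$L,
              x$params$hash_width))
  invisible(x)
}

#' @export
length.kssd_sketch_set <- function(x) length(x$sketches)

sketch_names <- function(set)
  vapply(set$sketches, `[[`, character(1L), "name", USE.NAMES = FALSE)

sketch_sizes <- function(set)
  vapply(set$sketches, function(s) length(s$hashes), integer(1L),
         USE.NAMES = FALSE)

# Strip directory, compression suffix and sequence-format extension.
genome_label <- function(path) {
  b <- basename(path)
  b <- sub("\\.gz$", "", b)
  sub("\\.(fa|fasta|fna|fq|fastq)$", "", b, ignore.case = TRUE)
}

# Read all records of a FASTA/FASTQ file (plain or gzip) as character
# sequences. Format is sniffed from the first byte.
read_genome_file <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    stop("cannot read genome file: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0L)
    stop("empty genome file: ", path, call. = FALSE)
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else stop("unrecognized sequence format (expected FASTA or FASTQ): ",
                   path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  if (length(seqs) == 0L)
    stop("no sequence records in file: ", path, call. = FALSE)
  as.character(seqs)
}

#' Sketch a genome file
#'
#' Parses every record of a FASTA/FASTQ file (plain or gzip-compressed; all
#' records are treated as one genome), scans canonical k-mers, filters them
#' through the selected subspace of `table`, and returns the sorted,
#' deduplicated hash set together with scan counters. About `1/N` of the
#' distinct canonical k-mers are kept.
#'
#' @param path Path to the sequence file.
#' @param table A `kssd_shuffle` table.
#' @param params A [sketch_params()] object built against `table`.
#' @param name Genome label; defaults to the file name without extensions.
#' @return A `kssd_sketch`.
#' @export
sketch_file <- function(path, table, params, name = genome_label(path)) {
  check_table_params(table, params)
  seqs <- read_genome_file(path)
  res <- cpp_sketch_sequences(seqs, params$k, params$s, params$L, table$perm)
  if (res$total_kmers == 0)
    warning("no valid k-mer window in ", path, "; sketch is empty",
            call. = FALSE)
  genome_sketch(name, res$hashes, res$total_kmers, res$distinct_kmers, params)
}

#' Partition genome files into big and small sketching tasks
#'
#' Files at least `max(64 MiB, total_size / (4 * workers))` are classified
#' as big and scheduled first (conceptually parsed by a multi-worker
#' parser); the remaining small files are handled one per worker. The point
#' of the split is load balance: no worker sits idle while a big file is
#' still unparsed.
#'
#' @param files Character vector of paths, or a data.frame with columns
#'   `path` and `size`.
#' @param workers Number of workers `P >= 1`.
#' @return An object of class `kssd_task_plan` with data.frames `big` and
#'   `small` (columns `path`, `size`); together they cover the input list
#'   exactly once.
#' @export
partition_tasks <- function(files, workers = 1L) {
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L)
    stop("`workers` must be >= 1", call. = FALSE)
  if (is.character(files))
    files <- data.frame(path = files, size = file.size(files),
                        stringsAsFactors = FALSE)
  stopifnot(all(c("path", "size") %in% names(files)))
  if (any(is.na(files$size)) || any(files$size < 0))
    stop("file sizes must be nonnegative (missing file?)", call. = FALSE)
  threshold <- max(64 * 1024^2, sum(files$size) / (4 * workers))
  big <- files$size >= threshold & nrow(files) > 0
  structure(
    list(big = files[big, , drop = FALSE],
         small = files[!big, , drop = FALSE],
         workers = workers, threshold = threshold),
    class = "kssd_task_plan"
  )
}

#' @export
print.kssd_task_plan <- function(x, ...) {
  cat(sprintf("task plan: %d big, %d small files (threshold %.1f MiB, %d workers)\n",
              nrow(x$big), nrow(x$small), x$threshold / 1024^2, x$workers))
  invisible(x)
}

#' Sketch a list of genome files
#'
#' Builds one sketch per file. Big files (see [partition_tasks()]) are
#' scheduled before small ones so no worker idles behind a large parse;
#' results are returned in input-list order regardless of the worker count,
#' so the output is deterministic for any `threads`.
#'
#' @param paths Character vector of FASTA/FASTQ paths (plain or gzip).
#' @param table A `kssd_shuffle` table.
#' @param params A [sketch_params()] object built against `table`.
#' @param threads Number of parallel workers (forked; 1 = sequential).
#' @param names Genome labels; default derived from file names.
#' @return A `kssd_sketch_set` in input order.
#' @export
sketch_files <- function(paths, table, params, threads = 1L,
                         names = vapply(paths, genome_label, character(1L))) {
  check_table_params(table, params)
  if (length(paths) == 0L) return(sketch_set(params, list()))
  if (anyDuplicated(names))
    stop("duplicate genome names; pass unique `names`", call. = FALSE)
  sizes <- file.size(paths)
  if (anyNA(sizes))
    stop("cannot read genome file: ",
         paste(paths[is.na(sizes)], collapse = ", "), call. = FALSE)
  plan <- partition_tasks(data.frame(path = paths, size = sizes,
                                     stringsAsFactors = FALSE),
                          workers = threads)
  is_big <- sizes >= plan$threshold
  sched <- c(which(is_big), which(!is_big))  # big files first
  work <- function(i) sketch_file(paths[i], table, params, name = names[i])
  res <- run_workers(sched, work, threads)
  sketches <- vector("list", length(paths))
  sketches[sched] <- res
  sketch_set(params, sketches)
}

# Fork-based worker pool; falls back to sequential where forking is
# unavailable. Results come back in the order of `items`.
run_workers <- function(items, fun, threads) {
  threads <- as.integer(threads)
  if (threads > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(items, fun, mc.cores = threads,
                              mc.preschedule = TRUE)
    err <- vapply(res, inherits, logical(1L), "try-error")
    if (any(err)) stop(attr(res[[which(err)[1L]]], "condition"))
    res
  } else {
    lapply(items, fun)
  }
}

SKETCH_MAGIC <- "KSSSK1"
SKETCH_VERSION <- 1L

#' Write and read sketch archives
#'
#' Binary archive holding a whole sketch set. Layout: magic `"KSSSK1"`,
#' then a body of `u8 version`, `u8 k`, `u8 s`, `u8 L`, `u8 hash_bits`,
#' `u8 hash_width`, `u64 shuffle id`, `u32 genome count`, and per genome
#' `u16 name length`, UTF-8 name, `u64 total_kmers`, `u64 distinct_kmers`,
#' `u64 hash count`, and the sorted hashes as little-endian records of
#' `hash_width / 8` bytes; a trailing `u64` FNV-1a checksum over the body
#' detects corruption. The round trip is bit-exact.
#'
#' @param set A `kssd_sketch_set`.
#' @param path File path.
#' @return `write_sketch_set()` returns `path` invisibly;
#'   `read_sketch_set()` returns the `kssd_sketch_set`.
#' @export
write_sketch_set <- function(set, path) {
  stopifnot(inherits(set, "kssd_sketch_set"))
  p <- set$params
  id_raw <- hex_to_raw(p$shuffle_id)
  width <- p$hash_width %/% 8L
  chunks <- list(as.raw(c(SKETCH_VERSION, p$k, p$s, p$L, p$hash_bits,
                          p$hash_width)),
                 id_raw,
                 pack_u32(length(set$sketches)))
  for (sk in set$sketches) {
    nm <- charToRaw(enc2utf8(sk$name))
    chunks[[length(chunks) + 1L]] <- c(
      pack_u16(length(nm)), nm,
      pack_u64(c(sk$total_kmers, sk$distinct_kmers, length(sk$hashes))),
      cpp_pack_values(sk$hashes, width))
  }
  body <- do.call(c, chunks)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(SKETCH_MAGIC), con)
  writeBin(body, con)
  writeBin(cpp_fnv1a(body), con)
  invisible(path)
}

#' @rdname write_sketch_set
#' @param table Optional `kssd_shuffle` table; when given, its id must match
#'   the archive's stored shuffle id (configuration error otherwise).
#' @export
read_sketch_set <- function(path, table = NULL) {
  if (!file.exists(path))
    stop("sketch archive not found: ", path, call. = FALSE)
  size <- file.size(path)
  magic_n <- nchar(SKETCH_MAGIC)
  if (size < magic_n + 8L)
    stop("truncated sketch archive: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = magic_n)
  if (!identical(rawToChar(magic), SKETCH_MAGIC))
    stop("not a sketch archive (bad magic): ", path, call. = FALSE)
  body <- readBin(con, "raw", n = size - magic_n - 8L)
  stored_sum <- read_exact(con, 8L, "checksum", path)
  if (!identical(cpp_fnv1a(body), stored_sum))
    stop("sketch archive checksum mismatch: ", path, call. = FALSE)

  pos <- 1L
  take <- function(n) {
    if (n == 0L) return(raw(0))
    if (pos + n - 1L > length(body))
      stop("truncated sketch archive: ", path, call. = FALSE)
    out <- body[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  hdr <- as.integer(take(6L))
  if (hdr[1L] != SKETCH_VERSION)
    stop("unsupported sketch archive version ", hdr[1L], ": ", path,
         call. = FALSE)
  k <- hdr[2L]; s <- hdr[3L]; L <- hdr[4L]
  hash_bits <- hdr[5L]; hash_width <- hdr[6L]
  if (hash_bits != 2L * k - 4L * L || hash_width != if (hash_bits > 32L) 64L else 32L)
    stop("inconsistent hash geometry in sketch archive: ", path, call. = FALSE)
  shuffle_id <- raw_to_hex(take(8L))
  if (!is.null(table) && !identical(table$id, shuffle_id))
    stop("shuffle id mismatch: archive was built against a different ",
         "shuffle table", call. = FALSE)
  params <- structure(
    list(k = k, s = s, L = L, hash_bits = hash_bits,
         hash_width = hash_width, shuffle_id = shuffle_id),
    class = "kssd_sketch_params")
  n_genomes <- unpack_u32(take(4L))
  width <- hash_width %/% 8L
  sketches <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    name_len <- unpack_u16(take(2L))
    name <- rawToChar(take(name_len))
    Encoding(name) <- "UTF-8"
    counters <- unpack_u64(take(24L))
    hashes <- cpp_unpack_values(take(as.integer(counters[3L]) * width), width)
    sketches[[i]] <- genome_sketch(name, hashes, counters[1L], counters[2L],
                                   params)
  }
  if (pos != length(body) + 1L)
    stop("trailing bytes in sketch archive: ", path, call. = FALSE)
  sketch_set(params, sketches)
}

pack_u16 <- function(x) cpp_pack_values(as.double(x), 2L)
unpack_u16 <- function(b) as.integer(cpp_unpack_values(b, 2L))
pack_u32 <- function(x) cpp_pack_values(as.double(x), 4L)
unpack_u32 <- function(b) as.integer(cpp_unpack_values(b, 4L))

hex_to_raw <- function(hex) {
  as.raw(strtoi(substring(hex, seq(1L, nchar(hex), 2L),
                          seq(2L, nchar(hex), 2L)), 16L))
}
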