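#' Parameters of a substring-space decomposition
#'
#' The sketching rate is controlled by decomposing the space of all `4^s`
#' length-`s` substrings into `N = 16^L` subspaces with a seeded random
#' permutation; k-mers whose center substring lands in subspace 0 are kept,
#' so roughly `1/N` of distinct k-mers enter a sketch.
#'
#' @param s Substring length in bases. Must be even, with `2 <= s <= 13`.
#' @param L Dimensionality-reduction level, an integer `>= 0`. The number of
#'   subspaces is `N = 16^L`; each level reduces the sketch a further 16-fold.
#'   Requires `2*s >= 4*L` so the within-subspace rank has a nonnegative
#'   bit width `2*s - 4*L`.
#' @param seed Seed of the deterministic 64-bit generator (splitmix64)
#'   driving the shuffle. A nonnegative whole number below 2^53.
#' @return An object of class `kssd_shuffle_params` with fields `s`, `L`,
#'   `N`, and `seed`.
#' @examples
#' shuffle_params(s = 4, L = 1, seed = 1)
#' @export
shuffle_params <- function(s = 12L, L = 3L, seed = 11L) {
  if (!is.numeric(s) || length(s) != 1L || s != as.integer(s))
    stop("`s` must be a single integer", call. = FALSE)
  s <- as.integer(s)
  if (s < 2L || s > 13L)
    stop("`s` out of range: need 2 <= s <= 13, got ", s, call. = FALSE)
  if (s %% 2L != 0L)
    stop("`s` must be even, got ", s, call. = FALSE)
  if (!is.numeric(L) || length(L) != 1L || L != as.integer(L) || L < 0)
    stop("`L` must be a single nonnegative integer", call. = FALSE)
  L <- as.integer(L)
  if (2L * s < 4L * L)
    stop("constraint 2*s >= 4*L violated (s = ", s, ", L = ", L,
         "): the within-subspace rank would have negative bit width",
         call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed < 0 || seed >= 2^53 || seed != trunc(seed))
    stop("`seed` must be a nonnegative whole number below 2^53", call. = FALSE)
  structure(
    list(s = s, L = L, N = as.double(16)^L, seed = as.double(seed)),
    class = "kssd_shuffle_params"
  )
}

#' @export
print.kssd_shuffle_params <- function(x, ...) {
  cat(sprintf("substring-space parameters: s = %d, L = %d, N = %.0f, seed = %.0f\n",
              x$s, x$L, x$N, x$seed))
  invisible(x)
}

#' Generate a shuffled substring-space table
#'
#' Draws a uniform random permutation of the `4^s` substring codes with an
#' in-place Fisher-Yates shuffle driven by splitmix64 (unbiased bounded
#' draws by rejection). Codes whose shuffled rank falls below `4^s / N`
#' belong to the selected subspace; the rank itself is the invertible
#' within-subspace identifier used by [encode_hash()].
#'
#' @param params A [shuffle_params()] object.
#' @return An object of class `kssd_shuffle` with fields `params`, `perm`
#'   (integer vector of length `4^s`, 0-based shuffled ranks), and `id`
#'   (hex checksum identifying the table; sketches record it so that
#'   incompatible shuffles are never mixed).
#' @examples
#' tab <- generate_shuffle(shuffle_params(s = 4, L = 1, seed = 1))
#' sum(tab$perm < 4^4 / 16)  # exactly 16 codes selected
#' @export
generate_shuffle <- function(params) {
  if (!inherits(params, "kssd_shuffle_params"))
    stop("`params` must come from shuffle_params()", call. = FALSE)
  perm <- cpp_generate_perm(params$s, params$seed)
  new_shuffle_table(params, perm)
}

# Internal constructor; validates nothing beyond structure so tests can
# build degenerate tables (e.g. the identity permutation).
new_shuffle_table <- function(params, perm) {
  id_raw <- cpp_fnv1a_u32(perm)
  structure(
    list(params = params, perm = perm,
         id = paste(format(id_raw), collapse = ""), id_raw = id_raw),
    class = "kssd_shuffle"
  )
}

#' @export
print.kssd_shuffle <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "substring-space shuffle: s = %d, L = %d (N = %.0f subspaces), seed = %.0f\n",
    p$s, p$L, p$N, p$seed))
  cat(sprintf("  %d codes, %.0f selected (fraction 1/%.0f), id %s\n",
              length(x$perm), 4^p$s / p$N, p$N, x$id))
  invisible(x)
}

# Size of the selected subspace, 4^s / N = 2^(2s - 4L).
subspace_size <- function(table) {
  2^(2L * table$params$s - 4L * table$params$L)
}

#' Within-subspace rank of substring codes
#'
#' Looks up the shuffled rank of each substring code: an amortized
#' constant-cost membership test. Codes in the selected subspace (rank
#' below `4^s / N`) return their rank; all other codes are rejected and
#' return `NA`.
#'
#' @param table A `kssd_shuffle` table.
#' @param code Vector of substring codes in `[0, 4^s)`.
#' @return Integer vector: the rank for selected codes, `NA` for rejected
#'   ones.
#' @examples
#' tab <- generate_shuffle(shuffle_params(s = 4, L = 1, seed = 1))
#' sum(!is.na(subspace_rank(tab, 0:255)))  # 16
#' @export
subspace_rank <- function(table, code) {
  stopifnot(inherits(table, "kssd_shuffle"))
  n <- length(table$perm)
  if (any(is.na(code)) || any(code < 0) || any(code >= n))
    stop("substring code out of range [0, ", n, ")", call. = FALSE)
  r <- table$perm[as.integer(code) + 1L]
  r[r >= subspace_size(table)] <- NA_integer_
  r
}

SHUF_MAGIC <- "KSSHUF1"

#' Write and read shuffle files
#'
#' The shuffle table is what makes sketches comparable across runs and
#' machines, so it is shipped as a file rather than re-derived from the
#' generator. Binary layout: magic `"KSSHUF1"`, `u8 s`, `u8 L`, `u64 seed`,
#' `u64 checksum` (FNV-1a over the body), then `4^s` unsigned 32-bit
#' little-endian rank values. Corruption and truncation are caught by the
#' length and the checksum.
#'
#' @param table A `kssd_shuffle` table.
#' @param path File path.
#' @return `write_shuffle()` returns `path` invisibly; `read_shuffle()`
#'   returns the `kssd_shuffle` table.
#' @examples
#' tab <- generate_shuffle(shuffle_params(s = 4, L = 1, seed = 1))
#' f <- tempfile(fileext = ".shuf")
#' write_shuffle(tab, f)
#' identical(read_shuffle(f)$perm, tab$perm)
#' @export
write_shuffle <- function(table, path) {
  stopifnot(inherits(table, "kssd_shuffle"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(SHUF_MAGIC), con)
  writeBin(as.raw(c(table$params$s, table$params$L)), con)
  writeBin(pack_u64(table$params$seed), con)
  writeBin(table$id_raw, con)
  writeBin(table$perm, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_shuffle
#' @export
read_shuffle <- function(path) {
  if (!file.exists(path))
    stop("shuffle file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = nchar(SHUF_MAGIC))
  if (length(magic) < nchar(SHUF_MAGIC) ||
      !identical(rawToChar(magic), SHUF_MAGIC))
    stop("not a shuffle file (bad magic): ", path, call. = FALSE)
  hdr <- readBin(con, "raw", n = 2L)
  if (length(hdr) < 2L) stop("truncated shuffle file: ", path, call. = FALSE)
  s <- as.integer(hdr[1L]); L <- as.integer(hdr[2L])
  seed_raw <- readBin(con, "raw", n = 8L)
  sum_raw <- readBin(con, "raw", n = 8L)
  if (length(seed_raw) < 8L || length(sum_raw) < 8L)
    stop("truncated shuffle file: ", path, call. = FALSE)
  n <- 4L^s
  perm <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  if (length(perm) != n || length(readBin(con, "raw", n = 1L)) != 0L)
    stop("truncated or oversized shuffle file: ", path, call. = FALSE)
  if (!identical(cpp_fnv1a_u32(perm), sum_raw))
    stop("shuffle file checksum mismatch: ", path, call. = FALSE)
  new_shuffle_table(shuffle_params(s = s, L = L, seed = unpack_u64(seed_raw)),
                    perm)
}
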