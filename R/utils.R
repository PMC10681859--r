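# Little-endian u64 <-> double helpers. Values are exact below 2^53, which
# every stored quantity (seeds, counters, hash values) is constrained to.
pack_u64 <- function(x) cpp_pack_values(as.double(x), 8L)

unpack_u64 <- function(bytes) cpp_unpack_values(bytes, 8L)

raw_to_hex <- function(bytes) paste(format(bytes), collapse = "")

# Read exactly n bytes or fail with the caller-supplied context.
read_exact <- function(con, n, what, path) {
  bytes <- readBin(con, "raw", n = n)
  if (length(bytes) != n)
    stop("truncated file (while reading ", what, "): ", path, call. = FALSE)
  bytes
}

`%||%` <- function(a, b) if (is.null(a)) b else a
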