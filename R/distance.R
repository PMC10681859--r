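# Instrumentation registry for the P*m memory contract: every in-flight
# query owns exactly one m-length counter row, acquired before the postings
# walk and released right after. Tests read the peak through counter_stats().
.counter_registry <- new.env(parent = emptyenv())
.counter_registry$live <- 0L
.counter_registry$peak <- 0L

#' Counter-row instrumentation
#'
#' The all-vs-all engine never materializes an `m x n` intersection matrix:
#' each in-flight query holds one `m`-length counter row, so with `P`
#' workers at most `P * m` counters are live. `counter_reset()` zeroes the
#' registry and `counter_stats()` reports the number of counter rows
#' currently live and the peak since the last reset (per process; forked
#' workers track their own peaks, which [all_vs_all()] aggregates).
#'
#' @return `counter_stats()`: list with `live` and `peak` row counts.
#' @export
counter_reset <- function() {
  .counter_registry$live <- 0L
  .counter_registry$peak <- 0L
  invisible(NULL)
}

#' @rdname counter_reset
#' @export
counter_stats <- function() {
  list(live = .counter_registry$live, peak = .counter_registry$peak)
}

counter_acquire <- function() {
  .counter_registry$live <- .counter_registry$live + 1L
  if (.counter_registry$live > .counter_registry$peak)
    .counter_registry$peak <- .counter_registry$live
  invisible(NULL)
}

counter_release <- function() {
  .counter_registry$live <- .counter_registry$live - 1L
  invisible(NULL)
}

#' Build the unified inverted-index dictionary
#'
#' Inverts a reference sketch set into a single map from hash value to the
#' sorted list of reference IDs containing it. The dictionary exclusively
#' includes hashes present in the sketches (no slot for absent values), and
#' one unified dictionary covers all references regardless of hash width —
#' no sub-dictionary passes.
#'
#' @param refs A `kssd_sketch_set` of reference genomes.
#' @return An object of class `kssd_index`: `m`, `ref_names`, `ref_sizes`,
#'   sorted `keys`, and `postings` (list parallel to `keys` of 1-based
#'   reference IDs).
#' @export
build_index <- function(refs) {
  stopifnot(inherits(refs, "kssd_sketch_set"))
  if (length(refs$sketches) == 0L)
    stop("reference sketch set is empty", call. = FALSE)
  m <- length(refs$sketches)
  lens <- sketch_sizes(refs)
  all_h <- unlist(lapply(refs$sketches, `[[`, "hashes"), use.names = FALSE)
  ids <- rep.int(seq_len(m), lens)
  if (length(all_h) == 0L) {
    keys <- numeric(0)
    postings <- list()
  } else {
    o <- order(all_h, ids)
    h <- all_h[o]
    ids <- ids[o]
    new_key <- c(TRUE, h[-1L] != h[-length(h)])
    keys <- h[new_key]
    postings <- split(ids, cumsum(new_key))
    names(postings) <- NULL
  }
  structure(
    list(m = m, ref_names = sketch_names(refs), ref_sizes = lens,
         keys = keys, postings = postings, params = refs$params),
    class = "kssd_index"
  )
}

#' @export
print.kssd_index <- function(x, ...) {
  cat(sprintf("unified indexed dictionary: %d references, %d hash keys, %d postings\n",
              x$m, length(x$keys), sum(lengths(x$postings))))
  invisible(x)
}

#' Intersection counts of one query against all references
#'
#' Streams the query's hashes through the dictionary postings and
#' accumulates shared-hash counts into a fresh `m`-length counter row (the
#' `P * m` contract: one live row per in-flight query).
#'
#' @param query A `kssd_sketch`.
#' @param index A [build_index()] dictionary.
#' @return Integer vector of length `m`: `counts[r] == |S(q) ∩ S(r)|`.
#' @export
intersections_for_query <- function(query, index) {
  stopifnot(inherits(query, "kssd_sketch"), inherits(index, "kssd_index"))
  counter_acquire()
  on.exit(counter_release())
  q <- query$hashes
  if (length(q) == 0L || length(index$keys) == 0L)
    return(integer(index$m))
  pos <- findInterval(q, index$keys)
  hit <- pos > 0L & index$keys[pmax(pos, 1L)] == q
  if (!any(hit)) return(integer(index$m))
  tabulate(unlist(index$postings[pos[hit]], use.names = FALSE),
           nbins = index$m)
}

#' Sketch similarity and distance estimators
#'
#' From an intersection count and two sketch sizes:
#' Jaccard `J = inter / (|Sq| + |Sr| - inter)`; containment
#' `C = inter / min(|Sq|, |Sr|)` (orientation-free by the min); Mash
#' distance `Dm = -(1/k) * ln(2J / (1 + J))`, an estimate of the per-base
#' mutation distance (about `1 - ANI`); and the
#' alignment-and-assembly-free distance `Da = -(1/k) * ln(C)`. The
#' distances diverge at `J = 0` / `C = 0` and are capped there at exactly
#' 1.0; all distances are clamped to `[0, 1]`.
#'
#' @param inter Intersection count `|S(q) ∩ S(r)|`.
#' @param size_q,size_r Sketch sizes.
#' @param J Jaccard index in `[0, 1]`.
#' @param C Containment coefficient in `[0, 1]`.
#' @param k K-mer length used to build the sketches.
#' @return Numeric vector (vectorized over the inputs).
#' @examples
#' jaccard(40, 100, 80)         # 40/140
#' containment(40, 100, 80)     # 0.5
#' mash_distance(0.5, 21)
#' aaf_distance(0.25, 21)
#' @export
jaccard <- function(inter, size_q, size_r) {
  check_inter(inter, size_q, size_r)
  denom <- size_q + size_r - inter
  ifelse(denom == 0, 0, inter / denom)
}

#' @rdname jaccard
#' @export
containment <- function(inter, size_q, size_r) {
  check_inter(inter, size_q, size_r)
  mn <- pmin(size_q, size_r)
  if (any(mn == 0)) {
    warning("containment of an empty sketch is reported as 0", call. = FALSE)
  }
  ifelse(mn == 0, 0, inter / mn)
}

check_inter <- function(inter, size_q, size_r) {
  if (any(inter < 0) || any(inter > pmin(size_q, size_r)))
    stop("contract violation: need 0 <= inter <= min(size_q, size_r)",
         call. = FALSE)
  invisible(NULL)
}

#' @rdname jaccard
#' @export
mash_distance <- function(J, k) {
  if (any(is.na(J)) || any(J < 0) || any(J > 1))
    stop("Jaccard index outside [0, 1]", call. = FALSE)
  stopifnot(k >= 1)
  ifelse(J == 0, 1, pmin(1, pmax(0, -(1 / k) * log(2 * J / (1 + J)))))
}

#' @rdname jaccard
#' @export
aaf_distance <- function(C, k) {
  if (any(is.na(C)) || any(C < 0) || any(C > 1))
    stop("containment coefficient outside [0, 1]", call. = FALSE)
  stopifnot(k >= 1)
  ifelse(C == 0, 1, pmin(1, pmax(0, -(1 / k) * log(C))))
}

# Distance records of one query against all references, already filtered.
query_records <- function(qi, queries, index, max_dist, report_all, k) {
  sk <- queries$sketches[[qi]]
  counts <- intersections_for_query(sk, index)
  keep <- if (report_all) rep(TRUE, index$m) else counts > 0L
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_records())
  inter <- counts[idx]
  size_q <- length(sk$hashes)
  size_r <- index$ref_sizes[idx]
  J <- jaccard(inter, size_q, size_r)
  Dm <- mash_distance(J, k)
  sel <- Dm <= max_dist
  if (!any(sel)) return(empty_records())
  idx <- idx[sel]; inter <- inter[sel]; size_r <- size_r[sel]
  J <- J[sel]; Dm <- Dm[sel]
  C <- suppressWarnings(containment(inter, size_q, size_r))
  data.frame(query = sk$name, reference = index$ref_names[idx],
             shared = inter, size_q = size_q, size_r = size_r,
             jaccard = J, containment = C, mash_dist = Dm,
             aaf_dist = aaf_distance(C, k), stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(query = character(), reference = character(),
             shared = integer(), size_q = integer(), size_r = integer(),
             jaccard = numeric(), containment = numeric(),
             mash_dist = numeric(), aaf_dist = numeric(),
             stringsAsFactors = FALSE)
}

#' All-vs-all sketch distances with sharded, indexed output
#'
#' Computes distances between every query and every reference through the
#' unified inverted-index dictionary. The intersection matrix is split into
#' individual query rows: each of the `P` workers holds one live counter
#' row, so peak counter storage is `P * m`, never `m * n`. A pair is
#' emitted when its intersection is positive (unless `report_all`) and its
#' Mash distance is at most `max_dist` (default 1, i.e. everything; 0.05 is
#' the conventional screening threshold). Rows for one query are contiguous
#' in one shard file `dist.<shard>.tsv` (shard = query index modulo
#' `shards`), and a global index `dist.index.tsv` maps every query to its
#' shard, byte offset, and record count. The emitted record set is
#' identical for any `threads` and `shards`.
#'
#' @param refs,queries `kssd_sketch_set`s sharing parameters and shuffle id.
#' @param out_dir Output directory (created if missing).
#' @param max_dist Mash-distance output threshold in `[0, 1]`.
#' @param threads Worker count `P`.
#' @param shards Number of output sub-files; default `threads`.
#' @param report_all Also emit pairs with an empty intersection.
#' @return Invisibly, a `kssd_dist_run`: `out_dir`, the index data.frame,
#'   `n`, `m`, and `stats` (per-worker peak counter rows and the aggregate
#'   `peak_counters = sum(worker peaks) * m`).
#' @export
all_vs_all <- function(refs, queries, out_dir, max_dist = 1.0, threads = 1L,
                       shards = threads, report_all = FALSE) {
  stopifnot(inherits(refs, "kssd_sketch_set"),
            inherits(queries, "kssd_sketch_set"))
  if (!params_compatible(refs$params, queries$params))
    stop("reference and query sketch sets have different parameters or ",
         "shuffle id", call. = FALSE)
  if (!is.numeric(max_dist) || max_dist < 0 || max_dist > 1)
    stop("`max_dist` must be in [0, 1]", call. = FALSE)
  threads <- max(1L, as.integer(threads))
  shards <- max(1L, as.integer(shards))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)

  index <- build_index(refs)
  n <- length(queries$sketches)
  k <- refs$params$k

  # One chunk per worker; each worker processes its queries sequentially so
  # it never holds more than one counter row.
  chunk_of <- (seq_len(n) - 1L) %% threads + 1L
  worker <- function(w) {
    counter_reset()
    recs <- lapply(which(chunk_of == w), query_records,
                   queries = queries, index = index, max_dist = max_dist,
                   report_all = report_all, k = k)
    list(records = recs, peak_rows = counter_stats()$peak)
  }
  parts <- run_workers(seq_len(threads), worker, threads)

  per_query <- vector("list", n)
  for (w in seq_len(threads))
    per_query[which(chunk_of == w)] <- parts[[w]]$records
  peak_rows <- vapply(parts, `[[`, numeric(1L), "peak_rows")

  idx_df <- write_shards(per_query, sketch_names(queries), shards, out_dir)
  res <- structure(
    list(out_dir = out_dir, index = idx_df, n = n, m = index$m,
         max_dist = max_dist,
         stats = list(workers = threads, m = index$m,
                      worker_peak_rows = peak_rows,
                      peak_counter_rows = sum(peak_rows),
                      peak_counters = sum(peak_rows) * index$m)),
    class = "kssd_dist_run")
  invisible(res)
}

#' @export
print.kssd_dist_run <- function(x, ...) {
  cat(sprintf(
    "distance run: %d queries x %d references -> %s (%d records, Dm <= %g)\n",
    x$n, x$m, x$out_dir, sum(x$index$n_records), x$max_dist))
  invisible(x)
}

DIST_HEADER <- paste("query", "reference", "shared", "|Sq|", "|Sr|",
                     "jaccard", "containment", "mash_dist", "aaf_dist",
                     sep = "\t")

format_records <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sprintf("%s\t%s\t%d\t%d\t%d\t%.6f\t%.6f\t%.6f\t%.6f",
          df$query, df$reference, df$shared, df$size_q, df$size_r,
          df$jaccard, df$containment, df$mash_dist, df$aaf_dist)
}

# Writes dist.<shard>.tsv files plus the global index dist.index.tsv.
# Buffers each shard in memory and flushes it in one unit.
write_shards <- function(per_query, query_names, shards, out_dir) {
  n <- length(per_query)
  shard_of <- (seq_len(n) - 1L) %% shards + 1L
  idx <- data.frame(query = query_names, shard = shard_of - 1L,
                    offset = NA_real_, n_records = NA_integer_,
                    stringsAsFactors = FALSE)
  for (sh in seq_len(shards)) {
    buffer <- DIST_HEADER
    offset <- nchar(DIST_HEADER, type = "bytes") + 1L
    for (qi in which(shard_of == sh)) {
      lines <- format_records(per_query[[qi]])
      idx$offset[qi] <- offset
      idx$n_records[qi] <- length(lines)
      buffer <- c(buffer, lines)
      offset <- offset + sum(nchar(lines, type = "bytes") + 1L)
    }
    writeLines(buffer, file.path(out_dir, sprintf("dist.%d.tsv", sh - 1L)))
  }
  utils::write.table(idx, file.path(out_dir, "dist.index.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  idx
}

#' Read distance records back from a sharded run
#'
#' `read_distances()` concatenates all shards into one data.frame (ordered
#' by query input order via the global index); `lookup_query()` uses the
#' index to seek straight to one query's contiguous rows.
#'
#' @param out_dir Directory written by [all_vs_all()].
#' @param query Query name to look up.
#' @return A data.frame of distance records.
#' @export
read_distances <- function(out_dir) {
  idx <- utils::read.table(file.path(out_dir, "dist.index.tsv"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(idx)),
                 function(i) read_at(out_dir, idx[i, ]))
  do.call(rbind, c(recs, list(empty_records())))
}

#' @rdname read_distances
#' @export
lookup_query <- function(out_dir, query) {
  idx <- utils::read.table(file.path(out_dir, "dist.index.tsv"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  row <- idx[idx$query == query, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("query not present in index: ", query, call. = FALSE)
  read_at(out_dir, row[1L, ])
}

read_at <- function(out_dir, row) {
  if (row$n_records == 0L) return(empty_records())
  path <- file.path(out_dir, sprintf("dist.%d.tsv", row$shard))
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, row$offset)
  lines <- readLines(con, n = row$n_records)
  df <- utils::read.table(text = lines, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("query", "reference", "shared",
                                        "size_q", "size_r", "jaccard",
                                        "containment", "mash_dist",
                                        "aaf_dist"))
  df
}
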