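# Exact set algebra on sketches. The one-to-one hash makes these operations
# exact: a hash is present iff its k-mer is, so union/intersection/difference
# on hash sets equal the same operations on the underlying k-mer sets.

check_setop_compat <- function(a_params, b_params) {
  if (!params_compatible(a_params, b_params))
    stop("sketches were built with different parameters or shuffle tables; ",
         "set operations across hash spaces are not meaningful", call. = FALSE)
  invisible(NULL)
}

#' Union of a sketch set into a pan-sketch
#'
#' Collapses all member sketches into one sketch holding the exact union of
#' their hash sets, e.g. the pan k-mer sketch of a reference collection
#' used for variant enrichment by [subtract_sketches()].
#'
#' @param set A `kssd_sketch_set`.
#' @param name Label of the resulting pan-sketch.
#' @return A `kssd_pan` (also a `kssd_sketch`): the union sketch, with
#'   `provenance` listing the source genome names and aggregate scan
#'   counters (sums over members, which bound the union from above).
#' @export
union_sketches <- function(set, name = "pan") {
  stopifnot(inherits(set, "kssd_sketch_set"))
  hashes <- sort(unique(unlist(lapply(set$sketches, `[[`, "hashes"),
                               use.names = FALSE)))
  totals <- sum(vapply(set$sketches, `[[`, numeric(1L), "total_kmers"))
  distinct <- sum(vapply(set$sketches, `[[`, numeric(1L), "distinct_kmers"))
  pan <- genome_sketch(name, hashes, max(totals, length(hashes)),
                       max(distinct, length(hashes)), set$params)
  pan$provenance <- sketch_names(set)
  pan$params <- set$params
  class(pan) <- c("kssd_pan", class(pan))
  pan
}

#' @export
print.kssd_pan <- function(x, ...) {
  cat(sprintf("pan-sketch '%s': %d hashes from %d genomes\n",
              x$name, length(x$hashes), length(x$provenance)))
  invisible(x)
}

# Shared machinery for subtract/intersect: apply `op` to each genome's
# hash set against the pan-sketch. A staging step lists per-genome work
# items; processing units apply the operation; output order equals input
# order for any worker count.
setop_apply <- function(queries, ref, op, threads, op_name) {
  stopifnot(inherits(queries, "kssd_sketch_set"), inherits(ref, "kssd_pan"))
  check_setop_compat(queries$params, ref$params)
  items <- seq_along(queries$sketches)
  work <- function(i) {
    sk <- queries$sketches[[i]]
    h <- op(sk$hashes, ref$hashes)
    genome_sketch(sk$name, h, sk$total_kmers, sk$distinct_kmers,
                  queries$params)
  }
  out <- run_workers(items, work, threads)
  empty <- vapply(out, function(s) length(s$hashes) == 0L, logical(1L))
  if (any(empty))
    warning(op_name, " left ", sum(empty),
            " empty sketch(es); kept to preserve genome order",
            call. = FALSE)
  sketch_set(queries$params, out)
}

# setdiff/intersect on sorted inputs; results stay sorted because the
# first argument is scanned in order.
sorted_setdiff <- function(a, b) a[is.na(match(a, b))]
sorted_intersect <- function(a, b) a[!is.na(match(a, b))]

#' Subtract a pan-sketch from every query sketch
#'
#' Removes reference-associated k-mers from each query: the exact set
#' difference `S(q) \ ref`, the enrichment step that isolates
#' sample-specific variant k-mers. Names and order are preserved; sketches
#' that become empty are kept (with a warning) so downstream distance runs
#' see a stable genome list. Scan counters are retained as provenance of
#' the original scan.
#'
#' @param queries A `kssd_sketch_set`.
#' @param ref A `kssd_pan` from [union_sketches()] (same parameters and
#'   shuffle id).
#' @param threads Number of processing workers; results are identical for
#'   any value.
#' @return A `kssd_sketch_set` in the input order.
#' @export
subtract_sketches <- function(queries, ref, threads = 1L) {
  setop_apply(queries, ref, sorted_setdiff, threads, "subtraction")
}

#' Intersect every query sketch with a pan-sketch
#'
#' The complement of [subtract_sketches()]: keeps exactly the
#' reference-associated hashes, `S(q) ∩ ref`.
#'
#' @inheritParams subtract_sketches
#' @return A `kssd_sketch_set` in the input order.
#' @export
intersect_sketches <- function(queries, ref, threads = 1L) {
  setop_apply(queries, ref, sorted_intersect, threads, "intersection")
}

#' Summarize a sketch set
#'
#' @param set A `kssd_sketch_set`.
#' @return A data.frame with one row per genome: name, sketch size, and
#'   scan counters.
#' @export
sketch_info <- function(set) {
  stopifnot(inherits(set, "kssd_sketch_set"))
  data.frame(
    name = sketch_names(set),
    sketch_size = sketch_sizes(set),
    total_kmers = vapply(set$sketches, `[[`, numeric(1L), "total_kmers"),
    distinct_kmers = vapply(set$sketches, `[[`, numeric(1L), "distinct_kmers"),
    stringsAsFactors = FALSE
  )
}
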