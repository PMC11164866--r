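# Descriptor matching: L2 distances, Lowe's ratio test, symmetry
# cross-checking, and per-database-entry match counts.
#
# Nearest-neighbour search is exact (no approximate indexing): databases
# here hold hundreds of entries, and exact search keeps the ratio test's
# semantics unambiguous. The compiled kernel returns the two smallest
# distances per feature in both directions in a single pass. Descriptors
# are integer vectors with squared distances below 2^24, so the
# single-precision accumulation in the kernel is exact.

#' Euclidean (L2-norm) distance between two descriptors
#'
#' @param d1,d2 numeric or integer vectors of length 128.
#' @return the L2 norm of the component-wise difference.
#' @export
descriptor_distance <- function(d1, d2) {
  if (length(d1) != 128L || length(d2) != 128L) {
    stop("descriptors must have length 128", call. = FALSE)
  }
  sqrt(sum((as.numeric(d1) - as.numeric(d2))^2))
}

# Lowe ratio acceptance from the two smallest distances. Ties (d1 == d2)
# and duplicate best descriptors (d2 == 0) are defined as ratio 1, so they
# survive only at k = 1; a missing second neighbour never passes.
ratio_ok <- function(d1, d2, k) {
  r <- ifelse(!is.finite(d2), Inf, ifelse(d2 == 0 | d1 == d2, 1, d1 / d2))
  r <= k
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k > 1) {
    stop("k must be in (0, 1]", call. = FALSE)
  }
}

empty_matches <- function() {
  data.frame(query_index = integer(0), db_index = integer(0),
             distance = numeric(0))
}

#' Lowe's ratio-test matching between two feature sets
#'
#' For every feature in \code{fa}, finds its two nearest neighbours among
#' the descriptors of \code{fb} (exact search; ties between database
#' features keep the lowest index) and retains the best candidate if and
#' only if the distance ratio \code{d1/d2 <= k}. At most one match is
#' produced per query feature. If \code{fb} has fewer than two features
#' the ratio test is undefined and an empty match list is returned.
#'
#' @param fa,fb \code{feature_set} objects (query and database sides).
#' @param k distance-ratio threshold in (0, 1].
#' @return a data frame of match pairs with columns \code{query_index},
#'   \code{db_index} (1-based feature indices) and \code{distance}.
#' @export
ratio_match <- function(fa, fb, k = 0.7) {
  stopifnot(inherits(fa, "feature_set"), inherits(fb, "feature_set"))
  check_k(k)
  if (n_features(fa) == 0L || n_features(fb) < 2L) return(empty_matches())
  nn <- .two_nn_both_cpp(fa$descriptors, fb$descriptors)
  keep <- which(ratio_ok(nn$f_d1, nn$f_d2, k))
  data.frame(query_index = keep, db_index = nn$f_j1[keep] + 1L,
             distance = nn$f_d1[keep])
}

#' Symmetry (cross-check) filtering of match pairs
#'
#' Retains exactly the forward pairs \code{(i, j)} for which the reverse
#' matching also paired \code{(j, i)}. Implemented as set membership over
#' the reversed pairs; the result is identical to the quadratic
#' pairwise-comparison formulation.
#'
#' @param forward match pairs from A to B (as from [ratio_match()]).
#' @param reverse match pairs from B to A, computed with the same \code{k}.
#' @return the surviving subset of \code{forward}.
#' @export
symmetry_filter <- function(forward, reverse) {
  if (nrow(forward) == 0L || nrow(reverse) == 0L) {
    return(forward[integer(0), , drop = FALSE])
  }
  fwd_key <- paste(forward$query_index, forward$db_index)
  rev_key <- paste(reverse$db_index, reverse$query_index)
  forward[fwd_key %in% rev_key, , drop = FALSE]
}

# Surviving match count between one query and one database entry, using
# the single-pass bidirectional kernel. Equivalent to
# ratio_match + (optionally) symmetry_filter, but does not materialise the
# pair lists.
count_pair <- function(qdesc, edesc, k, symmetry) {
  if (nrow(qdesc) == 0L || nrow(edesc) < 2L) return(0L)
  nn <- .two_nn_both_cpp(qdesc, edesc)
  fkeep <- ratio_ok(nn$f_d1, nn$f_d2, k)
  if (!symmetry) return(sum(fkeep))
  rkeep <- ratio_ok(nn$r_d1, nn$r_d2, k)
  i <- which(fkeep)
  if (length(i) == 0L) return(0L)
  j <- nn$f_j1[i] + 1L
  sum(rkeep[j] & nn$r_j1[j] + 1L == i)
}

#' Count surviving matches against every database entry
#'
#' Runs forward ratio matching of the query against each database feature
#' set; with symmetry checking enabled, also runs the reverse matching and
#' keeps only symmetric pairs. The per-entry counts are the \code{N_i}
#' statistics from which the best count \code{N1}, runner-up \code{N2} and
#' prominence are derived by [decide()].
#'
#' @param query a \code{feature_set}.
#' @param db a named list of \code{feature_set}s (or an \code{epuf_db}).
#' @param k distance-ratio threshold.
#' @param symmetry logical; enable symmetry cross-checking.
#' @return an object of class \code{match_counts}: list with \code{counts}
#'   (named integer vector, one per database entry) and
#'   \code{query_feature_total}.
#' @export
count_matches <- function(query, db, k = 0.7, symmetry = TRUE) {
  check_k(k)
  if (inherits(db, "epuf_db")) db <- db$features
  if (length(db) == 0L) stop("database is empty", call. = FALSE)
  if (is.null(names(db)) || anyDuplicated(names(db))) {
    stop("database entries must have unique names", call. = FALSE)
  }
  nq <- n_features(query)
  if (nq == 0L) {
    warning("query has no features; all match counts are zero")
    counts <- setNames(integer(length(db)), names(db))
    return(structure(list(counts = counts, query_feature_total = 0L),
                     class = "match_counts"))
  }
  counts <- vapply(db, function(entry) {
    as.integer(count_pair(query$descriptors, entry$descriptors, k, symmetry))
  }, integer(1))
  structure(list(counts = counts, query_feature_total = nq),
            class = "match_counts")
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("Match counts over %d database entries (query features: %d)\n",
              length(x$counts), x$query_feature_total))
  top <- sort(x$counts, decreasing = TRUE)
  show <- utils::head(top, 5L)
  cat("  top entries:",
      paste(sprintf("%s=%d", names(show), show), collapse = ", "), "\n")
  invisible(x)
}
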