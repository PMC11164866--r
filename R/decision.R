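# The matching-threshold / prominence decision rule and its outcomes.

#' Matching configuration (operating point)
#'
#' The four tunables of the matching algorithm. The defaults --
#' \code{k = 0.7}, \code{p = 0.5}, \code{lam = 0.02}, symmetry checking on
#' -- are the recommended operating point: the distance ratio and symmetry
#' check control per-feature match specificity, the matching threshold
#' \code{lam} discards verdicts supported by too few matches (fewer than
#' \code{lam * len(F)} of the query's features), and the prominence
#' threshold \code{p} requires the best database entry to stand out from
#' the runner-up.
#'
#' @param k Lowe distance-ratio threshold, in (0, 1].
#' @param p prominence threshold, in [0, 1].
#' @param lam matching threshold (fraction of query features), in [0, 1].
#' @param symmetry logical; enable symmetry cross-checking.
#' @return an object of class \code{match_config}.
#' @export
match_config <- function(k = 0.7, p = 0.5, lam = 0.02, symmetry = TRUE) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k > 1) {
    stop("k must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
    stop("p must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1) {
    stop("lam must be in [0, 1]", call. = FALSE)
  }
  structure(list(k = k, p = p, lam = lam, symmetry = isTRUE(symmetry)),
            class = "match_config")
}

#' @export
print.match_config <- function(x, ...) {
  cat(sprintf("Match config: k = %g, p = %g, lambda = %g, symmetry %s\n",
              x$k, x$p, x$lam, if (x$symmetry) "on" else "off"))
  invisible(x)
}

#' Match prominence
#'
#' The relative gap between the best and second-best per-entry match
#' counts, \code{(N1 - N2) / N1}. A prominence of 1 is the ideal case
#' where only one database entry has any matches; 0 means the two best
#' entries are tied (or there are no matches at all).
#'
#' @param n1 best per-entry match count.
#' @param n2 second-best per-entry match count; must not exceed \code{n1}.
#' @return the prominence ratio in [0, 1]; 0 when \code{n1} is 0.
#' @export
prominence <- function(n1, n2) {
  if (n2 > n1 || n2 < 0) stop("require N1 >= N2 >= 0", call. = FALSE)
  if (n1 == 0) return(0)
  (n1 - n2) / n1
}

#' Decide a verdict from per-entry match counts
#'
#' Applies the two confidence criteria to the match counts: the matching
#' threshold \code{N1 >= lam * len(F)} (with the exact real-valued product,
#' no rounding) and the prominence threshold
#' \code{(N1 - N2)/N1 >= p}. The verdict is \emph{confident} only if both
#' hold, in which case the best-matching entry id is reported; otherwise
#' the verdict is \emph{unconfident} and no entry is named. A tie for the
#' best count gives prominence 0, hence an unconfident verdict at any
#' \code{p > 0}.
#'
#' @param counts a [count_matches()] result.
#' @param config a [match_config()].
#' @return an object of class \code{match_verdict}: list with
#'   \code{outcome} ("confident"/"unconfident"), \code{best_id} (entry id
#'   or \code{NA}), \code{N1}, \code{N2}, \code{prominence},
#'   \code{query_feature_total}, \code{truth_status} ("not_evaluated"
#'   until [evaluate_truth()] is applied) and the configuration used.
#' @export
decide <- function(counts, config = match_config()) {
  stopifnot(inherits(counts, "match_counts"),
            inherits(config, "match_config"))
  cc <- counts$counts
  if (length(cc) == 0L) stop("empty match counts", call. = FALSE)
  i1 <- which.max(cc)
  n1 <- cc[[i1]]
  n2 <- if (length(cc) > 1L) max(cc[-i1]) else 0L
  prom <- prominence(n1, n2)
  confident <- (n1 >= config$lam * counts$query_feature_total) &&
    (prom >= config$p) && n1 > 0
  structure(
    list(outcome = if (confident) "confident" else "unconfident",
         best_id = if (confident) names(cc)[i1] else NA_character_,
         N1 = n1, N2 = n2, prominence = prom,
         query_feature_total = counts$query_feature_total,
         truth_status = "not_evaluated", config = config),
    class = "match_verdict"
  )
}

#' Categorise a confident verdict against ground truth
#'
#' Confident verdicts become \code{correct} when the best-matching entry is
#' the true one and \code{incorrect} otherwise. Unconfident verdicts are
#' not tested for correctness: their truth status stays
#' \code{not_evaluated}.
#'
#' @param verdict a [decide()] result.
#' @param true_id the ground-truth database entry id for the query.
#' @return the verdict with \code{truth_status} filled in.
#' @export
evaluate_truth <- function(verdict, true_id) {
  stopifnot(inherits(verdict, "match_verdict"))
  if (verdict$outcome == "confident") {
    verdict$truth_status <- if (identical(verdict$best_id, true_id)) {
      "correct"
    } else {
      "incorrect"
    }
  }
  verdict
}

#' @export
print.match_verdict <- function(x, ...) {
  cat(sprintf(
    "Verdict: %s%s  (N1 = %d, N2 = %d, prominence = %.3f, features = %d)\n",
    x$outcome,
    if (!is.na(x$best_id)) paste0(" -> ", x$best_id) else "",
    x$N1, x$N2, x$prominence, x$query_feature_total))
  if (x$truth_status != "not_evaluated") {
    cat(sprintf("  ground truth: %s\n", x$truth_status))
  }
  invisible(x)
}

# Flatten a verdict (plus optional query id) to a one-row data frame.
verdict_row <- function(verdict, query_id = NA_character_) {
  data.frame(query_id = query_id, outcome = verdict$outcome,
             best_id = verdict$best_id, N1 = verdict$N1, N2 = verdict$N2,
             prominence = verdict$prominence,
             truth_status = verdict$truth_status,
             stringsAsFactors = FALSE)
}
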