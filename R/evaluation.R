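# Evaluation procedures: precision/recall scoring, distance-ratio sweeps,
# leave-true-entry-out cross-validation, specificity traces, and
# eta = precision x recall accuracy grids.

#' Score authentication outcomes into precision, recall and eta
#'
#' Bookkeeping: a true positive is a confident-correct verdict; a false
#' positive is any confident verdict that is wrong -- either incorrect for
#' a registered query or any confident (hence invalid) match for an
#' unregistered query; a false negative is a non-confident verdict for a
#' registered query. Unconfident verdicts of unregistered queries are the
#' desired outcome and enter no cell. Divisions with a zero denominator
#' are defined as 0 and flagged.
#'
#' @param verdicts a data frame of verdict rows (as produced by the sweep /
#'   cross-validation helpers) with columns \code{outcome} and
#'   \code{truth_status}; every row must carry ground truth.
#' @param registered logical vector: is the query's true pattern present in
#'   the database?
#' @return an object of class \code{eval_summary} with components
#'   \code{TP}, \code{FP}, \code{FN}, \code{precision}, \code{recall},
#'   \code{eta} and \code{zero_division}.
#' @export
score_outcomes <- function(verdicts, registered) {
  stopifnot(is.data.frame(verdicts), nrow(verdicts) == length(registered))
  confident <- verdicts$outcome == "confident"
  if (any(confident & registered &
          !(verdicts$truth_status %in% c("correct", "incorrect")))) {
    stop("confident verdicts of registered queries must carry ground truth",
         call. = FALSE)
  }
  tp <- sum(confident & registered & verdicts$truth_status == "correct")
  fp <- sum(confident & ((registered &
                          verdicts$truth_status == "incorrect") |
                         !registered))
  fn <- sum(!confident & registered)
  zero_division <- (tp + fp) == 0 || (tp + fn) == 0
  precision <- if ((tp + fp) == 0) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0) 0 else tp / (tp + fn)
  structure(
    list(TP = tp, FP = fp, FN = fn, precision = precision, recall = recall,
         eta = precision * recall, zero_division = zero_division),
    class = "eval_summary"
  )
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf(
    "TP = %d, FP = %d, FN = %d; precision = %.3f, recall = %.3f, eta = %.3f%s\n",
    x$TP, x$FP, x$FN, x$precision, x$recall, x$eta,
    if (x$zero_division) " (zero-denominator case)" else ""))
  invisible(x)
}

# Normalise a query collection to a named list of feature_sets.
as_feature_sets <- function(queries, sift = sift_params()) {
  if (inherits(queries, "feature_set")) queries <- list(queries)
  if (is.character(queries)) {
    nms <- names(queries) %||% tools::file_path_sans_ext(basename(queries))
    queries <- lapply(queries, function(p) {
      extract_features(process_image(p), params = sift)
    })
    names(queries) <- nms
  }
  if (is.null(names(queries))) {
    names(queries) <- vapply(queries, function(q) q$source_id,
                             character(1))
  }
  queries
}

# Per-query match counts for one (k, symmetry) setting, as a list of
# match_counts objects; this is the unit that is cached and shared across
# prominence thresholds, since p acts only at decision time.
counts_for_setting <- function(query_feats, db, k, symmetry) {
  lapply(query_feats, count_matches, db = db, k = k, symmetry = symmetry)
}

decide_all <- function(counts_list, config, true_ids) {
  rows <- lapply(names(counts_list), function(qid) {
    v <- decide(counts_list[[qid]], config)
    v <- evaluate_truth(v, true_ids[[qid]])
    verdict_row(v, qid)
  })
  do.call(rbind, rows)
}

#' Sweep the distance ratio k over a query set
#'
#' Authenticates every query at each value of \code{k}, with and without
#' symmetry checking, and reports the fraction of correct, incorrect and
#' unconfident verdicts per setting.
#'
#' @param queries named list of \code{feature_set}s (or character vector of
#'   image paths).
#' @param db an \code{epuf_db} or named list of \code{feature_set}s.
#' @param k_values distance ratios to evaluate.
#' @param config base [match_config()] supplying \code{p} and \code{lam}.
#' @param true_ids named character vector mapping query names to their
#'   ground-truth entry ids.
#' @return a data frame with columns \code{k}, \code{symmetry},
#'   \code{frac_correct}, \code{frac_incorrect}, \code{frac_unconfident}.
#' @export
sweep_k <- function(queries, db, k_values = c(0.7, 0.9, 1.0),
                    config = match_config(), true_ids) {
  queries <- as_feature_sets(queries)
  if (length(queries) < 1L) stop("no queries", call. = FALSE)
  res <- list()
  for (sym in c(FALSE, TRUE)) {
    for (k in k_values) {
      counts <- counts_for_setting(queries, db, k, sym)
      cfg <- match_config(k = k, p = config$p, lam = config$lam,
                          symmetry = sym)
      rows <- decide_all(counts, cfg, true_ids)
      n <- nrow(rows)
      res[[length(res) + 1L]] <- data.frame(
        k = k, symmetry = sym,
        frac_correct = sum(rows$truth_status == "correct") / n,
        frac_incorrect = sum(rows$truth_status == "incorrect") / n,
        frac_unconfident = sum(rows$outcome != "confident") / n)
    }
  }
  do.call(rbind, res)
}

#' Leave-true-entry-out cross-validation
#'
#' Evaluates every query against the database with its own true entry
#' removed, so each query is by construction unregistered: any confident
#' match is invalid. This probes the false-accept behaviour of the
#' decision rule, in particular the protective role of the prominence
#' threshold.
#'
#' @param queries named list of \code{feature_set}s or image paths.
#' @param db database whose entries include every query's true entry.
#' @param config a [match_config()].
#' @param true_ids named character vector of ground-truth entry ids.
#' @return a list with \code{summary} (an \code{eval_summary}; all queries
#'   unregistered) and \code{verdicts} (per-query rows).
#' @export
cross_validate <- function(queries, db, config = match_config(), true_ids) {
  queries <- as_feature_sets(queries)
  feats <- if (inherits(db, "epuf_db")) db$features else db
  missing <- setdiff(unname(true_ids[names(queries)]), names(feats))
  if (length(missing) > 0L) {
    stop("true entries absent from database: ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(names(queries), function(qid) {
    true_id <- true_ids[[qid]]
    eff <- feats[setdiff(names(feats), true_id)]
    if (length(eff) == 0L) {
      v <- structure(
        list(outcome = "unconfident", best_id = NA_character_, N1 = 0L,
             N2 = 0L, prominence = 0,
             query_feature_total = n_features(queries[[qid]]),
             truth_status = "not_evaluated", config = config),
        class = "match_verdict")
      return(verdict_row(v, qid))
    }
    counts <- count_matches(queries[[qid]], eff, k = config$k,
                            symmetry = config$symmetry)
    verdict_row(decide(counts, config), qid)
  })
  verdicts <- do.call(rbind, rows)
  list(summary = score_outcomes(verdicts,
                                registered = rep(FALSE, nrow(verdicts))),
       verdicts = verdicts)
}

#' Per-entry match-count trace for one query
#'
#' Returns the number of surviving feature matches between one query and
#' every database entry, for each matching configuration -- the
#' "specificity trace" whose shape shows how the distance ratio and
#' symmetry checking isolate the true match: unconstrained matching gives
#' a flat trace at the query's feature total, constrained matching a
#' single peak over near-zero background.
#'
#' @param query a \code{feature_set} (or image path).
#' @param db database.
#' @param configs list of [match_config()]s.
#' @return a matrix with one row per database entry and one column per
#'   configuration (named \code{k=..,sym=..}).
#' @export
specificity_trace <- function(query, db,
                              configs = list(
                                match_config(k = 1, symmetry = FALSE),
                                match_config(k = 1, symmetry = TRUE),
                                match_config(k = 0.9, symmetry = FALSE),
                                match_config(k = 0.7, symmetry = TRUE))) {
  query <- as_feature_sets(query)[[1L]]
  feats <- if (inherits(db, "epuf_db")) db$features else db
  out <- vapply(configs, function(cfg) {
    count_matches(query, feats, k = cfg$k, symmetry = cfg$symmetry)$counts
  }, numeric(length(feats)))
  colnames(out) <- vapply(configs, function(cfg) {
    sprintf("k=%g,sym=%s", cfg$k, if (cfg$symmetry) "on" else "off")
  }, character(1))
  rownames(out) <- names(feats)
  out
}

#' eta accuracy grid over distance ratio and prominence threshold
#'
#' Computes \code{eta = precision * recall} for every \code{(k, p)} cell.
#' Feature matching is recomputed per \code{k} (and cached); decisions per
#' \code{p} reuse the cached counts, since the prominence threshold acts
#' only at decision time.
#'
#' @param queries named list of \code{feature_set}s or image paths.
#' @param db database.
#' @param k_grid,p_grid grid values; must be non-empty.
#' @param symmetry logical; symmetry checking for the whole grid.
#' @param config base config supplying \code{lam}.
#' @param true_ids named ground-truth ids.
#' @param registered logical vector per query (default all registered).
#' @return a numeric matrix with rows indexed by \code{k_grid} and columns
#'   by \code{p_grid} (row/column names carry the values).
#' @export
grid_eta <- function(queries, db, k_grid = seq(0.05, 1, by = 0.05),
                     p_grid = seq(0, 1, by = 0.05), symmetry = TRUE,
                     config = match_config(), true_ids,
                     registered = NULL) {
  if (length(k_grid) == 0L || length(p_grid) == 0L) {
    stop("empty grid", call. = FALSE)
  }
  queries <- as_feature_sets(queries)
  if (is.null(registered)) registered <- rep(TRUE, length(queries))
  out <- matrix(NA_real_, length(k_grid), length(p_grid),
                dimnames = list(k = as.character(k_grid),
                                p = as.character(p_grid)))
  for (i in seq_along(k_grid)) {
    counts <- counts_for_setting(queries, db, k_grid[i], symmetry)
    for (j in seq_along(p_grid)) {
      cfg <- match_config(k = k_grid[i], p = p_grid[j], lam = config$lam,
                          symmetry = symmetry)
      rows <- decide_all(counts, cfg, true_ids)
      out[i, j] <- score_outcomes(rows, registered)$eta
    }
  }
  out
}
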