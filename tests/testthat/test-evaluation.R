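vrows <- function(outcomes, truths) {
  data.frame(query_id = seq_along(outcomes), outcome = outcomes,
             best_id = NA, N1 = 0L, N2 = 0L, prominence = 0,
             truth_status = truths, stringsAsFactors = FALSE)
}

test_that("score_outcomes implements the precision/recall bookkeeping", {
  s <- score_outcomes(vrows(c("confident", "confident"),
                            c("correct", "correct")), c(TRUE, TRUE))
  expect_identical(c(s$TP, s$FP, s$FN), c(2L, 0L, 0L))
  expect_identical(s$eta, 1)
  s <- score_outcomes(vrows(c("confident", "confident"),
                            c("correct", "incorrect")), c(TRUE, TRUE))
  expect_identical(s$precision, 0.5)
  expect_identical(s$recall, 1)
  expect_identical(s$eta, 0.5)
  # all unconfident: eta 0 with flagged zero-division
  s <- score_outcomes(vrows(rep("unconfident", 3),
                            rep("not_evaluated", 3)), rep(TRUE, 3))
  expect_identical(s$eta, 0)
  expect_true(s$zero_division)
  # a confident match of an unregistered query is a false positive
  s <- score_outcomes(vrows(c("confident", "unconfident"),
                            c("not_evaluated", "not_evaluated")),
                      c(FALSE, FALSE))
  expect_identical(s$FP, 1L)
  expect_identical(s$FN, 0L)
  # eta identities
  withr::with_seed(41, {
    for (i in 1:10) {
      n <- 8
      oc <- sample(c("confident", "unconfident"), n, replace = TRUE)
      reg <- sample(c(TRUE, FALSE), n, replace = TRUE)
      tr <- ifelse(oc == "confident" & reg,
                   sample(c("correct", "incorrect"), n, replace = TRUE),
                   "not_evaluated")
      s <- score_outcomes(vrows(oc, tr), reg)
      expect_lte(s$eta, min(s$precision, s$recall) + 1e-12)
      expect_identical(s$eta == 1, s$FP == 0 && s$FN == 0 && s$TP > 0)
    }
  })
})

test_that("missing ground truth for confident registered verdicts errors", {
  expect_error(
    score_outcomes(vrows("confident", "not_evaluated"), TRUE),
    "ground truth")
})

test_that("sweep_k reports outcome fractions per k and symmetry setting", {
  db <- tiny_db()
  qf <- tiny_query_features()
  true_ids <- setNames(names(qf), names(qf))
  res <- sweep_k(qf, db, k_values = c(0.7, 1.0), true_ids = true_ids)
  expect_identical(nrow(res), 4L)
  sums <- res$frac_correct + res$frac_incorrect + res$frac_unconfident
  expect_true(all(abs(sums - 1) < 1e-12))
  # k = 1.0: flat counts, zero prominence, nothing confident (no symmetry)
  expect_identical(res$frac_unconfident[res$k == 1 & !res$symmetry], 1)
  # k = 0.7 with symmetry: the mildly perturbed queries all match
  expect_identical(res$frac_correct[res$k == 0.7 & res$symmetry], 1)
  # single query, single k: fractions are 0 or 1
  res1 <- sweep_k(qf[1], db, k_values = 0.7, true_ids = true_ids)
  expect_true(all(unlist(res1[, 3:5]) %in% c(0, 1)))
})

test_that("cross-validation removes the true entry and flags invalid matches", {
  db <- tiny_db()
  qf <- tiny_query_features()
  true_ids <- setNames(names(qf), names(qf))
  cv <- cross_validate(qf, db, match_config(), true_ids)
  expect_identical(cv$summary$TP, 0L)
  expect_identical(nrow(cv$verdicts), length(qf))
  # every confident match is by construction invalid and counted as FP
  # (a 3-entry leave-out database is too small for the prominence
  # criterion to reject reliably; the 50-entry behaviour is covered by
  # the acceptance suite)
  expect_identical(cv$summary$FP,
                   sum(cv$verdicts$outcome == "confident"))
  # a database of one entry leaves an empty effective database
  db1 <- list(p001 = db$features[[1]])
  cv1 <- cross_validate(qf[1], db1, match_config(),
                        setNames("p001", names(qf)[1]))
  expect_identical(cv1$verdicts$outcome, "unconfident")
  # unknown true id errors
  expect_error(cross_validate(qf[1], db, match_config(),
                              setNames("nope", names(qf)[1])),
               "absent")
})

test_that("specificity traces are flat under unconstrained matching and peaked when constrained", {
  db <- tiny_db()
  qf <- tiny_query_features()
  tr <- specificity_trace(qf[[1]], db)
  expect_identical(dim(tr), c(4L, 4L))
  flat <- tr[, "k=1,sym=off"]
  expect_true(all(flat == n_features(qf[[1]])))
  constrained <- tr[, "k=0.7,sym=on"]
  peak <- which.max(constrained)
  expect_identical(names(peak), names(qf)[1])
  expect_lte(max(constrained[-peak]), 0.1 * constrained[peak])
  # a feature-less query traces all zeros
  empty <- fake_feature_set(matrix(integer(0), 0, 128))
  tr0 <- suppressWarnings(specificity_trace(empty, db))
  expect_true(all(tr0 == 0))
})

test_that("grid_eta reuses counts across p and is monotone non-increasing in p", {
  db <- tiny_db()
  qf <- tiny_query_features()
  true_ids <- setNames(names(qf), names(qf))
  g <- grid_eta(qf, db, k_grid = c(0.7, 0.9), p_grid = c(0, 0.5, 0.9),
                true_ids = true_ids)
  expect_identical(dim(g), c(2L, 3L))
  for (i in seq_len(nrow(g))) {
    expect_true(all(diff(g[i, ]) <= 1e-12))
  }
  # self-queries at the recommended operating point: perfect accuracy
  self <- grid_eta(db$features[1:2], db, k_grid = 0.7, p_grid = 0.5,
                   true_ids = setNames(names(db$features)[1:2],
                                       names(db$features)[1:2]))
  expect_identical(unname(g["0.7", "0.5"]), 1)
  expect_identical(unname(self[1, 1]), 1)
  # 1x1 grid is consistent with a direct sweep + score at the same point
  s <- sweep_k(qf, db, k_values = 0.7, true_ids = true_ids)
  frac_correct <- s$frac_correct[s$k == 0.7 & s$symmetry]
  g11 <- grid_eta(qf, db, k_grid = 0.7, p_grid = 0.5, true_ids = true_ids)
  expect_identical(unname(g11[1, 1]) == 1, frac_correct == 1)
  expect_error(grid_eta(qf, db, k_grid = numeric(0), p_grid = 0.5,
                        true_ids = true_ids), "empty grid")
})
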