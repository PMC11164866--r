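test_that("descriptor distances follow the L2 norm", {
  expect_identical(descriptor_distance(rep(7L, 128), rep(7L, 128)), 0)
  d2 <- c(3, 4, rep(0, 126))
  expect_identical(descriptor_distance(rep(0, 128), d2), 5)
  expect_error(descriptor_distance(1:10, 1:10), "128")
  # scalar-loop reference on random integer vectors
  withr::with_seed(11, {
    for (i in 1:5) {
      a <- sample(0:255, 128, replace = TRUE)
      b <- sample(0:255, 128, replace = TRUE)
      ref <- 0
      for (n in 1:128) ref <- ref + (a[n] - b[n])^2
      expect_equal(descriptor_distance(a, b), sqrt(ref), tolerance = 1e-6)
    }
  })
})

test_that("ratio_match agrees with the exhaustive two-nearest-neighbour oracle", {
  withr::with_seed(12, {
    for (trial in 1:4) {
      A <- matrix(sample(0:255, 40 * 128, replace = TRUE), 40)
      B <- matrix(sample(0:255, 50 * 128, replace = TRUE), 50)
      for (k in c(0.8, 0.95, 1.0)) {
        got <- ratio_match(fake_feature_set(A), fake_feature_set(B), k)
        want <- oracle_ratio_match(A, B, k)
        expect_equal(got$query_index, want$query_index)
        expect_equal(got$db_index, want$db_index)
        expect_equal(got$distance, want$distance, tolerance = 1e-6)
      }
    }
  })
})

test_that("ratio-test boundaries: clear accept, ties, and duplicate descriptors", {
  # crafted database: query descriptor q, best at distance 6, second at 10
  q <- rep(0L, 128)
  b1 <- c(6L, rep(0L, 127))          # d = 6
  b2 <- c(0L, 10L, rep(0L, 126))     # d = 10
  fa <- fake_feature_set(rbind(q))
  fb <- fake_feature_set(rbind(b1, b2))
  expect_identical(nrow(ratio_match(fa, fb, k = 0.7)), 1L)  # 0.6 <= 0.7
  expect_identical(nrow(ratio_match(fa, fb, k = 0.5)), 0L)
  # tie d1 = d2: kept only at k = 1
  fb_tie <- fake_feature_set(rbind(b1, c(0L, 6L, rep(0L, 126))))
  expect_identical(nrow(ratio_match(fa, fb_tie, k = 0.99)), 0L)
  expect_identical(nrow(ratio_match(fa, fb_tie, k = 1.0)), 1L)
  expect_identical(ratio_match(fa, fb_tie, k = 1.0)$db_index, 1L)  # low index
  # duplicate best descriptor (d2 = 0): ratio defined as 1
  fb_dup <- fake_feature_set(rbind(q, q))
  expect_identical(nrow(ratio_match(fa, fb_dup, k = 0.9)), 0L)
  expect_identical(nrow(ratio_match(fa, fb_dup, k = 1.0)), 1L)
})

test_that("k = 1 matches every query feature; fewer than 2 db features match none", {
  A <- random_descriptors(20, seed = 13)
  B <- random_descriptors(30, seed = 14)
  fa <- fake_feature_set(A)
  expect_identical(nrow(ratio_match(fa, fake_feature_set(B), k = 1.0)), 20L)
  expect_identical(nrow(ratio_match(fa, fake_feature_set(B[1, , drop = FALSE]),
                                    k = 1.0)), 0L)
  expect_error(ratio_match(fa, fake_feature_set(B), k = 0), "in \\(0, 1\\]")
})

test_that("match sets are monotone in k", {
  A <- random_descriptors(60, seed = 15)
  B <- random_descriptors(80, seed = 16)
  fa <- fake_feature_set(A)
  fb <- fake_feature_set(B)
  prev <- NULL
  for (k in c(0.5, 0.7, 0.9, 1.0)) {
    cur <- ratio_match(fa, fb, k)
    key <- paste(cur$query_index, cur$db_index)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("symmetry filtering keeps exactly the mutual pairs", {
  fwd <- data.frame(query_index = c(0L, 1L), db_index = c(5L, 6L),
                    distance = c(1, 2))
  expect_identical(
    symmetry_filter(fwd, data.frame(query_index = 5L, db_index = 0L,
                                    distance = 1))$db_index, 5L)
  expect_identical(
    nrow(symmetry_filter(fwd, data.frame(query_index = 5L, db_index = 1L,
                                         distance = 1))), 0L)
  # property: output is a subset of forward, bounded by both sides
  A <- random_descriptors(40, seed = 17)
  B <- random_descriptors(40, seed = 18)
  fa <- fake_feature_set(A)
  fb <- fake_feature_set(B)
  f <- ratio_match(fa, fb, 0.95)
  r <- ratio_match(fb, fa, 0.95)
  s <- symmetry_filter(f, r)
  expect_true(all(paste(s$query_index, s$db_index) %in%
                  paste(f$query_index, f$db_index)))
  expect_lte(nrow(s), min(nrow(f), nrow(r)))
})

test_that("symmetric self-matching of an image against itself keeps all matches", {
  pf <- tiny_db()$features[[1]]
  n <- sym_count(pf, pf, k = 0.7)
  # every feature with a distinct descriptor matches itself symmetrically;
  # occasional duplicate descriptors (identical-looking spots) are dropped
  # by the d2 = 0 rule
  expect_gte(n, 0.97 * n_features(pf))
})

test_that("count_matches reduces to the pairwise path and honours symmetry", {
  A <- random_descriptors(30, seed = 19)
  B1 <- random_descriptors(40, seed = 20)
  B2 <- random_descriptors(40, seed = 21)
  fa <- fake_feature_set(A)
  db <- list(e1 = fake_feature_set(B1), e2 = fake_feature_set(B2))
  for (k in c(0.9, 1.0)) {
    cm_sym <- count_matches(fa, db, k = k, symmetry = TRUE)
    cm_fwd <- count_matches(fa, db, k = k, symmetry = FALSE)
    for (e in names(db)) {
      f <- ratio_match(fa, db[[e]], k)
      r <- ratio_match(db[[e]], fa, k)
      expect_identical(cm_fwd$counts[[e]], nrow(f))
      expect_identical(cm_sym$counts[[e]], nrow(symmetry_filter(f, r)))
      expect_lte(cm_sym$counts[[e]], cm_fwd$counts[[e]])
    }
  }
  # k = 1, symmetry off: every entry with >= 2 features matches everything
  cm <- count_matches(fa, db, k = 1.0, symmetry = FALSE)
  expect_true(all(cm$counts == nrow(A)))
  expect_identical(cm$query_feature_total, 30L)
})

test_that("degenerate queries and databases are handled explicitly", {
  empty <- fake_feature_set(matrix(integer(0), 0, 128))
  db <- list(e1 = fake_feature_set(random_descriptors(10, 22)))
  expect_warning(cm <- count_matches(empty, db), "no features")
  expect_true(all(cm$counts == 0L))
  expect_error(count_matches(db$e1, list()), "empty")
  expect_identical(length(count_matches(db$e1, db)$counts), 1L)
})
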