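# Shared fixtures, built once per test session and cached in an
# environment. Everything is generated in code under tempdir(); no binary
# fixtures ship with the package.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# A 4-pattern corpus with one perturbed query per pattern.
tiny_corpus <- function() {
  memo("corpus", function() {
    generate_corpus(4, file.path(tempdir(), "epuf-tiny-corpus"), seed = 42)
  })
}

tiny_db <- function() {
  memo("db", function() {
    corp <- tiny_corpus()
    refs <- corp$key[corp$key$role == "reference", ]
    build_database(file.path(corp$dir, refs$image_path),
                   file.path(tempdir(), "epuf-tiny-db"),
                   ids = refs$pattern_id)
  })
}

tiny_query_features <- function() {
  memo("query_features", function() {
    corp <- tiny_corpus()
    qs <- corp$key[corp$key$role == "query", ]
    fs <- lapply(seq_len(nrow(qs)), function(i) {
      extract_features(process_image(file.path(corp$dir, qs$image_path[i])))
    })
    names(fs) <- qs$pattern_id
    fs
  })
}

# Wrap a bare descriptor matrix as a feature_set (for matching-level tests
# that do not need real keypoints).
fake_feature_set <- function(desc, id = "fake") {
  desc <- matrix(as.integer(desc), nrow = nrow(desc))
  structure(
    list(source_id = id, keypoints = NULL, descriptors = desc,
         image_shape = c(64L, 64L), params = sift_params()),
    class = "feature_set"
  )
}

random_descriptors <- function(n, seed) {
  withr::with_seed(seed, matrix(sample(0:255, n * 128, replace = TRUE), n))
}

# Independent brute-force oracle for the ratio test: plain double loops,
# no shared code with the package implementation.
oracle_ratio_match <- function(A, B, k) {
  out <- NULL
  for (i in seq_len(nrow(A))) {
    d <- numeric(nrow(B))
    for (j in seq_len(nrow(B))) {
      d[j] <- sqrt(sum((as.numeric(A[i, ]) - as.numeric(B[j, ]))^2))
    }
    j1 <- which.min(d)
    d1 <- d[j1]
    d2 <- min(d[-j1])
    ratio <- if (d2 == 0 || d1 == d2) 1 else d1 / d2
    if (ratio <= k) {
      out <- rbind(out, c(i, j1, d1))
    }
  }
  if (is.null(out)) {
    data.frame(query_index = integer(0), db_index = integer(0),
               distance = numeric(0))
  } else {
    data.frame(query_index = as.integer(out[, 1]),
               db_index = as.integer(out[, 2]), distance = out[, 3])
  }
}

# Symmetric match count between two feature sets via the public API.
sym_count <- function(fa, fb, k = 0.7) {
  count_matches(fa, setNames(list(fb), "e"), k = k,
                symmetry = TRUE)$counts[["e"]]
}
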