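test_that("the bundled synthetic production fixture honors the published set algebra", {
  pats <- read_production_patterns()
  aff <- vapply(pats, `[[`, character(1), "affect")
  expect_equal(sum(aff == "pain"), 11L)
  expect_equal(sum(aff == "orgasm"), 3L)
  pain_major <- majority_set(pats[aff == "pain"])
  org_major <- majority_set(pats[aff == "orgasm"])
  expect_true(all(c(4, 6, 10, 43, 25, 26, 27, 7, 17, 45) %in% pain_major))
  expect_equal(org_major, c(4L, 6L, 10L, 25L, 26L, 27L, 43L))
  expect_equal(intersect(pain_major, org_major),
               c(4L, 6L, 10L, 25L, 26L, 27L, 43L))
})

test_that("malformed production files are rejected", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"study_id": "s1", "affect": "pain", "aus": [4, 99]}]', bad)
  expect_error(read_production_patterns(bad), "unknown AU")
  bad2 <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"study_id": "s1", "aus": [4]}]', bad2)
  expect_error(read_production_patterns(bad2), "affect")
})

test_that("Hamming distance counts differing positions", {
  u <- au_set_to_vector(c(4, 6, 9))
  v <- au_set_to_vector(c(4, 6, 10, 20))
  expect_equal(hamming_distance(u, u), 0)
  expect_equal(hamming_distance(u, 1 - u), 42)
  expect_equal(hamming_distance(u, v), 3)
  expect_error(hamming_distance(u, v[-1]), "equal length")
})

test_that("nearest-pattern classification matches a brute-force scan", {
  pats <- read_production_patterns()
  withr::with_seed(43, {
    models <- lapply(1:40, function(i)
      fake_model(paste0("m", i), sample(c("pain", "orgasm"), 1),
                 sample(build_catalog()$au_id, sample(2:8, 1))))
  })
  res <- nearest_pattern_classify(models, pats)
  X <- models_matrix(models)
  P <- do.call(rbind, lapply(pats, `[[`, "au_vector"))
  brute_min <- vapply(seq_len(nrow(X)), function(i)
    min(vapply(seq_len(nrow(P)), function(j)
      hamming_distance(X[i, ], P[j, ]), numeric(1))), numeric(1))
  expect_equal(res$assignments$min_distance, brute_min)
  # non-tied models take the affect of the unique closest pattern
  aff <- vapply(pats, `[[`, character(1), "affect")
  for (i in seq_len(nrow(X))) {
    d <- vapply(seq_len(nrow(P)), function(j)
      hamming_distance(X[i, ], P[j, ]), numeric(1))
    tied_affs <- unique(aff[d == min(d)])
    if (length(tied_affs) == 1L)
      expect_equal(res$assignments$assigned[i], tied_affs)
  }
  expect_equal(sum(res$confusion), 40)
})

test_that("a model equal to a pattern is classified at distance zero", {
  pats <- read_production_patterns()
  m <- fake_model("exact", "pain", pats[[7]]$au_set)
  res <- nearest_pattern_classify(list(m, fake_model("o", "orgasm",
                                                     c(1, 2, 5))), pats)
  row <- res$assignments[res$assignments$model_id == "exact", ]
  expect_equal(row$min_distance, 0)
  expect_equal(row$assigned, "pain")
})

test_that("affect ties are broken by majority among tied patterns", {
  cat42 <- build_catalog()
  mini <- structure(list(
    list(study_id = "p1", affect = "pain", au_set = c(4L, 6L),
         au_vector = au_set_to_vector(c(4, 6), cat42)),
    list(study_id = "p2", affect = "pain", au_set = c(4L, 9L),
         au_vector = au_set_to_vector(c(4, 9), cat42)),
    list(study_id = "o1", affect = "orgasm", au_set = c(4L, 12L),
         au_vector = au_set_to_vector(c(4, 12), cat42))),
    class = "production_patterns")
  # model {4} is at distance 1 from all three -> 2-vs-1 pain majority
  res <- nearest_pattern_classify(list(fake_model("t", "orgasm", 4),
                                       fake_model("x", "pain", c(4, 6))),
                                  mini)
  expect_equal(res$assignments$assigned[1], "pain")
  expect_true(res$assignments$tie_broken[1])
})

test_that("majority sets require a strict majority", {
  sets <- c(rep(list(c(4, 6)), 6), rep(list(c(6, 9)), 5))
  expect_equal(majority_set(sets), c(4, 6))   # 6/11 in, 5/11 out
  expect_equal(majority_set(list(c(2, 5), c(2, 5), c(2, 9))), c(2, 5))
  expect_error(majority_set(list()), "empty")
})

test_that("the four-set Venn partition is disjoint and exhaustive", {
  withr::with_seed(53, {
    for (i in 1:25) {
      sets <- lapply(1:4, function(j)
        sample(build_catalog()$au_id, sample(0:10, 1)))
      vp <- venn_partition(sets[[1]], sets[[2]], sets[[3]], sets[[4]])
      all_aus <- sort(unique(unlist(sets)))
      expect_equal(sort(unlist(vp$regions, use.names = FALSE)), all_aus)
      expect_equal(sum(lengths(vp$regions)), length(all_aus))
    }
  })
  vp <- venn_partition(c(4, 6), c(1, 2), c(4, 7), c(25))
  expect_equal(venn_overlap(vp, c("model_pain", "prod_pain")), 4L)
  expect_equal(venn_overlap(vp, "model_pain",
                            c("model_orgasm", "prod_pain",
                              "prod_orgasm")), 6L)
})
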