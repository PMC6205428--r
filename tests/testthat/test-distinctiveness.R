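cat42 <- build_catalog()
single_au_matrix <- function(au, n) {
  m <- matrix(rep(au_set_to_vector(au, cat42), n), nrow = n, byrow = TRUE)
  colnames(m) <- paste0("AU", cat42$au_id)
  m
}

test_that("Bernoulli naive Bayes training matches the Laplace closed form", {
  X <- rbind(single_au_matrix(4, 20), single_au_matrix(12, 20))
  fit <- train_bernoulli_nb(X, rep(c("pain", "orgasm"), each = 20),
                            alpha = 1)
  expect_equal(fit$theta["pain", "AU4"], 21 / 22)
  expect_equal(fit$theta["orgasm", "AU4"], 1 / 22)
  expect_equal(unname(fit$priors), c(0.5, 0.5))
  # alpha = 0 permits boundary probabilities and warns about them
  expect_warning(f0 <- train_bernoulli_nb(X, rep(c("pain", "orgasm"),
                                                 each = 20), alpha = 0),
                 "-Inf")
  expect_equal(f0$theta["pain", "AU12"], 0)
  # identical vectors in equal classes give identical class-conditionals
  Xs <- rbind(single_au_matrix(4, 10), single_au_matrix(4, 10))
  fs <- train_bernoulli_nb(Xs, rep(c("a", "b"), each = 10))
  expect_equal(fs$theta["a", ], fs$theta["b", ])
  expect_error(train_bernoulli_nb(X, factor(rep("pain", 40),
                                            levels = c("pain", "orgasm"))),
               "empty class")
})

test_that("posteriors follow Bayes rule and normalize", {
  X <- rbind(single_au_matrix(4, 20), single_au_matrix(12, 20))
  fit <- train_bernoulli_nb(X, rep(c("pain", "orgasm"), each = 20))
  post <- nb_posterior(fit, au_set_to_vector(4, cat42))
  # two discriminating likelihood ratios of 21 each: posterior 441/442
  expect_equal(unname(post[1, "pain"]), 441 / 442, tolerance = 1e-12)
  expect_equal(rowSums(post), 1)
  Xs <- rbind(single_au_matrix(4, 10), single_au_matrix(4, 10))
  fs <- train_bernoulli_nb(Xs, rep(c("a", "b"), each = 10))
  expect_equal(unname(nb_posterior(fs, au_set_to_vector(4, cat42))[1, ]),
               c(0.5, 0.5))
})

test_that("split-half classification separates disjoint classes and is seed-stable", {
  X <- rbind(single_au_matrix(4, 20), single_au_matrix(12, 20))
  labs <- rep(c("pain", "orgasm"), each = 20)
  res <- split_half_classify(X, labs, n_splits = 50, seed = 5)
  expect_true(all(diag(res$posterior_matrix) > 0.99))
  expect_equal(unname(rowSums(res$posterior_matrix)), c(1, 1),
               tolerance = 1e-9)
  res2 <- split_half_classify(X, labs, n_splits = 50, seed = 5)
  expect_identical(res$posterior_matrix, res2$posterior_matrix)
  # shuffling the labels destroys the separation
  shuf <- withr::with_seed(9, sample(labs))
  res3 <- split_half_classify(X, shuf, n_splits = 200, seed = 6)
  expect_true(all(abs(diag(res3$posterior_matrix) - 0.5) < 0.12))
  expect_error(split_half_classify(X[1:3, ], c("a", "a", "b"), 10),
               "at least 2")
})

test_that("d-prime matches inverse-normal oracles and assigns quadrants", {
  expect_equal(dprime(10, 10, 10, 10, correction = "none")$dprime, 0)
  # equal rates sit on the boundary; ties go to the non-discriminated side
  expect_equal(dprime(10, 10, 10, 10, correction = "none")$quadrant,
               "confused")
  d <- dprime(10, 0, 0, 10)
  expect_equal(d$hit_rate, 10.5 / 11)
  expect_equal(d$fa_rate, 0.5 / 11)
  expect_equal(d$dprime, stats::qnorm(10.5 / 11) - stats::qnorm(0.5 / 11))
  expect_equal(d$dprime, 3.38, tolerance = 1e-3)
  expect_equal(d$quadrant, "discriminated")
  raw <- dprime(84134, 15866, 15866, 84134, correction = "none")
  expect_equal(raw$dprime, 2, tolerance = 1e-4)
  expect_error(dprime(0, 0, 5, 5), "denominator")
})

test_that("d-prime is antisymmetric under hit / false-alarm exchange", {
  withr::with_seed(23, {
    for (i in 1:50) {
      k <- sample(0:20, 4, replace = TRUE) + c(1, 0, 1, 0)
      d1 <- dprime(k[1], k[2], k[3], k[4])
      d2 <- dprime(k[3], k[4], k[1], k[2])
      expect_equal(d1$dprime, -d2$dprime, tolerance = 1e-12)
    }
  })
})

test_that("validation d-prime pools counts per model", {
  val <- data.frame(
    observer_id = "v", trial_id = 1:8,
    word = rep(c("pain", "orgasm"), 4),
    model_id = rep(c("m1", "m2"), each = 4),
    matched = rep(c(TRUE, TRUE, FALSE, FALSE), 2),
    answer = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))
  out <- validation_dprime(val)
  m1 <- out[out$model_id == "m1", ]
  expect_equal(m1$hits, 2)
  expect_equal(m1$false_alarms, 0)
  expect_equal(m1$quadrant, "discriminated")
  m2 <- out[out$model_id == "m2", ]
  expect_equal(c(m2$hits, m2$misses, m2$false_alarms,
                 m2$correct_rejections), c(1, 1, 2, 0))
})

test_that("the 2x2 chi-square follows the closed form", {
  r <- chi_square_2x2(matrix(c(35, 5, 5, 35), 2, byrow = TRUE))
  expect_equal(r$statistic, 45)
  expect_equal(r$df, 1L)
  flat <- chi_square_2x2(matrix(20, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(40, 0, 0, 0), 2)), "margin")
  # independent oracle: uncorrected chisq.test
  m <- matrix(c(30, 12, 7, 31), 2)
  expect_equal(chi_square_2x2(m)$statistic,
               unname(stats::chisq.test(m, correct = FALSE)$statistic),
               tolerance = 1e-12)
})
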