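test_that("noise-free templates reproduce the group-level AU sets", {
  w <- make_template("western", add_prob = 0, drop_prob = 0, seed = 1)
  expect_equal(w$pain_aus, c(4L, 6L, 9L, 10L, 20L))
  expect_equal(w$orgasm_aus, c(1L, 2L, 5L, 26L, 27L, 43L))
  e <- make_template("east_asian", add_prob = 0, drop_prob = 0, seed = 1)
  expect_equal(e$pain_aus, c(4L, 6L, 9L, 10L, 20L))
  expect_equal(e$orgasm_aus, c(1L, 2L, 12L, 43L))
})

test_that("template noise keeps at least one AU per affect and the affects disjoint", {
  for (s in 1:20) {
    t1 <- make_template("western", add_prob = 0.3, drop_prob = 1, seed = s)
    expect_gte(length(t1$pain_aus), 1L)
    expect_gte(length(t1$orgasm_aus), 1L)
    expect_length(intersect(t1$pain_aus, t1$orgasm_aus), 0L)
  }
  expect_error(make_template("western", add_prob = 1.5), "probability")
  expect_error(make_template("western", drop_prob = -0.1), "probability")
})

test_that("responses follow the overlap rule deterministically at zero lapse", {
  tmpl <- make_template("western",
                        base_templates = list(pain = c(4, 9),
                                              orgasm = c(12, 26)),
                        add_prob = 0, drop_prob = 0, lapse_rate = 0,
                        seed = 1)
  mk <- function(aus) {
    s <- sample_stimulus(seed = 2)
    s$au_ids <- as.integer(aus)
    s$au_vector <- au_set_to_vector(aus)
    prof <- s$profiles[rep(1, length(aus)), -1]
    s$profiles <- cbind(au_id = as.integer(aus), prof)
    s
  }
  # stimulus containing the whole pain template -> pain, rated 1-5
  r <- respond(tmpl, mk(c(4, 9, 20)), seed = 4)
  expect_equal(r$response, "pain")
  expect_true(r$intensity %in% 1:5)
  # disjoint from both templates -> other, no rating
  r2 <- respond(tmpl, mk(c(1, 2, 5)), seed = 4)
  expect_equal(r2$response, "other")
  expect_true(is.na(r2$intensity))
  # equal overlap with both affects ties to other
  r3 <- respond(tmpl, mk(c(4, 12)), seed = 4)
  expect_equal(r3$response, "other")
})

test_that("a fully lapsing observer responds uniformly at random", {
  tmpl <- make_template("western", add_prob = 0, drop_prob = 0,
                        lapse_rate = 1, seed = 5)
  log <- withr::with_seed(6, simulate_observer(tmpl, n_trials = 9000))
  freq <- table(factor(log$trials$response,
                       levels = c("pain", "orgasm", "other"))) / 9000
  se <- sqrt((1 / 3) * (2 / 3) / 9000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})

test_that("cohort simulation is reproducible and correctly sized", {
  c1 <- simulate_cohort(3, "western", n_trials = 50, seed = 77)
  c2 <- simulate_cohort(3, "western", n_trials = 50, seed = 77)
  expect_length(c1, 3L)
  expect_equal(nrow(c1[[1]]$trials), 50L)
  expect_identical(c1[[2]]$trials, c2[[2]]$trials)
  expect_identical(c1[[3]]$au_matrix, c2[[3]]$au_matrix)
  expect_identical(c1[[1]]$template$pain_aus, c2[[1]]$template$pain_aus)
  one <- simulate_cohort(1, "western", n_trials = 10, seed = 1)
  expect_length(one, 1L)
  expect_equal(nrow(one[[1]]$trials), 10L)
  expect_error(simulate_cohort(0, "western"), "at least 1")
})

test_that("intensity ratings are present exactly on affect trials", {
  log <- simulate_cohort(1, "western", n_trials = 2000, seed = 13)[[1]]
  aff <- log$trials$response != "other"
  expect_true(all(!is.na(log$trials$intensity[aff])))
  expect_true(all(is.na(log$trials$intensity[!aff])))
  expect_true(all(log$trials$intensity[aff] %in% 1:5))
})

test_that("template AUs are enriched on affect-labeled trials", {
  # the statistical structure the reverse-correlation fit relies on
  log <- simulate_cohort(1, "western", n_trials = 3600, seed = 23,
                         lapse_rate = 0)[[1]]
  tmpl <- log$template
  pain <- log$trials$response == "pain"
  cols <- paste0("AU", tmpl$pain_aus)
  non <- setdiff(colnames(log$au_matrix),
                 paste0("AU", c(tmpl$pain_aus, tmpl$orgasm_aus)))
  rate_in <- mean(log$au_matrix[pain, cols])
  rate_out <- mean(log$au_matrix[pain, non])
  expect_gt(rate_in, rate_out)
  org <- log$trials$response == "orgasm"
  expect_gt(mean(log$au_matrix[org, paste0("AU", tmpl$orgasm_aus)]),
            mean(log$au_matrix[org, non]))
})

test_that("validation sessions have the stated design: 400 stimuli, 800 trials, half matched", {
  models <- c(lapply(1:20, function(i)
    fake_model(paste0("p", i), "pain", c(4, 6, 9, 10, 20))),
    lapply(1:20, function(i)
      fake_model(paste0("o", i), "orgasm", c(1, 2, 5, 26, 27, 43))))
  tmpl <- make_template("western", add_prob = 0, drop_prob = 0,
                        lapse_rate = 0, observer_id = "val1", seed = 2)
  val <- simulate_validation(models, list(tmpl), n_identities = 10,
                             seed = 31)
  expect_equal(nrow(val), 800L)
  expect_equal(sum(val$matched), 400L)
  expect_equal(length(unique(paste(val$model_id, val$matched))), 80L)
  # templates identical to the models and no lapse: perfect discrimination
  expect_true(all(val$answer[val$matched]))
  expect_false(any(val$answer[!val$matched]))
})

test_that("a fully lapsing validator answers yes about half the time", {
  models <- list(fake_model("p1", "pain", c(4, 6)),
                 fake_model("o1", "orgasm", c(12, 26)))
  tmpl <- make_template("western", lapse_rate = 1, observer_id = "v",
                        seed = 3)
  val <- simulate_validation(models, list(tmpl), n_identities = 500,
                             seed = 41)
  hit <- mean(val$answer[val$matched])
  fa <- mean(val$answer[!val$matched])
  se <- 3 * sqrt(0.25 / 1000)
  expect_lt(abs(hit - 0.5), se)
  expect_lt(abs(fa - 0.5), se)
  expect_error(simulate_validation(list(), list(tmpl)), "empty")
})
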