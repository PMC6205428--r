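test_that("phi correlation matches the contingency closed form and cor.test", {
  # a=40 (AU & orgasm), b=10, c=10, d=40 over n=100
  x <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  res <- phi_correlation(x, y)
  a <- 40; b <- 10; cc <- 10; d <- 40
  phi <- (a * d - b * cc) /
    sqrt((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(res$r, phi, tolerance = 1e-12)
  expect_equal(res$r, 0.6, tolerance = 1e-12)
  expect_lt(res$p, 1e-9)
  ct <- stats::cor.test(x, y)
  expect_equal(res$p, unname(ct$p.value), tolerance = 1e-12)
  expect_equal(phi_correlation(x, x)$r, 1)
  expect_error(phi_correlation(rep(1, 10), rep(0:1, 5)), "constant")
  expect_error(phi_correlation(0:1, 0:1), "at least 3")
  expect_error(phi_correlation(c(0, 1, 2), c(0, 1, 1)), "binary")
})

test_that("phi agrees with brute-force Pearson on random binary pairs", {
  withr::with_seed(17, {
    for (i in 1:1000) {
      n <- sample(10:60, 1)
      x <- stats::rbinom(n, 1, runif(1, 0.2, 0.8))
      y <- stats::rbinom(n, 1, runif(1, 0.2, 0.8))
      if (var(x) == 0 || var(y) == 0) next
      brute <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(phi_correlation(x, y)$r, brute, tolerance = 1e-12)
    }
  })
})

test_that("fitting a deterministic observer recovers its single-AU templates with correct signs", {
  log <- deterministic_log()
  m <- fit_models(log)
  expect_true(4L %in% m$pain$significant_aus)
  expect_true(12L %in% m$orgasm$significant_aus)
  expect_false(12L %in% m$pain$significant_aus)
  # sign coherence: pain AUs correlate negatively with the orgasm coding
  cors <- m$pain$au_correlations
  expect_true(all(cors$r[cors$au_id %in% m$pain$significant_aus] < 0))
  expect_true(all(cors$r[cors$au_id %in% m$orgasm$significant_aus] > 0))
  expect_length(intersect(m$pain$significant_aus,
                          m$orgasm$significant_aus), 0L)
})

test_that("a random responder yields about alpha * 42 significant AUs", {
  tot <- withr::with_seed(57, vapply(1:12, function(i) {
    tmpl <- make_template("western", lapse_rate = 1,
                          observer_id = paste0("r", i))
    log <- simulate_observer(tmpl, n_trials = 3600)
    m <- fit_models(log)
    length(m$pain$significant_aus) + length(m$orgasm$significant_aus)
  }, numeric(1)))
  # expectation 0.05 * 42 = 2.1 false positives per observer
  expect_lt(abs(mean(tot) - 2.1), 1.3)
})

test_that("degenerate logs are rejected", {
  log <- deterministic_log(n_trials = 400)
  log$trials$response[log$trials$response == "orgasm"] <- "other"
  expect_error(fit_models(log), "no orgasm responses")
  log2 <- deterministic_log(n_trials = 400)
  log2$trials$response[] <- "other"
  expect_error(fit_models(log2), "no pain responses")
})

test_that("temporal regression recovers a planted amplitude coefficient", {
  y <- rep(c(0, 1), each = 100)
  log <- planted_log(n = 200, response = ifelse(y == 1, "orgasm", "pain"),
                     amplitude = y)
  b <- fit_temporal(log, 4L)
  expect_equal(unname(b["amplitude"]), 1, tolerance = 1e-8)
  expect_true(all(abs(b[setdiff(names(b), "amplitude")]) < 1e-8))
})

test_that("temporal regression slopes are null when parameters carry no signal", {
  log <- planted_log(n = 800, seed = 11)
  X <- log$profiles[, facerevcorr:::profile_columns()]
  y <- as.integer(log$trials$response == "orgasm")
  fit <- stats::lm(y ~ ., data = cbind(y = y, X))
  se <- summary(fit)$coefficients[-1, "Std. Error"]
  b <- fit_temporal(log, 4L)
  expect_true(all(abs(b) < 4 * se))
})

test_that("regressions refuse too few trials", {
  log <- planted_log(n = 5)
  expect_error(fit_temporal(log, 4L), "need >= 9")
  expect_error(fit_intensity_gradient(log, 4L, "pain"), "need >= 9")
  expect_error(fit_temporal(planted_log(n = 100), 9L), "only 0")
})

test_that("intensity gradient recovers a planted amplitude dependence", {
  withr::with_seed(19, {
    amp <- stats::runif(400, 0.2, 1)
    log <- planted_log(n = 400, amplitude = amp,
                       response = rep("pain", 400),
                       intensity = pmin(pmax(round(1 + 4 * amp), 1), 5))
  })
  g <- fit_intensity_gradient(log, 4L, "pain")
  expect_gt(unname(g["amplitude"]), 2)
  expect_error(fit_intensity_gradient(log, 4L, "orgasm"), "no trials")
})

test_that("high-intensity profiles are per-parameter means over the 4-5 band", {
  log <- planted_log(n = 20, response = rep("pain", 20),
                     intensity = c(5, 4, rep(2, 18)))
  prof <- high_intensity_profile(log, 4L, "pain")
  cols <- facerevcorr:::profile_columns()
  expect_equal(prof, colMeans(log$profiles[1:2, cols]))
  one <- planted_log(n = 20, response = rep("pain", 20),
                     intensity = c(4, rep(1, 19)))
  expect_equal(high_intensity_profile(one, 4L, "pain"),
               unlist(one$profiles[1, cols]))
  low <- planted_log(n = 20, response = rep("pain", 20),
                     intensity = rep(2, 20))
  expect_error(high_intensity_profile(low, 4L, "pain"), "widening")
})

test_that("fitted cohort models are sign-coherent and affect-disjoint", {
  cohort <- simulate_cohort(4, "western", n_trials = 3600, seed = 61)
  models <- fit_cohort(cohort)
  info <- models_info(models)
  for (i in seq_along(models)) {
    m <- models[[i]]
    cors <- m$au_correlations
    sig_r <- cors$r[cors$au_id %in% m$significant_aus]
    if (m$affect == "pain") expect_true(all(sig_r < 0))
    else expect_true(all(sig_r > 0))
  }
  for (ob in unique(info$observer_id)) {
    pm <- models[[which(info$observer_id == ob & info$affect == "pain")]]
    om <- models[[which(info$observer_id == ob & info$affect == "orgasm")]]
    expect_length(intersect(pm$significant_aus, om$significant_aus), 0L)
  }
  X <- models_matrix(models)
  expect_equal(dim(X), c(8L, 42L))
  expect_equal(unname(rowSums(X)), info$n_aus)
  rec <- recovery_summary(cohort, models)
  expect_true(all(rec$sensitivity >= 0 & rec$sensitivity <= 1))
})
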