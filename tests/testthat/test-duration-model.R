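test_that("baseline duration sums segment means and names missing phones", {
  seg <- tibble::tibble(phone = c("a", "b", "c"),
                        mean_duration = c(50, 100, 70))
  lex <- tibble::tibble(word_id = c("w1", "w2"),
                        transcription = c("abc", "b"))
  out <- baseline_duration(lex, seg)
  expect_equal(out$baseline_duration, c(220, 100))
  expect_error(baseline_duration(tibble::tibble(word_id = "x",
                                                transcription = "az"), seg),
               "z")
  # oracle: independent per-phone lookup-and-sum
  study <- small_study()
  bl <- baseline_duration(study$lexicon, study$segment_table)
  lookup <- setNames(study$segment_table$mean_duration,
                     study$segment_table$phone)
  oracle <- vapply(strsplit(study$lexicon$transcription, ""),
                   function(ph) sum(lookup[ph]), numeric(1))
  expect_equal(bl$baseline_duration, oracle)
})

test_that("duration difference is the residual of observed on baseline", {
  set.seed(21)
  tok <- tibble::tibble(baseline_duration = runif(50, 100, 500))
  tok$observed_duration <- 30 + 0.8 * tok$baseline_duration
  out <- duration_difference(tok)
  expect_equal(out$duration_difference, rep(0, 50), tolerance = 1e-10)

  tok$observed_duration <- tok$observed_duration + rnorm(50, sd = 25)
  out <- duration_difference(tok)
  expect_equal(sum(out$duration_difference), 0, tolerance = 1e-8)
  expect_lt(abs(cor(out$duration_difference, out$baseline_duration)), 1e-10)
  # intercept absorption: constant shifts leave residuals unchanged
  shifted <- dplyr::mutate(tok, observed_duration = observed_duration + 123)
  expect_equal(duration_difference(shifted)$duration_difference,
               out$duration_difference)

  expect_error(duration_difference(dplyr::mutate(tok, baseline_duration = 5)),
               "constant")
})

test_that("duration difference recovers the generator's non-baseline signal", {
  # word-level predictor independent of baseline: at vanishing residual
  # noise the residualized response is essentially the non-baseline signal
  set.seed(51)
  cov <- tibble::tibble(word_id = sprintf("w%03d", 1:150),
                        baseline_duration = runif(150, 150, 500),
                        x = rnorm(150))
  tok <- generate_tokens(cov, c(baseline_duration = 1, x = 25,
                                speech_rate = -15),
                         intercept = 80, residual_sd = 0.01, seed = 51)
  tok <- duration_difference(tok)
  signal <- 25 * tok$x - 15 * tok$speech_rate
  expect_gt(cor(tok$duration_difference, signal), 0.9)
})

test_that("log_plus_one maps counts as documented", {
  expect_equal(log_plus_one(0), 0)
  expect_equal(log_plus_one(exp(1) - 1), 1)
  x <- runif(20, 0, 100)
  expect_identical(order(log_plus_one(x)), order(x))
  expect_error(log_plus_one(-1), "non-negative")
})

test_that("fit_standard is exact OLS with calibrated null p-values", {
  d <- tibble::tibble(x = rnorm(40))
  d$y <- 2 * d$x
  fit <- fit_standard(d, y ~ x)
  expect_equal(unname(coef(fit$fit)["x"]), 2.0, tolerance = 1e-12)

  # aliased design fails naming the offender unless checks are off
  d$x2 <- d$x
  expect_error(fit_standard(d, y ~ x + x2), "x2")
  expect_s3_class(fit_standard(d, y ~ x + x2, check_rank = FALSE),
                  "duration_fit")

  set.seed(22)
  ps <- replicate(1000, {
    dd <- data.frame(y = rnorm(25), noise = rnorm(25))
    summary(lm(y ~ noise, dd))$coefficients["noise", 4]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("fit_standard recovers generating coefficients on generator data", {
  set.seed(23)
  cov <- tibble::tibble(word_id = sprintf("w%03d", 1:200), a = rnorm(200),
                        b = rnorm(200))
  truth <- c(a = 15, b = -8, speech_rate = -12)
  tok <- generate_tokens(cov, truth, intercept = 350, residual_sd = 18,
                         seed = 23)
  fit <- fit_standard(tok, observed_duration ~ a + b + speech_rate)
  td <- tidy(fit)
  for (nm in names(truth)) {
    row <- td[td$term == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]), 3 * row$std.error)
  }
  expect_gt(glance(fit)$adj.r.squared, 0)
})

test_that("fit_mixed filters hapax types and recovers variance components", {
  set.seed(24)
  # 100 types x 5 tokens, type intercept sd 2, residual sd 1
  tau_hat <- replicate(25, {
    d <- tibble::tibble(word_id = rep(sprintf("t%03d", 1:100), each = 5))
    u <- rnorm(100, sd = 2)
    d$x <- rnorm(500)
    d$y <- 3 + 0.5 * d$x + u[as.integer(factor(d$word_id))] + rnorm(500)
    fit <- fit_mixed(d, y ~ x)
    sqrt(lme4::VarCorr(fit$fit)$word_id[1, 1])
  })
  expect_gt(mean(tau_hat), 1.6)
  expect_lt(mean(tau_hat), 2.4)

  # hapax exclusion contract
  d <- tibble::tibble(word_id = c("a", "a", "b", "c", "c"),
                      x = rnorm(5), y = rnorm(5))
  fit <- suppressWarnings(suppressMessages(fit_mixed(d, y ~ x)))
  expect_identical(fit$n_hapax_dropped, 1L)
  expect_identical(nrow(fit$data), 4L)
})

test_that("zero between-type variance gives near-equal marginal and conditional R2", {
  set.seed(25)
  d <- tibble::tibble(word_id = rep(sprintf("t%02d", 1:40), each = 4))
  d$x <- rnorm(160)
  d$y <- 2 * d$x + rnorm(160)
  fit <- suppressMessages(fit_mixed(d, y ~ x))
  r2 <- r2_mixed(fit$fit)
  expect_lt(r2["conditional"] - r2["marginal"], 0.05)
  expect_true(is.logical(fit$singular))
})

test_that("residual trimming removes the expected Gaussian tail fraction", {
  set.seed(26)
  d <- tibble::tibble(x = rnorm(1000))
  d$y <- 1 + 2 * d$x + rnorm(1000)
  fit <- fit_standard(d, y ~ x)
  trimmed <- trim_refit(fit)
  frac <- trimmed$trimmed_fraction
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.025)

  # one gross outlier: exactly that observation removed
  d2 <- tibble::tibble(x = rnorm(200))
  d2$y <- d2$x + rnorm(200)
  d2$y[57] <- d2$y[57] + 30
  t2 <- trim_refit(fit_standard(d2, y ~ x))
  expect_identical(t2$trimmed, 1L)
  expect_identical(nrow(t2$data), 199L)

  # nothing beyond the threshold: fit unchanged
  d3 <- tibble::tibble(x = seq_len(20))
  d3$y <- d3$x + rep(c(-0.1, 0.1), 10)
  t3 <- trim_refit(fit_standard(d3, y ~ x))
  expect_identical(t3$trimmed, 0L)
  expect_equal(coef(t3$fit), coef(fit_standard(d3, y ~ x)$fit))

  # mass trimming is refused
  d4 <- tibble::tibble(x = rnorm(20), y = c(rep(0, 10), rep(1000, 10)))
  expect_error(trim_refit(fit_standard(d4, y ~ x), threshold = 0.1),
               "trimming")
})

test_that("stepwise elimination drops the weakest terms first and keeps forced ones", {
  set.seed(27)
  d <- tibble::tibble(x1 = rnorm(300), x2 = rnorm(300),
                      speech_rate = rnorm(300), noise = rnorm(300))
  d$y <- 5 * d$x1 + 4 * d$x2 + rnorm(300)
  fit <- fit_standard(d, y ~ x1 + x2 + speech_rate + noise)
  out <- stepwise_eliminate(fit)
  kept <- labels(terms(stats::formula(out$fit)))
  expect_true(all(c("x1", "x2", "speech_rate") %in% kept))
  expect_false("noise" %in% kept)
  expect_true("noise" %in% out$dropped)

  # all terms significant: unchanged
  fit2 <- fit_standard(d, y ~ x1 + x2)
  out2 <- stepwise_eliminate(fit2)
  expect_length(out2$dropped, 0)

  # pure-noise term goes first in the vast majority of draws
  first_drop <- replicate(200, {
    dd <- tibble::tibble(s1 = rnorm(60), s2 = rnorm(60), nz = rnorm(60))
    dd$y <- 4 * dd$s1 + 4 * dd$s2 + rnorm(60)
    res <- stepwise_eliminate(fit_standard(dd, y ~ s1 + s2 + nz),
                              forced = character(0))
    if (length(res$dropped)) res$dropped[1] else NA_character_
  })
  expect_gt(mean(first_drop == "nz", na.rm = TRUE), 0.9)

  # aliased duplicate: one copy eliminated, no crash
  d$x1b <- d$x1
  ali <- stepwise_eliminate(fit_standard(d, y ~ x1 + x1b + speech_rate,
                                         check_rank = FALSE))
  kept3 <- labels(terms(stats::formula(ali$fit)))
  expect_identical(sum(c("x1", "x1b") %in% kept3), 1L)
})

test_that("stepwise elimination works on mixed fits with Satterthwaite tests", {
  set.seed(28)
  d <- tibble::tibble(word_id = rep(sprintf("t%02d", 1:50), each = 4))
  u <- rnorm(50)
  d$x <- rnorm(200)
  d$noise <- rnorm(200)
  d$speech_rate <- rnorm(200)
  d$y <- 2 * d$x - 1 * d$speech_rate + u[as.integer(factor(d$word_id))] +
    rnorm(200)
  fit <- fit_mixed(d, y ~ x + noise + speech_rate)
  out <- stepwise_eliminate(fit)
  kept <- labels(terms(lme4::nobars(stats::formula(out$fit))))
  expect_true("x" %in% kept)
  expect_false("noise" %in% kept)
  expect_true("speech_rate" %in% kept)
})

test_that("vif matches its definition and flags collinearity", {
  set.seed(29)
  n <- 500
  d <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                      d = rnorm(n), e = rnorm(n))
  v <- vif(d, names(d))
  expect_true(all(v$vif < 2))
  # orthogonal design: exactly 1
  orth <- tibble::tibble(a = rep(c(-1, 1), each = 4),
                         b = rep(c(-1, 1), times = 4))
  expect_equal(vif(orth, c("a", "b"))$vif, c(1, 1))
  # near-duplicate predictor explodes
  d$a2 <- d$a + rnorm(n, sd = 1e-4)
  expect_gt(max(vif(d, c("a", "a2", "b"))$vif), 10)
  # cross-check against the car implementation
  d$y <- rnorm(n)
  cv <- car::vif(lm(y ~ a + b + c + d + e, data = d))
  expect_equal(v$vif, unname(cv[v$predictor]), tolerance = 1e-8)
})
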