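test_that("the efficiency fit recovers exact collinear relations", {
  m <- data.frame(mean_ref = c(1, 2, 3), mean_tag = c(2, 4, 6))
  f <- fit_efficiency(m)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
  expect_equal(f$n_points, 3L)
  f2 <- fit_efficiency(data.frame(mean_ref = c(0, 1, 2), mean_tag = c(1, 3, 5)))
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 1)
  expect_error(fit_efficiency(data.frame(mean_ref = 1:2, mean_tag = 1:2)),
               "insufficient data")
  expect_error(
    fit_efficiency(data.frame(mean_ref = c(1, 1, 1), mean_tag = c(1, 2, 3))),
    "degenerate design")
})

test_that("the efficiency fit matches closed-form least squares to 1e-9", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:15, 1)
    x <- runif(n, 0, 1000) + rnorm(n)
    y <- runif(1, -1, 2) * x + runif(1, -50, 200) + rnorm(n, sd = 5)
    f <- fit_efficiency(data.frame(mean_ref = x, mean_tag = y))
    o <- ols_closed_form(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-9)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-9)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-9)
  }
})

test_that("normalization sets the reference to 100 and scales others by the slope ratio", {
  fits <- data.frame(antibody_id = c("ref", "X"), experiment_id = "e1",
                     slope = c(2.0, 1.0))
  norm <- normalize_to_reference(fits, "ref")
  expect_equal(norm$normalized_value[norm$antibody_id == "ref"], 100)
  expect_equal(norm$normalized_value[norm$antibody_id == "X"], 50)
  fits$slope <- c(0.8, 0.8)
  expect_equal(normalize_to_reference(fits, "ref")$normalized_value, c(100, 100))
  fits$slope <- c(0, 1)
  expect_error(normalize_to_reference(fits, "ref"), "degenerate reference")
  expect_error(normalize_to_reference(fits, "absent"), "missing reference")
})

test_that("normalization is idempotent and invariant to channel gain", {
  fits <- data.frame(antibody_id = c("ref", "a", "b"),
                     experiment_id = "e1", slope = c(1.7, 0.85, 0.3))
  once <- normalize_to_reference(fits, "ref")
  again <- normalize_to_reference(
    data.frame(antibody_id = once$antibody_id,
               experiment_id = once$experiment_id,
               slope = once$normalized_value), "ref")
  expect_equal(again$normalized_value, once$normalized_value)
  # multiplying every tag measurement by c multiplies slopes by c and
  # leaves normalized values unchanged
  set.seed(7)
  x <- runif(20, 100, 2000)
  meas <- list(ref = data.frame(mean_ref = x,
                                mean_tag = 1.2 * x + 40 + rnorm(20)),
               a = data.frame(mean_ref = x,
                              mean_tag = 0.5 * x + 40 + rnorm(20)))
  fit_panel <- function(c_gain) {
    fits_c <- do.call(rbind, lapply(names(meas), function(id) {
      m <- meas[[id]]; m$mean_tag <- c_gain * m$mean_tag
      fit_efficiency(m, antibody_id = id, experiment_id = "e1")
    }))
    normalize_to_reference(fits_c, "ref")
  }
  base <- fit_panel(1); scaled <- fit_panel(3.7)
  expect_equal(scaled$slope, 3.7 * base$slope, tolerance = 1e-9)
  expect_equal(scaled$normalized_value, base$normalized_value,
               tolerance = 1e-9)
})

test_that("replicate aggregation reports mean and SEM across experiments", {
  s <- summarize_replicates(c(100, 100, 100))
  expect_equal(s$mean, 100); expect_equal(s$sem, 0); expect_equal(s$n, 3L)
  s2 <- summarize_replicates(c(90, 100, 110))
  expect_equal(s2$mean, 100)
  expect_equal(s2$sem, 10 / sqrt(3))
  expect_message(s1 <- summarize_replicates(42), "single experiment")
  expect_equal(s1$sem, 0)
  expect_error(summarize_replicates(numeric(0)), "insufficient data")
  # SEM respects scaling
  v <- c(55, 61, 48, 70)
  expect_equal(summarize_replicates(3 * v)$sem, 3 * summarize_replicates(v)$sem)
})

test_that("specificity requires at least twice the irrelevant-control signal", {
  r <- specificity_ratio(40, 10)
  expect_equal(r$ratio, 4); expect_true(r$is_specific)
  expect_false(specificity_ratio(15, 10)$is_specific)
  # boundary is inclusive
  expect_true(specificity_ratio(20, 10)$is_specific)
  # near-zero control is floored, with a warning, not an error
  expect_warning(rf <- specificity_ratio(10, 0.01), "below floor")
  expect_equal(rf$ratio, 10)
  expect_error(specificity_ratio(-5, 10), "non-negative")
})

test_that("classification reproduces the good / fair / mediocre / nonspecific scheme", {
  # high signal, specific even when 100-fold diluted
  expect_equal(classify_antibody(100, 90, TRUE, TRUE), "good")
  # high signal at 5000 ng/mL but loses specificity at 50 ng/mL
  expect_equal(classify_antibody(60, 1, TRUE, FALSE), "fair")
  # weak signal (< 25) even at high concentration
  expect_equal(classify_antibody(20, specific_high = TRUE), "mediocre")
  # fails the 2x-control floor entirely
  expect_equal(classify_antibody(10, specific_high = FALSE), "nonspecific")
  # low-concentration assay absent: conservative fair, flagged undetermined
  lab <- classify_antibody(80, NA, TRUE, NA)
  expect_equal(as.character(lab), "fair")
  expect_true(attr(lab, "undetermined"))
  expect_error(classify_antibody(-1, 0, TRUE, TRUE), "non-negative")
})

test_that("increasing the high-concentration signal never demotes the class", {
  rank_of <- function(label) tagquant:::class_rank(as.character(label))
  for (spec_high in c(TRUE, FALSE))
    for (spec_low in list(TRUE, FALSE, NA)) {
      values <- c(0, 10, 25, 40, 50, 50.01, 75, 150)
      ranks <- vapply(values, function(v)
        rank_of(classify_antibody(v, 50, spec_high, spec_low[[1]])), numeric(1))
      expect_true(all(diff(ranks) >= 0))
    }
})
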