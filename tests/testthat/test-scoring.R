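test_that("latency cleaning keeps boundary values and reconciles counts", {
  res <- clean_latencies(c(399, 400, 10000, 10001))
  expect_equal(res$kept, c(400, 10000))
  expect_identical(res$n_removed_low, 1L)
  expect_identical(res$n_removed_high, 1L)

  x <- c(450, 800, 9999)
  expect_equal(clean_latencies(x)$kept, x)

  # idempotence and order preservation
  once <- clean_latencies(c(100, 500, 20000, 700, 350))
  twice <- clean_latencies(once$kept)
  expect_equal(twice$kept, once$kept)
  expect_identical(twice$n_removed_low + twice$n_removed_high, 0L)
  expect_equal(once$kept, c(500, 700))

  expect_length(clean_latencies(numeric(0))$kept, 0L)
  expect_identical(length(once$kept) + once$n_removed_low + once$n_removed_high, 5L)

  # inclusive bounds drop the boundary values themselves
  incl <- clean_latencies(c(400, 500, 10000), cleaning_rules(exclusive_bounds = FALSE))
  expect_equal(incl$kept, 500)
  expect_error(cleaning_rules(lower_ms = 500, upper_ms = 400),
               class = "iat_config_error")
})

test_that("identical compatible and incompatible blocks give D = 0", {
  x <- c(500, 650, 720, 980)
  ses <- make_scored_session(x, x, x, x)
  d <- compute_d(ses)
  expect_equal(d$d_practice, 0)
  expect_equal(d$d_test, 0)
  expect_equal(d$d_overall, 0)
  expect_identical(d$category, "neutral")
})

test_that("a one-SD shift reproduces the hand-computed 4-trial example", {
  comp <- c(500, 600, 700, 800)        # mean 650, SD 129.0994449
  incomp <- comp + 129.0994449
  # pooled SD over the 8 values: sqrt((2*50000 + 8*(129.0994449/2)^2) / 7)
  # = 138.0131839, so D = 129.0994449 / 138.0131839 = 0.9354143
  ses <- make_scored_session(comp, comp, incomp, incomp,
                             compatible_blocks = c(3L, 4L))
  d <- compute_d(ses)
  expect_equal(d$d_practice, 0.9354143, tolerance = 1e-6)
  expect_equal(d$d_test, 0.9354143, tolerance = 1e-6)
  expect_equal(d$d_overall, 0.9354143, tolerance = 1e-6)
})

test_that("D is invariant to translation and positive scaling of all latencies", {
  withr::local_seed(101)
  for (i in 1:50) {
    ses <- random_scored_session(n = sample(4:20, 1), lo = 600, hi = 2200)
    d0 <- compute_d(ses)$d_overall
    k <- runif(1, 1.1, 3)
    c0 <- runif(1, 10, 1500)
    scale_ses <- ses; shift_ses <- ses
    for (b in paste0("block", c(3, 4, 6, 7))) {
      scale_ses$blocks[[b]]$latency_ms <- ses$blocks[[b]]$latency_ms * k
      shift_ses$blocks[[b]]$latency_ms <- ses$blocks[[b]]$latency_ms + c0
    }
    expect_equal(compute_d(scale_ses)$d_overall, d0, tolerance = 1e-10)
    expect_equal(compute_d(shift_ses)$d_overall, d0, tolerance = 1e-10)
  }
})

test_that("flipping the compatible orientation flips the sign of every D", {
  withr::local_seed(202)
  for (i in 1:25) {
    ses <- random_scored_session(n = 8)
    a <- compute_d(ses, config = scoring_config(orientation = "b34_compatible"))
    b <- compute_d(ses, config = scoring_config(orientation = "b67_compatible"))
    expect_equal(a$d_practice, -b$d_practice)
    expect_equal(a$d_test, -b$d_test)
    expect_equal(a$d_overall, -b$d_overall)
  }
})

test_that("compute_d matches the independent straight-line oracle", {
  withr::local_seed(303)
  for (i in 1:40) {
    compat <- if (i %% 2L) c(3L, 4L) else c(6L, 7L)
    ses <- random_scored_session(n = sample(4:10, 1), lo = 380, hi = 11000,
                                 compatible_blocks = compat)
    want <- oracle_d(ses)
    got <- compute_d(ses)
    expect_equal(got$d_practice, want$d_practice, tolerance = 1e-12)
    expect_equal(got$d_test, want$d_test, tolerance = 1e-12)
    expect_equal(got$d_overall, want$d_overall, tolerance = 1e-12)
  }
})

test_that("cleaning counts feed through compute_d and short blocks error", {
  ses <- make_scored_session(c(300, 500, 600, 12000), c(500, 600, 700, 800),
                             c(900, 950, 990, 1000), c(700, 720, 740, 760))
  d <- compute_d(ses)
  expect_identical(d$n_removed_low, 1L)
  expect_identical(d$n_removed_high, 1L)
  expect_identical(unname(d$n_kept), c(2L, 4L, 4L, 4L))

  bad <- make_scored_session(c(300, 350, 600, 12000), c(500, 600, 700, 800),
                             c(900, 950, 990, 1000), c(700, 720, 740, 760))
  err <- tryCatch(compute_d(bad), iat_undefined_score = function(e) e)
  expect_s3_class(err, "iat_undefined_score")
  expect_match(conditionMessage(err), "block3")
})

test_that("penalty variants replace error-trial latencies per block", {
  lat <- c(500, 600, 700, 800)
  errors <- list(block3 = c(TRUE, FALSE, FALSE, FALSE),
                 block4 = rep(FALSE, 4),
                 block6 = rep(FALSE, 4), block7 = rep(FALSE, 4))
  ses <- make_scored_session(lat, lat, lat + 200, lat + 200, errors = errors)
  base <- compute_d(ses)
  p600 <- compute_d(ses, config = scoring_config("penalty_mean_plus_600"))
  # in block 3 the error trial (500) becomes mean(600,700,800) + 600 = 1300
  lat3 <- c(1300, 600, 700, 800)
  expected_dp <- (mean(lat + 200) - mean(lat3)) / sd(c(lat3, lat + 200))
  expect_equal(p600$d_practice, expected_dp, tolerance = 1e-12)
  expect_equal(p600$d_test, base$d_test)  # no errors in the test pair
  p2sd <- compute_d(ses, config = scoring_config("penalty_mean_plus_2sd"))
  lat3b <- c(700 + 2 * 100, 600, 700, 800)
  expect_equal(p2sd$d_practice,
               (mean(lat + 200) - mean(lat3b)) / sd(c(lat3b, lat + 200)),
               tolerance = 1e-12)
})

test_that("D categories follow the thresholds and sign convention", {
  expect_identical(categorize_d(0), "neutral")
  expect_identical(categorize_d(0.14), "neutral")
  expect_identical(categorize_d(0.20), "slight preference for concept 1")
  expect_identical(categorize_d(-0.66), "strong preference for concept 2")
  expect_identical(categorize_d(0.5), "moderate preference for concept 1")
  expect_identical(categorize_d(-0.35, concept_names = c("thin", "fat")),
                   "moderate preference for fat")
  expect_error(categorize_d(0.2, thresholds = c(0.3, 0.2, 0.1)),
               class = "iat_config_error")
})
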