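test_that("profile validation rejects impossible rates", {
  expect_error(respondent_profile(latency_sigma = 0), class = "iat_config_error")
  expect_error(respondent_profile(error_rate = 1.2), class = "iat_config_error")
  expect_error(respondent_profile(bias_ms = Inf), class = "iat_config_error")
})

test_that("degenerate noise gives equal compatible and incompatible latencies", {
  withr::local_seed(1)
  p <- respondent_profile(bias_ms = 0, error_rate = 0, latency_sigma = 1e-12,
                          outlier_rate = 0, practice_ms = 0)
  a <- simulate_trial(p, compatible = TRUE)
  b <- simulate_trial(p, compatible = FALSE)
  expect_equal(a$latency_ms, b$latency_ms, tolerance = 1e-6)
  expect_true(a$initially_correct && b$initially_correct)

  task <- build_task(tiny_stimuli(), fast_config())
  ses <- simulate_session(p, task)
  lat <- trial_table(ses, blocks = c(3, 4, 6, 7))$latency_ms
  expect_lt(max(lat) - min(lat), 1e-6)
})

test_that("a fixed seed makes simulate_study fully reproducible", {
  d <- study_design(4, seed = 5)
  s1 <- simulate_study(d, config = fast_config(), seed = 99)
  s2 <- simulate_study(d, config = fast_config(), seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_study(d, config = fast_config(), seed = 100)
  expect_false(identical(s1, s3))
})

test_that("every participant takes each variant exactly once, in random order", {
  d <- study_design(20, seed = 3)
  expect_true(all(apply(d$orders, 1L, function(o) identical(sort(o), 1:4))))
  study <- simulate_study(d, config = fast_config(), seed = 3)
  expect_length(study, 80L)
  ss <- session_summary(study)
  tab <- table(ss$participant, ss$variant)
  expect_true(all(tab == 1L))
})

test_that("per-variant scored-trial volume matches the crossed design", {
  study <- simulate_study(study_design(6, seed = 1), seed = 2)
  tt <- trial_table(study, blocks = c(3, 4, 6, 7))
  expect_identical(unname(table(tt$variant)), rep(6L * 120L, 4L),
                   ignore_attr = TRUE)
  expect_identical(nrow(tt), 6L * 4L * 120L)
})

test_that("expected error count per session tracks the error rate", {
  withr::local_seed(7)
  p <- respondent_profile(error_rate = 0.035, outlier_rate = 0)
  task <- build_task(tiny_stimuli(), iat_config(seed = 1))
  errs <- vapply(1:40, function(i) session_errors(simulate_session(p, task)), 0L)
  # 188 trials at 0.035 -> 6.58 expected; check within 4 SEs
  se <- sqrt(188 * 0.035 * 0.965 / 40)
  expect_lt(abs(mean(errs) - 188 * 0.035), 4 * se)
})

test_that("bias sign drives the sign of the mean D score", {
  withr::local_seed(11)
  design <- study_design(30)
  for (beta in c(-200, 200)) {
    p <- respondent_profile(bias_ms = beta)
    study <- simulate_study(design, profile = p,
                            between = list(meanlog_sd = 0.2, bias_sd = 50,
                                           error_logit_sd = 0.4),
                            config = fast_config())
    md <- mean(session_summary(study)$d_overall)
    expect_identical(sign(md), sign(beta))
  }
  # beta = 0: mean D within Monte-Carlo error of zero
  p0 <- respondent_profile(bias_ms = 0)
  study0 <- simulate_study(study_design(50), profile = p0,
                           between = list(meanlog_sd = 0.2, bias_sd = 0,
                                          error_logit_sd = 0.4),
                           config = fast_config())
  d0 <- session_summary(study0)$d_overall
  expect_lt(abs(mean(d0)), 3 * sd(d0) / sqrt(length(d0)))
})

test_that("variant and order shifts move latencies but not D", {
  withr::local_seed(23)
  p <- respondent_profile(practice_ms = 120,
                          variant_ms = c(app.keyboard = 0, app.touch = 150,
                                         web.keyboard = 300, web.touch = 450))
  study <- simulate_study(study_design(40), profile = p, seed = 23)
  lat <- iat_describe(study, "latency", by = "variant", test = "none")
  expect_identical(lat$group[order(lat$mean)],
                   c("app.keyboard", "app.touch", "web.keyboard", "web.touch"))
  ord <- iat_describe(study, "latency", by = "order", test = "none")
  expect_identical(ord$group[order(ord$mean, decreasing = TRUE)],
                   paste0("test", 1:4))
  # D unaffected: variant test on D stays non-significant
  ht <- test_group_effect(study, "d_score", by = "variant", test = "kruskal_wallis")
  expect_gt(ht$p.value, 0.01)
})

test_that("the engine route and the direct simulator route agree statistically", {
  withr::local_seed(31)
  p <- respondent_profile(outlier_rate = 0)
  task <- build_task(tiny_stimuli(), iat_config(seed = 31))
  direct <- lapply(1:12, function(i) simulate_session(p, task))
  engine <- lapply(1:12, function(i) run_session(task, responder_profile(p)))
  d_direct <- vapply(direct, function(s) compute_d(s)$d_overall, 0)
  d_engine <- vapply(engine, function(s) compute_d(s)$d_overall, 0)
  # same latency model behind both: mean D within 3 combined SEs
  se <- sqrt(var(d_direct) / 12 + var(d_engine) / 12)
  expect_lt(abs(mean(d_direct) - mean(d_engine)), 3 * se)
  # engine route marks error trials exactly like the model draws them
  expect_true(all(vapply(engine, session_errors, 0L) >= 0L))
})
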