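#' Synthetic respondent profile
#'
#' Describes the latency-generating process of one simulated participant.
#' A trial's latency is a non-decision floor (`shift_ms`, reduced by
#' `practice_ms` for every test already taken) plus a log-normal decision
#' component, plus additive effects on the millisecond scale: the variant
#' shift of the app type / input method combination, an error-correction
#' cost when the initial classification was wrong, and the association
#' bias. The bias adds `abs(bias_ms)` to the *disfavoured* pairing —
#' incompatible blocks when `bias_ms > 0`, compatible blocks when
#' `bias_ms < 0` — so that positive `bias_ms` yields positive D scores
#' (preference for concept 1) while latencies always stay above the floor.
#' A small fraction of trials is replaced by outliers below 400 ms
#' (anticipations) or above 10,000 ms (distraction), which latency cleaning
#' is expected to remove.
#'
#' The defaults are calibrated so that a 51-participant crossed-design
#' study reproduces the order of magnitude of published app/web weight-IAT
#' comparisons: per-variant mean scored latencies around 850-1050 ms with
#' SDs around 500-620 ms, about 6-7 error trials per 188-trial session, and
#' moderate-to-strong D scores toward concept 2 (mean near -0.6).
#'
#' @param shift_ms non-decision floor in ms.
#' @param base_meanlog log-scale location of the log-normal decision
#'   component (log-ms).
#' @param latency_sigma log-scale SD of the decision component.
#' @param bias_ms association bias in ms; sign as described above.
#' @param error_rate per-trial probability of an initial misclassification.
#' @param error_extra_ms added latency when a forced correction occurs.
#' @param practice_ms latency reduction per unit of test order.
#' @param variant_ms named additive shifts for the four
#'   `"<app_type>.<input_method>"` combinations.
#' @param outlier_rate per-trial probability of an outlier latency.
#' @param outlier_fast_prob probability that an outlier is fast (sub-400
#'   ms) rather than slow.
#' @param outlier_fast_range,outlier_slow_range uniform ranges (ms) for the
#'   two outlier kinds.
#' @return An object of class `iat_profile`.
#' @export
respondent_profile <- function(shift_ms = 550,
                               base_meanlog = log(230) - 1.39^2 / 2,
                               latency_sigma = 1.39,
                               bias_ms = -240,
                               error_rate = 0.030,
                               error_extra_ms = 400,
                               practice_ms = 50,
                               variant_ms = c(app.keyboard = 0, app.touch = 10,
                                              web.keyboard = 53, web.touch = 146),
                               outlier_rate = 0.01,
                               outlier_fast_prob = 0.9,
                               outlier_fast_range = c(150, 399),
                               outlier_slow_range = c(10001, 14000)) {
  if (!(latency_sigma > 0)) stop_config("latency_sigma must be positive")
  if (!(error_rate >= 0 && error_rate < 1)) stop_config("error_rate must be in [0, 1)")
  if (!(outlier_rate >= 0 && outlier_rate < 1)) stop_config("outlier_rate must be in [0, 1)")
  vals <- c(shift_ms, base_meanlog, bias_ms, error_extra_ms, practice_ms, variant_ms)
  if (anyNA(vals) || any(!is.finite(vals))) stop_config("all profile rates must be finite")
  structure(
    list(shift_ms = shift_ms, base_meanlog = base_meanlog,
         latency_sigma = latency_sigma, bias_ms = bias_ms,
         error_rate = error_rate, error_extra_ms = error_extra_ms,
         practice_ms = practice_ms, variant_ms = variant_ms,
         outlier_rate = outlier_rate, outlier_fast_prob = outlier_fast_prob,
         outlier_fast_range = outlier_fast_range,
         outlier_slow_range = outlier_slow_range),
    class = "iat_profile"
  )
}

variant_key <- function(app_type, input_method) paste(app_type, input_method, sep = ".")

# vectorized latency model shared by simulate_trial() and simulate_session();
# `compatible` is logical (NA for sorting blocks, where no bias applies)
simulate_latencies <- function(n, profile, compatible, order_index, variant) {
  shift <- pmax(1, profile$shift_ms - profile$practice_ms * (order_index - 1L))
  lat <- shift + rlnorm(n, profile$base_meanlog, profile$latency_sigma)
  dv <- unname(profile$variant_ms[variant])
  if (!is.na(dv)) lat <- lat + dv
  b <- profile$bias_ms
  if (b != 0) {
    slower <- if (b > 0) compatible %in% FALSE else compatible %in% TRUE
    lat[slower] <- lat[slower] + abs(b)
  }
  err <- runif(n) < profile$error_rate
  lat[err] <- lat[err] + profile$error_extra_ms
  if (profile$outlier_rate > 0) {
    out <- runif(n) < profile$outlier_rate
    if (any(out)) {
      k <- sum(out)
      fast <- runif(k) < profile$outlier_fast_prob
      repl <- numeric(k)
      repl[fast] <- runif(sum(fast), profile$outlier_fast_range[1L],
                          profile$outlier_fast_range[2L])
      repl[!fast] <- runif(sum(!fast), profile$outlier_slow_range[1L],
                           profile$outlier_slow_range[2L])
      lat[out] <- repl
    }
  }
  list(latency_ms = lat, initially_correct = !err)
}

#' Simulate one trial's latency and correctness
#'
#' Draws a single trial from the profile's latency model. Uses the current
#' RNG stream.
#'
#' @param profile an [respondent_profile()].
#' @param compatible `TRUE`/`FALSE` for a pairing-block trial, `NA` for a
#'   sorting-block trial (no bias applies).
#' @param order_index position of the test in the participant's sequence.
#' @param variant variant key `"<app_type>.<input_method>"`.
#' @return A list with `latency_ms` and `initially_correct`.
#' @export
simulate_trial <- function(profile, compatible = NA, order_index = 1L,
                           variant = "app.keyboard") {
  stopifnot(inherits(profile, "iat_profile"))
  res <- simulate_latencies(1L, profile, compatible, order_index, variant)
  list(latency_ms = res$latency_ms, initially_correct = res$initially_correct)
}

#' Simulate a full session for one synthetic respondent
#'
#' Builds block results for a task directly from the profile's latency
#' model (vectorized per block); the result has exactly the structure
#' [run_session()] produces and can be scored, serialized and analyzed the
#' same way.
#'
#' @param profile an [respondent_profile()].
#' @param task an [`iat_task`][build_task].
#' @inheritParams run_session
#' @return An `iat_session`.
#' @export
simulate_session <- function(profile, task,
                             participant_id = "sim",
                             app_type = c("app", "web"),
                             input_method = c("keyboard", "touch"),
                             order_index = 1L) {
  stopifnot(inherits(profile, "iat_profile"), inherits(task, "iat_task"))
  app_type <- match.arg(app_type)
  input_method <- match.arg(input_method)
  vkey <- variant_key(app_type, input_method)
  compat_set <- compatible_block_set(task$sides)
  blocks <- list()
  for (step in task$steps) {
    if (step$type != "block") next
    b <- step$block_index
    trials <- step$trials
    compatible <- if (b %in% c(3L, 4L, 6L, 7L)) rep(b %in% compat_set, nrow(trials)) else rep(NA, nrow(trials))
    draw <- simulate_latencies(nrow(trials), profile, compatible, order_index, vkey)
    blocks[[paste0("block", b)]] <- make_block_result(
      trials, draw$latency_ms, draw$initially_correct,
      pairing_string(step$labels), b)
  }
  new_session(task, blocks, participant_id, app_type, input_method,
              as.integer(order_index), complete = TRUE)
}

#' Responder drawing from a respondent profile
#'
#' Adapter that lets the event-level session engine administer a task to a
#' synthetic respondent: each trial's latency and initial correctness are
#' drawn from the same model as [simulate_session()], and rendered as a
#' response-event sequence (a wrong-side event before the correct one when
#' the initial classification fails).
#'
#' @inheritParams simulate_trial
#' @return An [`iat_responder`][responders].
#' @export
responder_profile <- function(profile, order_index = 1L, variant = "app.keyboard") {
  stopifnot(inherits(profile, "iat_profile"))
  new_responder(function(trial, context) {
    draw <- simulate_latencies(1L, profile, context$compatible, order_index, variant)
    lat <- draw$latency_ms
    if (draw$initially_correct) {
      data.frame(side = trial$correct_side, elapsed_ms = lat)
    } else {
      wrong <- setdiff(c("left", "right"), trial$correct_side)
      data.frame(side = c(wrong, trial$correct_side),
                 elapsed_ms = c(max(lat / 2, 1), lat))
    }
  })
}

#' Crossed study design: four test variants in randomized order
#'
#' Each participant takes all four combinations of app type (native app
#' vs. web) and input method (keyboard vs. touch screen) exactly once, in
#' an independently randomized order.
#'
#' @param n_participants number of participants (default 51).
#' @param seed optional seed for the order randomization.
#' @return An object of class `iat_study_design`: the variant table
#'   (`variants`) and an `n_participants` x 4 matrix `orders`, row `i`
#'   giving the variant index taken at each position by participant `i`.
#' @export
study_design <- function(n_participants = 51L, seed = NULL) {
  n_participants <- as.integer(n_participants)
  stopifnot(n_participants >= 1L)
  variants <- data.frame(
    app_type = c("app", "app", "web", "web"),
    input_method = c("keyboard", "touch", "keyboard", "touch"),
    stringsAsFactors = FALSE
  )
  orders <- with_seed_or_current(seed,
    t(vapply(seq_len(n_participants), function(i) sample.int(4L), integer(4L))))
  structure(list(n_participants = n_participants, variants = variants,
                 orders = orders, seed = seed),
            class = "iat_study_design")
}

#' Simulate a complete crossed-design study
#'
#' Generates `n_participants` x 4 sessions: every participant receives each
#' of the four app-type / input-method variants once, in the randomized
#' order of the design. Each participant gets individual random effects —
#' a base-speed offset on the log scale and a bias offset in ms — shared
#' across their four sessions; each session gets a freshly randomized task
#' (stimulus shuffles and concept-side assignment).
#'
#' @param design an [study_design()].
#' @param profile population-level [respondent_profile()].
#' @param between list of between-participant SDs: `meanlog_sd` for the
#'   base-speed offset (log scale), `bias_sd` (ms) for the bias offset, and
#'   `error_logit_sd` for the error-rate offset on the logit scale
#'   (error-count dispersion across participants is far above binomial in
#'   observed data).
#' @param stimuli an [iat_stimuli] object.
#' @param config an [iat_config()]; its `seed` is ignored here — the
#'   study-level `seed` governs all randomization.
#' @param seed optional study seed.
#' @return A list of `iat_session` objects (class `iat_study`), in
#'   participant-major, order-of-administration order.
#' @examples
#' study <- simulate_study(study_design(6), seed = 1)
#' length(study)
#' @export
simulate_study <- function(design = study_design(),
                           profile = respondent_profile(),
                           between = list(meanlog_sd = 0.25, bias_sd = 130,
                                          error_logit_sd = 0.6),
                           stimuli = example_stimuli(),
                           config = iat_config(),
                           seed = NULL) {
  stopifnot(inherits(design, "iat_study_design"), inherits(profile, "iat_profile"))
  config$seed <- NULL
  with_seed_or_current(seed, {
    sessions <- vector("list", design$n_participants * 4L)
    k <- 0L
    for (i in seq_len(design$n_participants)) {
      pid <- sprintf("P%03d", i)
      p_i <- profile
      p_i$base_meanlog <- profile$base_meanlog + rnorm(1L, 0, between$meanlog_sd)
      p_i$bias_ms <- profile$bias_ms + rnorm(1L, 0, between$bias_sd)
      if (profile$error_rate > 0 && (between$error_logit_sd %||% 0) > 0)
        p_i$error_rate <- stats::plogis(stats::qlogis(profile$error_rate) +
                                          rnorm(1L, 0, between$error_logit_sd))
      for (pos in 1:4) {
        v <- design$orders[i, pos]
        task <- build_task(stimuli, config)
        k <- k + 1L
        sessions[[k]] <- simulate_session(
          p_i, task, participant_id = pid,
          app_type = design$variants$app_type[v],
          input_method = design$variants$input_method[v],
          order_index = pos)
      }
    }
    structure(sessions, class = c("iat_study", "list"))
  })
}
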