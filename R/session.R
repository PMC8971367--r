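#' Responder objects for administering a task
#'
#' The session engine is headless: responses come from a *responder*, an
#' object with a `respond(trial, context)` method returning the response
#' events of one trial, and an `acknowledge(step)` method called for
#' instruction/overview/completion steps. Events are a data frame with
#' columns `side` (`"left"`/`"right"`) and `elapsed_ms` (strictly increasing
#' milliseconds since stimulus onset); the engine consumes them until the
#' first correct-side event, exactly as the touch-screen app accepts taps
#' until the stimulus is classified correctly.
#'
#' `responder_fixed()` answers correctly after a fixed latency, optionally
#' preceded by a wrong-side event (one forced correction) with probability
#' `error_rate`. `responder_replay()` replays a recorded event log, as
#' produced by `run_session(..., record_events = TRUE)`.
#'
#' @param latency_ms latency of the correct response in milliseconds.
#' @param error_rate probability that a wrong-side event precedes the
#'   correct one.
#' @param error_lead_ms how many milliseconds before the correct response
#'   the wrong event occurs.
#' @param events event log: a data frame with columns `trial` (global trial
#'   counter in task order), `side` and `elapsed_ms`.
#' @return An object of class `iat_responder`.
#' @name responders
NULL

new_responder <- function(respond, acknowledge = function(step) invisible(NULL)) {
  structure(list(respond = respond, acknowledge = acknowledge),
            class = "iat_responder")
}

#' @rdname responders
#' @export
responder_fixed <- function(latency_ms = 600, error_rate = 0, error_lead_ms = 300) {
  stopifnot(latency_ms > 0, error_rate >= 0, error_rate < 1,
            error_lead_ms > 0, error_lead_ms < latency_ms)
  new_responder(function(trial, context) {
    wrong <- error_rate > 0 && runif(1L) < error_rate
    if (wrong) {
      data.frame(side = c(setdiff(c("left", "right"), trial$correct_side), trial$correct_side),
                 elapsed_ms = c(latency_ms - error_lead_ms, latency_ms))
    } else {
      data.frame(side = trial$correct_side, elapsed_ms = latency_ms)
    }
  })
}

#' @rdname responders
#' @export
responder_replay <- function(events) {
  events <- as.data.frame(events)
  need <- c("trial", "side", "elapsed_ms")
  if (!all(need %in% names(events)))
    stop_validation("replay events need columns 'trial', 'side', 'elapsed_ms'")
  counter <- 0L
  new_responder(function(trial, context) {
    counter <<- counter + 1L
    ev <- events[events$trial == counter, c("side", "elapsed_ms"), drop = FALSE]
    if (nrow(ev) == 0L)
      stop_iat(sprintf("replay log has no events for trial %d", counter),
               "iat_trial_abort")
    ev
  })
}

#' Administer a single trial
#'
#' Implements the trial lifecycle: events are accepted until the first one
#' on the correct side; every preceding wrong-side event marks the trial as
#' initially incorrect (the on-screen error indicator forces
#' reclassification); input stops at the correct event. The recorded
#' latency is the time from stimulus onset to that first correct response.
#'
#' @param trial one trial of a block step (a list or one-row data frame with
#'   `stimulus`, `kind`, `correct_side`).
#' @param events data frame of response events (`side`, `elapsed_ms`).
#' @return A list with `latency_ms`, `initially_correct`, and `n_events`
#'   (events consumed, including the correct one).
#' @examples
#' trial <- list(stimulus = "joy", kind = "attribute", correct_side = "left")
#' run_trial(trial, data.frame(side = c("right", "left"), elapsed_ms = c(400, 900)))
#' @export
run_trial <- function(trial, events) {
  events <- as.data.frame(events)
  if (nrow(events) == 0L)
    stop_iat("responder produced no events for a trial", "iat_trial_abort")
  if (!all(events$side %in% c("left", "right")))
    stop_validation("event sides must be 'left' or 'right'")
  el <- as.numeric(events$elapsed_ms)
  if (anyNA(el) || any(el <= 0) || any(diff(el) <= 0))
    stop_validation("event times must be positive and strictly increasing within a trial")
  hit <- match(trial$correct_side, events$side)
  if (is.na(hit))
    stop_iat("responder never gave the correct response for a trial", "iat_trial_abort")
  list(latency_ms = el[hit],
       initially_correct = hit == 1L,
       n_events = hit)
}

#' Administer a full task and collect a session result
#'
#' Walks the ordered steps of a task: instruction, overview and completion
#' steps consume a responder acknowledgment and produce no trial results;
#' each block step runs its trials in order through [run_trial()]. The
#' result carries participant and test-variant metadata, the side
#' assignment, which pairing blocks were the *compatible* arrangement
#' (concept 1 sharing a side with the positive attribute), and one result
#' row per trial.
#'
#' If the responder fails to produce a correct response for some trial the
#' session aborts: an error of class `iat_session_abort` is signalled whose
#' `partial` field holds the session collected so far, flagged
#' `complete = FALSE`.
#'
#' @param task an [`iat_task`][build_task].
#' @param responder an [`iat_responder`][responders].
#' @param participant_id participant identifier (metadata).
#' @param app_type `"app"` (native) or `"web"` (metadata only).
#' @param input_method `"keyboard"` or `"touch"` (metadata only).
#' @param order_index position of this test in the participant's sequence
#'   (1-4 in the four-variant crossed design).
#' @param record_events if `TRUE`, attach the full tap-level event log as
#'   attribute `"events"` (usable with [responder_replay()]).
#' @return An object of class `iat_session`; see [session_blocks()],
#'   [session_errors()], [compute_d()].
#' @examples
#' task <- build_task(example_stimuli(), iat_config(seed = 1))
#' ses <- run_session(task, responder_fixed(650), participant_id = "P01")
#' ses
#' @export
run_session <- function(task, responder,
                        participant_id = "anonymous",
                        app_type = c("app", "web"),
                        input_method = c("keyboard", "touch"),
                        order_index = 1L,
                        record_events = FALSE) {
  stopifnot(inherits(task, "iat_task"))
  if (!inherits(responder, "iat_responder"))
    stop_validation("responder must be an 'iat_responder' (see ?responders)")
  app_type <- match.arg(app_type)
  input_method <- match.arg(input_method)
  order_index <- as.integer(order_index)
  stopifnot(order_index >= 1L)

  compatible <- compatible_block_set(task$sides)
  blocks <- list()
  log <- if (record_events) list() else NULL
  global_trial <- 0L

  abort_with_partial <- function(msg) {
    partial <- new_session(task, blocks, participant_id, app_type, input_method,
                           order_index, complete = FALSE)
    stop(errorCondition(paste0(msg, " — session aborted, partial results attached"),
                        partial = partial,
                        class = c("iat_session_abort", "iat_error", "error", "condition")))
  }

  for (step in task$steps) {
    if (step$type != "block") {
      responder$acknowledge(step)
      next
    }
    b <- step$block_index
    trials <- step$trials
    n <- nrow(trials)
    lat <- numeric(n); init_ok <- logical(n)
    pairing <- pairing_string(step$labels)
    for (i in seq_len(n)) {
      trial <- as.list(trials[i, , drop = FALSE])
      global_trial <- global_trial + 1L
      context <- list(block_index = b,
                      compatible = if (b %in% c(3L, 4L, 6L, 7L)) b %in% compatible else NA,
                      labels = step$labels)
      res <- tryCatch({
        events <- responder$respond(trial, context)
        run_trial(trial, events)
      }, iat_trial_abort = function(e) e)
      if (inherits(res, "condition")) {
        blocks[[paste0("block", b)]] <- make_block_result(trials[seq_len(i - 1L), , drop = FALSE],
                                                          lat[seq_len(i - 1L)],
                                                          init_ok[seq_len(i - 1L)], pairing, b)
        abort_with_partial(sprintf("block %d, trial %d: %s", b, i, conditionMessage(res)))
      }
      lat[i] <- res$latency_ms
      init_ok[i] <- res$initially_correct
      if (record_events)
        log[[global_trial]] <- data.frame(trial = global_trial,
                                          side = events$side,
                                          elapsed_ms = events$elapsed_ms)
    }
    blocks[[paste0("block", b)]] <- make_block_result(trials, lat, init_ok, pairing, b)
  }
  ses <- new_session(task, blocks, participant_id, app_type, input_method,
                     order_index, complete = TRUE)
  if (record_events) attr(ses, "events") <- do.call(rbind, log)
  ses
}

pairing_string <- function(labels) {
  sprintf("left: %s | right: %s",
          paste(labels$left, collapse = " or "),
          paste(labels$right, collapse = " or "))
}

make_block_result <- function(trials, latency_ms, initially_correct, pairing, block_index) {
  n <- nrow(trials)
  data.frame(
    stimulus = trials$stimulus,
    kind = trials$kind,
    cat = trials$cat,
    trial_code = paste(trials$correct_side, trials$kind, sep = "-"),
    pairing = rep(pairing, n),
    latency_ms = latency_ms,
    initially_correct = initially_correct,
    stringsAsFactors = FALSE
  )
}

# pairing blocks in which concept 1 shares a side with the first (positive)
# attribute: blocks 3 and 4 when the blocks 1-4 assignment puts them on the
# same side, otherwise blocks 6 and 7 (after the concept-side swap)
compatible_block_set <- function(sides) {
  if (sides$attribute_left == sides$concept_left) c(3L, 4L) else c(6L, 7L)
}

new_session <- function(task, blocks, participant_id, app_type, input_method,
                        order_index, complete) {
  structure(
    list(
      participant_id = as.character(participant_id),
      app_type = app_type,
      input_method = input_method,
      order_index = order_index,
      task_seed = task$seed,
      sides = task$sides,
      compatible_blocks = compatible_block_set(task$sides),
      complete = complete,
      blocks = blocks
    ),
    class = "iat_session"
  )
}

#' Access the per-block results of a session
#'
#' @param session an `iat_session`.
#' @param which block indices to return (default all present).
#' @return Named list of per-block result data frames.
#' @export
session_blocks <- function(session, which = NULL) {
  stopifnot(inherits(session, "iat_session"))
  b <- session$blocks
  if (!is.null(which)) b <- b[intersect(paste0("block", which), names(b))]
  b
}

#' Number of error trials in a session
#'
#' A trial counts as one error when its initial classification was wrong,
#' regardless of how many wrong-side events occurred before the forced
#' correction succeeded.
#'
#' @param session an `iat_session`.
#' @param blocks block indices to count over (default all seven).
#' @return Integer error count.
#' @export
session_errors <- function(session, blocks = 1:7) {
  bl <- session_blocks(session, blocks)
  sum(vapply(bl, function(b) sum(!b$initially_correct), 0L))
}

#' @export
print.iat_session <- function(x, ...) {
  n <- vapply(x$blocks, nrow, 0L)
  cat(sprintf("IAT session '%s' (%s, %s input, test %d)%s\n",
              x$participant_id, x$app_type, x$input_method, x$order_index,
              if (x$complete) "" else " [INCOMPLETE]"))
  cat("  trials per block:", paste(n, collapse = ", "),
      sprintf(" (errors: %d)\n", session_errors(x, seq_along(x$blocks))))
  cat("  compatible pairing in blocks:", paste(x$compatible_blocks, collapse = ", "), "\n")
  invisible(x)
}
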