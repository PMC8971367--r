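#' Latency cleaning rules
#'
#' Before any D-score or latency analysis, implausibly fast or slow trials
#' are discarded: by default, latencies strictly below 400 ms (anticipatory
#' or accidental responses) and strictly above 10,000 ms (distraction) are
#' removed; the boundary values themselves are kept.
#'
#' @param lower_ms lower bound in milliseconds (default 400).
#' @param upper_ms upper bound in milliseconds (default 10000).
#' @param exclusive_bounds if `TRUE` (default) remove strictly
#'   below/above the bounds; if `FALSE` the bounds themselves are removed
#'   too.
#' @return An object of class `iat_cleaning_rules`.
#' @export
cleaning_rules <- function(lower_ms = 400, upper_ms = 10000, exclusive_bounds = TRUE) {
  if (!(lower_ms > 0 && upper_ms > lower_ms))
    stop_config("cleaning bounds must satisfy 0 < lower_ms < upper_ms")
  structure(list(lower_ms = lower_ms, upper_ms = upper_ms,
                 exclusive_bounds = isTRUE(exclusive_bounds)),
            class = "iat_cleaning_rules")
}

#' Remove implausibly fast or slow latencies
#'
#' @param latencies numeric vector of positive latencies in milliseconds.
#' @param rules an [cleaning_rules()] object.
#' @return A list with `kept` (order-preserving), `n_removed_low` and
#'   `n_removed_high`.
#' @examples
#' clean_latencies(c(399, 400, 10000, 10001), cleaning_rules())
#' @export
clean_latencies <- function(latencies, rules = cleaning_rules()) {
  stopifnot(inherits(rules, "iat_cleaning_rules"))
  latencies <- as.numeric(latencies)
  if (anyNA(latencies) || any(latencies <= 0))
    stop_validation("latencies must be positive and non-missing")
  if (rules$exclusive_bounds) {
    low <- latencies < rules$lower_ms
    high <- latencies > rules$upper_ms
  } else {
    low <- latencies <= rules$lower_ms
    high <- latencies >= rules$upper_ms
  }
  list(kept = latencies[!(low | high)],
       n_removed_low = sum(low),
       n_removed_high = sum(high))
}

#' D-score computation settings
#'
#' The default `builtin_correction` variant scores each trial by its full
#' latency up to the eventual correct response, with no added penalty —
#' matching an engine that forces reclassification after errors. The
#' penalty variants instead replace error-trial latencies, per block, by
#' the mean of that block's correct trials plus 600 ms, or plus twice the
#' block SD, covering the other members of the conventional D-algorithm
#' family.
#'
#' @param algorithm_variant `"builtin_correction"` (default),
#'   `"penalty_mean_plus_600"` or `"penalty_mean_plus_2sd"`.
#' @param category_thresholds three strictly increasing positive breakpoints
#'   separating neutral / slight / moderate / strong preference (defaults
#'   0.15, 0.35, 0.65, the conventional feedback breakpoints).
#' @param orientation `"auto"` (default; use the compatible-block set the
#'   session records), `"b34_compatible"` or `"b67_compatible"` to force
#'   which pairing counts as compatible.
#' @return An object of class `iat_scoring_config`.
#' @export
scoring_config <- function(algorithm_variant = c("builtin_correction",
                                                 "penalty_mean_plus_600",
                                                 "penalty_mean_plus_2sd"),
                           category_thresholds = c(0.15, 0.35, 0.65),
                           orientation = c("auto", "b34_compatible", "b67_compatible")) {
  algorithm_variant <- match.arg(algorithm_variant)
  orientation <- match.arg(orientation)
  t <- as.numeric(category_thresholds)
  if (length(t) != 3L || anyNA(t) || any(t <= 0) || any(diff(t) <= 0))
    stop_config("category_thresholds must be three strictly increasing positive values")
  structure(list(algorithm_variant = algorithm_variant,
                 category_thresholds = t,
                 orientation = orientation),
            class = "iat_scoring_config")
}

block_scoring_latencies <- function(block, rules, variant) {
  lat <- block$latency_ms
  if (variant != "builtin_correction" && any(!block$initially_correct)) {
    correct <- lat[block$initially_correct]
    if (length(correct) >= 2L) {
      penalty <- if (variant == "penalty_mean_plus_600")
        mean(correct) + 600 else mean(correct) + 2 * sd(correct)
      lat[!block$initially_correct] <- penalty
    }
  }
  clean_latencies(lat, rules)
}

d_pair <- function(comp, incomp) {
  sd_pool <- sd(c(comp, incomp))
  if (!is.finite(sd_pool) || sd_pool == 0) return(0)
  (mean(incomp) - mean(comp)) / sd_pool
}

#' Compute the differential (D) score of a session
#'
#' The D score standardizes the latency cost of the incompatible pairing:
#' for the practice pair (blocks 3 and 6) and the test pair (blocks 4
#' and 7) separately, `D = (M_incompatible - M_compatible) / SD_pool`,
#' where the means are over the cleaned latencies of each block and
#' `SD_pool` is the standard deviation of the two blocks' cleaned latencies
#' combined; the overall D is the mean of the two pair scores. Positive D
#' means faster responding when concept 1 shares a side with the positive
#' attribute, i.e. an implicit preference for concept 1.
#'
#' @param session an [`iat_session`][run_session] containing blocks 3, 4, 6
#'   and 7.
#' @param rules latency [cleaning_rules()].
#' @param config a [scoring_config()].
#' @return An object of class `iat_dscore`: a list with `d_practice`,
#'   `d_test`, `d_overall`, the removal counts `n_removed_low` /
#'   `n_removed_high`, per-block kept-trial counts `n_kept`, and the
#'   qualitative `category` label (see [categorize_d()]).
#' @examples
#' task <- build_task(example_stimuli(), iat_config(seed = 9))
#' ses <- run_session(task, responder_fixed(700, error_rate = 0.05))
#' compute_d(ses)
#' @export
compute_d <- function(session, rules = cleaning_rules(), config = scoring_config()) {
  stopifnot(inherits(session, "iat_session"))
  stopifnot(inherits(config, "iat_scoring_config"))
  need <- paste0("block", c(3L, 4L, 6L, 7L))
  missing <- setdiff(need, names(session$blocks))
  if (length(missing))
    stop_validation(paste0("session lacks scored block(s): ", paste(missing, collapse = ", ")))

  compat <- switch(config$orientation,
                   auto = session$compatible_blocks,
                   b34_compatible = c(3L, 4L),
                   b67_compatible = c(6L, 7L))
  if (is.null(compat) || !length(compat))
    stop_validation("session does not record its compatible blocks; set orientation explicitly")
  incompat <- setdiff(c(3L, 4L, 6L, 7L), compat)

  cleaned <- lapply(setNames(c(3L, 4L, 6L, 7L), need), function(b) {
    block_scoring_latencies(session$blocks[[paste0("block", b)]], rules,
                            config$algorithm_variant)
  })
  n_kept <- vapply(cleaned, function(x) length(x$kept), 0L)
  short <- names(n_kept)[n_kept < 2L]
  if (length(short))
    stop_iat(paste0("undefined D score: fewer than 2 cleaned trials in ",
                    paste(short, collapse = ", ")),
             "iat_undefined_score",
             n_kept = n_kept)

  kept <- lapply(cleaned, `[[`, "kept")
  # practice pair = blocks 3 & 6, test pair = blocks 4 & 7
  pair_d <- function(practice) {
    idx <- if (practice) c(3L, 6L) else c(4L, 7L)
    cb <- intersect(idx, compat); ib <- intersect(idx, incompat)
    d_pair(kept[[paste0("block", cb)]], kept[[paste0("block", ib)]])
  }
  d_practice <- pair_d(TRUE)
  d_test <- pair_d(FALSE)
  d_overall <- mean(c(d_practice, d_test))

  structure(
    list(
      d_practice = d_practice,
      d_test = d_test,
      d_overall = d_overall,
      n_removed_low = sum(vapply(cleaned, `[[`, 0L, "n_removed_low")),
      n_removed_high = sum(vapply(cleaned, `[[`, 0L, "n_removed_high")),
      n_kept = n_kept,
      compatible_blocks = compat,
      algorithm_variant = config$algorithm_variant,
      category = categorize_d(d_overall, config$category_thresholds,
                              concept_names = NULL)
    ),
    class = "iat_dscore"
  )
}

#' Qualitative label for a D score
#'
#' Maps a D value to neutral / slight / moderate / strong preference using
#' three breakpoints on its absolute value; the sign selects which concept
#' is preferred (positive toward concept 1).
#'
#' @param d numeric D score(s).
#' @param thresholds three increasing positive breakpoints
#'   (default 0.15, 0.35, 0.65).
#' @param concept_names optional two concept names used in the label;
#'   `NULL` uses `"concept 1"`/`"concept 2"`.
#' @return Character label(s).
#' @examples
#' categorize_d(c(0, 0.2, -0.66))
#' @export
categorize_d <- function(d, thresholds = c(0.15, 0.35, 0.65), concept_names = NULL) {
  t <- as.numeric(thresholds)
  if (length(t) != 3L || any(t <= 0) || any(diff(t) <= 0))
    stop_config("thresholds must be three strictly increasing positive values")
  if (is.null(concept_names)) concept_names <- c("concept 1", "concept 2")
  vapply(as.numeric(d), function(di) {
    a <- abs(di)
    if (a < t[1L]) return("neutral")
    strength <- if (a < t[2L]) "slight" else if (a < t[3L]) "moderate" else "strong"
    toward <- if (di > 0) concept_names[1L] else concept_names[2L]
    sprintf("%s preference for %s", strength, toward)
  }, character(1L))
}

#' @export
print.iat_dscore <- function(x, ...) {
  cat(sprintf("IAT D score (%s)\n", x$algorithm_variant))
  cat(sprintf("  practice (B3/B6): %+.3f   test (B4/B7): %+.3f\n",
              x$d_practice, x$d_test))
  cat(sprintf("  overall: %+.3f  -> %s\n", x$d_overall, x$category))
  cat(sprintf("  cleaned out: %d too fast, %d too slow (kept %s)\n",
              x$n_removed_low, x$n_removed_high,
              paste(x$n_kept, collapse = "/")))
  invisible(x)
}
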