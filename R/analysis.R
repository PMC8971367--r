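variant_label <- function(session) variant_key(session$app_type, session$input_method)

as_session_list <- function(sessions) {
  if (inherits(sessions, "iat_session")) return(list(sessions))
  if (!is.list(sessions) || !all(vapply(sessions, inherits, TRUE, "iat_session")))
    stop_validation("sessions must be an iat_session or a list of them")
  sessions
}

#' Long-format trial table for a set of sessions
#'
#' One row per trial, in session and task order, carrying the participant,
#' variant and order metadata alongside the trial record. This is the
#' interchange shape used by the CSV exporter and by the latency analyses.
#'
#' @param sessions an `iat_session` or list of them.
#' @param blocks block indices to include (default all seven).
#' @param rules optional [cleaning_rules()]; when supplied, rows whose
#'   latency fails the rules are dropped.
#' @return A data frame with columns `participant`, `app_type`,
#'   `input_method`, `variant`, `order_index`, `block`, `trial_index`,
#'   `stimulus`, `stimulus_kind`, `compatible`, `latency_ms`,
#'   `initially_correct`, `trial_code`, `pairing`.
#' @export
trial_table <- function(sessions, blocks = 1:7, rules = NULL) {
  sessions <- as_session_list(sessions)
  rows <- lapply(sessions, function(s) {
    bl <- session_blocks(s, blocks)
    per_block <- lapply(names(bl), function(nm) {
      b <- as.integer(sub("block", "", nm))
      df <- bl[[nm]]
      if (nrow(df) == 0L) return(NULL)
      data.frame(
        participant = s$participant_id,
        app_type = s$app_type,
        input_method = s$input_method,
        variant = variant_label(s),
        order_index = s$order_index,
        block = b,
        trial_index = seq_len(nrow(df)),
        stimulus = df$stimulus,
        stimulus_kind = df$kind,
        compatible = if (b %in% c(3L, 4L, 6L, 7L)) b %in% s$compatible_blocks else NA,
        latency_ms = df$latency_ms,
        initially_correct = df$initially_correct,
        trial_code = df$trial_code,
        pairing = df$pairing,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_block)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- trial_table_prototype()
  if (!is.null(rules)) {
    stopifnot(inherits(rules, "iat_cleaning_rules"))
    keep <- if (rules$exclusive_bounds)
      out$latency_ms >= rules$lower_ms & out$latency_ms <= rules$upper_ms
    else
      out$latency_ms > rules$lower_ms & out$latency_ms < rules$upper_ms
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

trial_table_prototype <- function() {
  data.frame(participant = character(), app_type = character(),
             input_method = character(), variant = character(),
             order_index = integer(), block = integer(),
             trial_index = integer(), stimulus = character(),
             stimulus_kind = character(), compatible = logical(),
             latency_ms = numeric(), initially_correct = logical(),
             trial_code = character(), pairing = character(),
             stringsAsFactors = FALSE)
}

#' Per-session summary of scores and errors
#'
#' @param sessions an `iat_session` or list of them.
#' @param rules latency [cleaning_rules()] for the D computation.
#' @param config a [scoring_config()].
#' @return A data frame with one row per session: metadata, `d_practice`,
#'   `d_test`, `d_overall`, `category`, `n_errors` (over all blocks) and
#'   the cleaning removal counts.
#' @export
session_summary <- function(sessions, rules = cleaning_rules(),
                            config = scoring_config()) {
  sessions <- as_session_list(sessions)
  rows <- lapply(sessions, function(s) {
    d <- compute_d(s, rules, config)
    data.frame(
      participant = s$participant_id,
      app_type = s$app_type,
      input_method = s$input_method,
      variant = variant_label(s),
      order_index = s$order_index,
      d_practice = d$d_practice,
      d_test = d$d_test,
      d_overall = d$d_overall,
      category = d$category,
      n_errors = session_errors(s),
      n_removed_low = d$n_removed_low,
      n_removed_high = d$n_removed_high,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

measure_frame <- function(sessions, measure, by, rules, config) {
  sessions <- as_session_list(sessions)
  group_of <- function(meta_variant, meta_order) {
    switch(by,
           variant = meta_variant,
           order = paste0("test", meta_order),
           app_type = sub("\\..*$", "", meta_variant),
           input_method = sub("^.*\\.", "", meta_variant))
  }
  if (measure == "latency") {
    tt <- trial_table(sessions, blocks = c(3L, 4L, 6L, 7L), rules = rules)
    data.frame(value = tt$latency_ms,
               group = group_of(tt$variant, tt$order_index),
               stringsAsFactors = FALSE)
  } else {
    ss <- session_summary(sessions, rules = rules %||% cleaning_rules(),
                          config = config)
    value <- switch(measure, d_score = ss$d_overall, errors = ss$n_errors)
    data.frame(value = value,
               group = group_of(ss$variant, ss$order_index),
               stringsAsFactors = FALSE)
  }
}

#' Descriptive table by test variant or test order
#'
#' Per-group n, mean, SD, minimum and maximum of a chosen measure, in the
#' shape of the comparison tables of app/web IAT studies: latencies are
#' summarized at the trial level over the cleaned pairing blocks, while D
#' scores and error counts are summarized per participant and test.
#' A group test ([test_group_effect()]) is attached unless `test = "none"`.
#'
#' @param sessions an `iat_session` or list of them.
#' @param measure `"latency"`, `"d_score"` or `"errors"`.
#' @param by grouping factor: `"variant"` (the four app/input
#'   combinations), `"order"` (test 1-4), `"app_type"` or `"input_method"`.
#' @param rules latency [cleaning_rules()].
#' @param config [scoring_config()] (for D scores).
#' @param test `"kruskal_wallis"` (default), `"anova"` or `"none"`.
#' @return A data frame (class `iat_table`) with attributes `measure`,
#'   `by`, `test_name` and `p_value`.
#' @examples
#' study <- simulate_study(study_design(8), seed = 3)
#' iat_describe(study, "d_score", by = "variant")
#' @export
iat_describe <- function(sessions,
                         measure = c("latency", "d_score", "errors"),
                         by = c("variant", "order", "app_type", "input_method"),
                         rules = cleaning_rules(),
                         config = scoring_config(),
                         test = c("kruskal_wallis", "anova", "none")) {
  measure <- match.arg(measure)
  by <- match.arg(by)
  test <- match.arg(test)
  mf <- measure_frame(sessions, measure, by, rules, config)
  groups <- sort(unique(mf$group))
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- mf$value[mf$group == g]
    if (length(v) == 0L)
      data.frame(group = g, n = 0L, mean = NA_real_, sd = NA_real_,
                 min = NA_real_, max = NA_real_, stringsAsFactors = FALSE)
    else
      data.frame(group = g, n = length(v), mean = mean(v),
                 sd = if (length(v) > 1L) sd(v) else 0,
                 min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "measure") <- measure
  attr(out, "by") <- by
  if (test != "none") {
    ht <- test_group_effect(sessions, measure, by, test = test,
                            rules = rules, config = config)
    attr(out, "test_name") <- ht$method
    attr(out, "p_value") <- ht$p.value
  }
  class(out) <- c("iat_table", "data.frame")
  out
}

#' @export
print.iat_table <- function(x, ...) {
  cat(sprintf("IAT descriptives: %s by %s\n", attr(x, "measure"), attr(x, "by")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (!is.null(attr(x, "p_value")))
    cat(sprintf("%s: p = %.4g\n", attr(x, "test_name"), attr(x, "p_value")))
  invisible(x)
}

#' One-way group test of a measure against a grouping factor
#'
#' Tests whether the chosen measure differs across the levels of the
#' grouping factor, using a one-way fixed-effects ANOVA F test or a
#' Kruskal-Wallis rank sum test. Latencies enter at the trial level
#' (cleaned pairing blocks, ignoring within-participant clustering, as the
#' published comparison tables do); D scores and error counts enter per
#' participant and test. With `cluster = TRUE`, trial-level latencies are
#' first aggregated to per-session means (a deviation from the printed
#' analyses; a warning notes it).
#'
#' @inheritParams iat_describe
#' @param test `"anova"` or `"kruskal_wallis"`.
#' @param cluster aggregate latencies within session before testing.
#' @return A list (class `iat_test`) with `method`, `statistic`, `df`,
#'   `p.value`, `measure`, `by`.
#' @export
test_group_effect <- function(sessions,
                              measure = c("latency", "d_score", "errors"),
                              by = c("variant", "order", "app_type", "input_method"),
                              test = c("anova", "kruskal_wallis"),
                              rules = cleaning_rules(),
                              config = scoring_config(),
                              cluster = FALSE) {
  measure <- match.arg(measure)
  by <- match.arg(by)
  test <- match.arg(test)
  mf <- measure_frame(sessions, measure, by, rules, config)
  if (measure == "latency" && isTRUE(cluster)) {
    warning("aggregating latencies to per-session means before testing; ",
            "the trial-level test is the conventional (unclustered) analysis")
    tt <- trial_table(sessions, blocks = c(3L, 4L, 6L, 7L), rules = rules)
    key <- paste(tt$participant, tt$order_index)
    agg <- tapply(tt$latency_ms, key, mean)
    grp <- tapply(if (by == "order") paste0("test", tt$order_index)
                  else switch(by,
                              variant = tt$variant,
                              app_type = tt$app_type,
                              input_method = tt$input_method),
                  key, `[`, 1L)
    mf <- data.frame(value = as.numeric(agg), group = as.character(grp),
                     stringsAsFactors = FALSE)
  }
  g <- factor(mf$group)
  sizes <- table(g)
  if (nlevels(g) < 2L || sum(sizes >= 2L) < 2L)
    stop_validation("group test needs at least two groups with at least two observations")
  if (stats::var(mf$value) == 0) {
    warning("measure is constant across all groups; returning p = 1")
    res <- list(method = if (test == "anova") "one-way ANOVA" else "Kruskal-Wallis rank sum test",
                statistic = 0, df = c(nlevels(g) - 1L, length(mf$value) - nlevels(g)),
                p.value = 1, measure = measure, by = by)
    class(res) <- "iat_test"
    return(res)
  }
  if (test == "anova") {
    fit <- aov(value ~ g, data = mf)
    s <- summary(fit)[[1L]]
    res <- list(method = "one-way ANOVA",
                statistic = s[["F value"]][1L],
                df = c(s[["Df"]][1L], s[["Df"]][2L]),
                p.value = s[["Pr(>F)"]][1L],
                measure = measure, by = by)
  } else {
    ht <- kruskal.test(mf$value, g)
    res <- list(method = "Kruskal-Wallis rank sum test",
                statistic = unname(ht$statistic),
                df = unname(ht$parameter),
                p.value = ht$p.value,
                measure = measure, by = by)
  }
  class(res) <- "iat_test"
  res
}

#' @export
print.iat_test <- function(x, ...) {
  cat(sprintf("%s: %s by %s\n", x$method, x$measure, x$by))
  cat(sprintf("  statistic = %.4g (df %s), p = %.4g\n",
              x$statistic, paste(x$df, collapse = ", "), x$p.value))
  invisible(x)
}

#' Randomization check: test variant vs. administration order
#'
#' In a properly randomized crossed design the four test variants should be
#' spread evenly over the four administration positions. This computes the
#' 4x4 variant-by-order contingency table and Pearson's chi-squared test
#' (9 degrees of freedom). A non-significant result indicates satisfactory
#' randomization.
#'
#' @param x either a list of `iat_session` objects covering a complete
#'   design (every participant has four sessions, one per variant), or a
#'   4x4 matrix of counts (variants in rows, order positions in columns).
#' @return An object of class `htest` (from [stats::chisq.test()]) with the
#'   contingency table in `$observed`.
#' @examples
#' counts <- matrix(c(18, 9, 12, 12,  11, 14, 14, 12,
#'                    13, 13, 11, 14,  9, 15, 14, 13),
#'                  nrow = 4, byrow = TRUE)
#' randomization_check(counts)$p.value
#' @export
randomization_check <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(4L, 4L)))
      stop_validation("a count matrix must be 4x4 (variant rows, order columns)")
    return(suppressWarnings(chisq.test(x, correct = FALSE)))
  }
  sessions <- as_session_list(x)
  pids <- vapply(sessions, `[[`, "", "participant_id")
  vkeys <- vapply(sessions, variant_label, "")
  orders <- vapply(sessions, `[[`, 0L, "order_index")
  for (p in unique(pids)) {
    sel <- pids == p
    if (sum(sel) != 4L || anyDuplicated(vkeys[sel]) || anyDuplicated(orders[sel]))
      stop_validation(sprintf(
        "participant '%s' must have exactly four sessions, one per variant and order position", p))
  }
  tab <- table(factor(vkeys, levels = c("app.keyboard", "app.touch",
                                        "web.keyboard", "web.touch")),
               factor(orders, levels = 1:4))
  suppressWarnings(chisq.test(tab, correct = FALSE))
}

#' Post-hoc power of a linear ANOVA via the noncentral F distribution
#'
#' Power of the fixed-effects linear-model F test for a stipulated Cohen
#' effect size f-squared, at significance level `alpha`, with `n_predictors`
#' predictors (numerator df) and total sample size `n_total`. The
#' noncentrality parameter is `lambda = f2 * n_total` and the denominator
#' df are `n_total - n_predictors - 1`, matching the G*Power linear
#' multiple-regression convention.
#'
#' @param f2 Cohen's f-squared effect size (default 0.25, a medium-to-large
#'   effect).
#' @param alpha significance level (default 0.05).
#' @param n_predictors number of predictors `u` (default 4).
#' @param n_total total sample size `N` (default 51).
#' @return The power, a number in (0, 1).
#' @examples
#' posthoc_power(f2 = 0.25, alpha = 0.05, n_predictors = 4, n_total = 51)
#' @export
posthoc_power <- function(f2 = 0.25, alpha = 0.05, n_predictors = 4L, n_total = 51L) {
  if (!(f2 > 0)) stop_config("f2 must be positive")
  if (!(alpha > 0 && alpha < 1)) stop_config("alpha must be in (0, 1)")
  u <- as.integer(n_predictors); N <- as.integer(n_total)
  if (!(u >= 1L)) stop_config("n_predictors must be at least 1")
  if (!(N > u + 1L)) stop_config("n_total must exceed n_predictors + 1")
  df2 <- N - u - 1L
  lambda <- f2 * N
  pf(qf(1 - alpha, u, df2), u, df2, ncp = lambda, lower.tail = FALSE)
}
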