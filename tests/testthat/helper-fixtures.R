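# shared fixtures and the independent scoring oracle

tiny_stimuli <- function() {
  iat_stimuli(
    attribute_names = c("positive", "negative"),
    concept_names   = c("concept1", "concept2"),
    attribute_items = list(c("joy", "love", "peace"), c("agony", "hurt", "evil")),
    concept_items   = list(c("c1a", "c1b"), c("c2a", "c2b"))
  )
}

# build a minimal scored session directly (bypassing engine and simulator)
# from four latency vectors; `errors` optionally marks error trials
make_scored_session <- function(b3, b4, b6, b7, compatible_blocks = c(3L, 4L),
                                errors = NULL) {
  mk <- function(lat, b) {
    n <- length(lat)
    err <- if (is.null(errors)) rep(FALSE, n) else errors[[paste0("block", b)]]
    data.frame(
      stimulus = paste0("s", seq_len(n)),
      kind = rep(c("attribute", "concept"), length.out = n),
      cat = rep(1:2, length.out = n),
      trial_code = rep("left-attribute", n),
      pairing = "left: positive or concept1 | right: negative or concept2",
      latency_ms = lat,
      initially_correct = !err,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(participant_id = "T", app_type = "app", input_method = "keyboard",
         order_index = 1L, task_seed = NULL,
         sides = list(attribute_left = 1L, concept_left = 1L),
         compatible_blocks = as.integer(compatible_blocks), complete = TRUE,
         blocks = list(block3 = mk(b3, 3), block4 = mk(b4, 4),
                       block6 = mk(b6, 6), block7 = mk(b7, 7))),
    class = "iat_session"
  )
}

# draw a random scored session with latencies inside (lo, hi)
random_scored_session <- function(n = 10L, lo = 500, hi = 2500,
                                  compatible_blocks = c(3L, 4L)) {
  r <- function() runif(n, lo, hi)
  make_scored_session(r(), r(), r(), r(), compatible_blocks = compatible_blocks)
}

# Independent straight-line D recomputation: explicit means, explicit
# pooled SD over the union (n-1 denominator written out), ratio, average.
# Deliberately shares no code with compute_d().
oracle_d <- function(session, lower = 400, upper = 10000) {
  filt <- function(b) {
    x <- session$blocks[[b]]$latency_ms
    x[x >= lower & x <= upper]
  }
  compat <- session$compatible_blocks
  pair <- function(bc, bi) {
    xc <- filt(paste0("block", bc))
    xi <- filt(paste0("block", bi))
    all <- c(xc, xi)
    ss <- sum((all - sum(all) / length(all))^2)
    sd_pool <- sqrt(ss / (length(all) - 1))
    (sum(xi) / length(xi) - sum(xc) / length(xc)) / sd_pool
  }
  if (3L %in% compat) {
    dp <- pair(3L, 6L); dt <- pair(4L, 7L)
  } else {
    dp <- pair(6L, 3L); dt <- pair(7L, 4L)
  }
  list(d_practice = dp, d_test = dt, d_overall = (dp + dt) / 2)
}

# compact config for fast simulated studies in property tests
fast_config <- function() iat_config(trials_per_block = c(4L, 4L, 4L, 8L, 4L, 4L, 8L))
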