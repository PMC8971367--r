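#' Configure the seven-block IAT task structure
#'
#' The IAT consists of seven blocks: sorting practice for the concepts (B1),
#' sorting practice for the attributes (B2), combined pairing practice and
#' test (B3, B4), concept sorting with sides swapped (B5), and the reversed
#' pairing practice and test (B6, B7). The default trial counts
#' (20, 20, 20, 40, 28, 20, 40) follow the US web IAT; the `"german"` preset
#' raises block 5 to 40 trials.
#'
#' Pairing blocks (3, 4, 6, 7) must have counts divisible by 4 so that the
#' two attribute polarities and the two concepts can each appear equally
#' often within the block.
#'
#' @param trials_per_block integer vector of seven positive trial counts.
#' @param preset `"us"` (default) or `"german"`; presets only set
#'   `trials_per_block` and are overridden by an explicit value.
#' @param randomize_concept_sides if `TRUE` (default) the concept shown on
#'   the left in blocks 1-4 is chosen at random; sides are swapped for
#'   blocks 5-7 either way.
#' @param randomize_attribute_sides if `TRUE` the attribute side is also
#'   randomized; by default the first attribute is always presented left and
#'   keeps that side for the whole task.
#' @param include_instructions include the stimulus overview, the general
#'   instruction and the seven per-block instruction steps.
#' @param include_completion include the final completion step.
#' @param strict_alternation if `TRUE`, pairing blocks strictly alternate
#'   attribute and concept trials; by default the balanced multiset is fully
#'   shuffled.
#' @param seed optional integer seed; [build_task()] uses it to make the
#'   assembled task reproducible without disturbing the caller's RNG stream.
#' @return An object of class `iat_config`.
#' @examples
#' iat_config()
#' iat_config(preset = "german")
#' @export
iat_config <- function(trials_per_block = NULL,
                       preset = c("us", "german"),
                       randomize_concept_sides = TRUE,
                       randomize_attribute_sides = FALSE,
                       include_instructions = TRUE,
                       include_completion = TRUE,
                       strict_alternation = FALSE,
                       seed = NULL) {
  preset <- match.arg(preset)
  if (is.null(trials_per_block)) {
    trials_per_block <- c(20L, 20L, 20L, 40L, 28L, 20L, 40L)
    if (preset == "german") trials_per_block[5L] <- 40L
  }
  if (length(trials_per_block) != 7L || anyNA(trials_per_block))
    stop_config("trials_per_block must give seven trial counts")
  trials_per_block <- as.integer(trials_per_block)
  if (any(trials_per_block <= 0L))
    stop_config("all per-block trial counts must be positive")
  paired <- c(3L, 4L, 6L, 7L)
  bad <- paired[trials_per_block[paired] %% 4L != 0L]
  if (length(bad))
    stop_config(sprintf(
      "pairing block(s) %s must have trial counts divisible by 4 so attributes and concepts can be balanced",
      paste(bad, collapse = ", ")))
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(
      trials_per_block = trials_per_block,
      randomize_concept_sides = isTRUE(randomize_concept_sides),
      randomize_attribute_sides = isTRUE(randomize_attribute_sides),
      include_instructions = isTRUE(include_instructions),
      include_completion = isTRUE(include_completion),
      strict_alternation = isTRUE(strict_alternation),
      seed = seed
    ),
    class = "iat_config"
  )
}

#' @export
print.iat_config <- function(x, ...) {
  cat("IAT task configuration\n")
  cat("  trials per block:", paste(x$trials_per_block, collapse = ", "), "\n")
  cat(sprintf("  randomize sides: concepts %s, attributes %s\n",
              x$randomize_concept_sides, x$randomize_attribute_sides))
  cat(sprintf("  instructions %s, completion %s, strict alternation %s\n",
              x$include_instructions, x$include_completion, x$strict_alternation))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

# draw n items from `items` by cycling independently reshuffled copies, so
# no item repeats before the whole list has been used
cycle_sample <- function(items, n) {
  k <- length(items)
  reps <- ceiling(n / k)
  out <- unlist(lapply(seq_len(reps), function(i) sample(items, k)), use.names = FALSE)
  out[seq_len(n)]
}

# balanced draw over the two categories of one kind; odd counts give the
# spare trial to a random category
sorting_block_trials <- function(item_lists, n) {
  n1 <- n %/% 2L
  if (n %% 2L == 1L) n1 <- n1 + sample(0:1, 1L)
  n2 <- n - n1
  stim <- c(cycle_sample(item_lists[[1L]], n1), cycle_sample(item_lists[[2L]], n2))
  cat <- rep(1:2, c(n1, n2))
  ord <- sample.int(n)
  list(stimulus = stim[ord], cat = cat[ord])
}

# balanced attribute+concept draw for a pairing block (n divisible by 4)
pairing_block_trials <- function(stimuli, n, strict_alternation) {
  q <- n %/% 4L
  attr_stim <- c(cycle_sample(stimuli$attribute_items[[1L]], q),
                 cycle_sample(stimuli$attribute_items[[2L]], q))
  attr_cat <- rep(1:2, each = q)
  con_stim <- c(cycle_sample(stimuli$concept_items[[1L]], q),
                cycle_sample(stimuli$concept_items[[2L]], q))
  con_cat <- rep(1:2, each = q)
  oa <- sample.int(2L * q)
  oc <- sample.int(2L * q)
  attr_stim <- attr_stim[oa]; attr_cat <- attr_cat[oa]
  con_stim <- con_stim[oc]; con_cat <- con_cat[oc]
  if (strict_alternation) {
    first_attribute <- sample(c(TRUE, FALSE), 1L)
    idx_attr <- if (first_attribute) seq(1L, n, by = 2L) else seq(2L, n, by = 2L)
    kind <- rep("concept", n)
    kind[idx_attr] <- "attribute"
  } else {
    kind <- sample(rep(c("attribute", "concept"), each = 2L * q))
  }
  stim <- character(n); cat <- integer(n)
  is_attr <- kind == "attribute"
  stim[is_attr] <- attr_stim; cat[is_attr] <- attr_cat
  stim[!is_attr] <- con_stim; cat[!is_attr] <- con_cat
  list(stimulus = stim, kind = kind, cat = cat)
}

#' Swap the concept sides of a side assignment
#'
#' Block 5 of the IAT changes the sides on which the two concepts are
#' categorized, and blocks 5-7 keep the swapped arrangement; attribute sides
#' are never changed. This helper performs that exchange on a side
#' assignment as stored in an [`iat_task`][build_task]. Applying it twice
#' returns the original assignment.
#'
#' @param sides a list with elements `attribute_left` and `concept_left`
#'   (each 1 or 2, indexing the category shown on the left).
#' @return The assignment with `concept_left` exchanged.
#' @examples
#' swap_concept_sides(list(attribute_left = 1L, concept_left = 1L))
#' @export
swap_concept_sides <- function(sides) {
  if (!all(c("attribute_left", "concept_left") %in% names(sides)))
    stop_validation("sides must have elements 'attribute_left' and 'concept_left'")
  sides$concept_left <- 3L - as.integer(sides$concept_left)
  sides
}

# side assignment in force for block b, given the assignment of blocks 1-4
block_sides <- function(sides, block_index) {
  if (block_index >= 5L) swap_concept_sides(sides) else sides
}

# which categories label the left/right response for block b;
# sorting blocks carry one label per side, pairing blocks two
block_labels <- function(stimuli, sides, block_index) {
  s <- block_sides(sides, block_index)
  al <- s$attribute_left; cl <- s$concept_left
  attr_lab <- stimuli$attribute_names
  con_lab <- stimuli$concept_names
  if (block_index %in% c(1L, 5L)) {
    list(left = con_lab[cl], right = con_lab[3L - cl])
  } else if (block_index == 2L) {
    list(left = attr_lab[al], right = attr_lab[3L - al])
  } else {
    list(left = c(attr_lab[al], con_lab[cl]),
         right = c(attr_lab[3L - al], con_lab[3L - cl]))
  }
}

# correct response side for each trial of a block
derive_correct_side <- function(kind, cat, sides, block_index) {
  s <- block_sides(sides, block_index)
  left_cat <- ifelse(kind == "attribute", s$attribute_left, s$concept_left)
  ifelse(cat == left_cat, "left", "right")
}

#' Build a complete randomized IAT task
#'
#' Assembles the full ordered task: an overview of all stimuli, a general
#' instruction, then for each of the seven blocks an instruction step
#' followed by the block itself, and a completion step — 17 steps in all
#' with every optional step included. Stimuli for the sorting blocks are
#' drawn by cycling reshuffled category lists; pairing blocks contain
#' exactly equal numbers of the two attribute polarities and of the two
#' concepts, in shuffled order. The concept shown on the left in blocks 1-4
#' is randomized (unless disabled) and swapped for blocks 5-7; the first
#' attribute stays on the left throughout unless attribute randomization is
#' enabled.
#'
#' @param stimuli an [iat_stimuli] object.
#' @param config an [iat_config] object; its `seed` (if any) makes the
#'   build reproducible.
#' @return An object of class `iat_task`: a list with the stimulus set, the
#'   configuration, the side assignment of blocks 1-4 (`sides`), and
#'   `steps`, an ordered list of step descriptors. Block steps carry a
#'   `trials` data frame with columns `stimulus`, `kind`
#'   (`"attribute"`/`"concept"`), `cat` (1 or 2 within kind) and
#'   `correct_side`.
#' @examples
#' task <- build_task(example_stimuli(), iat_config(seed = 42))
#' task
#' vapply(task_blocks(task), nrow, 0L)
#' @export
build_task <- function(stimuli, config = iat_config()) {
  if (!inherits(stimuli, "iat_stimuli"))
    stop_validation("stimuli must be an 'iat_stimuli' object (see iat_stimuli())")
  if (!inherits(config, "iat_config"))
    stop_config("config must be an 'iat_config' object (see iat_config())")
  with_seed_or_current(config$seed, build_task_impl(stimuli, config))
}

build_task_impl <- function(stimuli, config) {
  sides <- list(
    attribute_left = if (config$randomize_attribute_sides) sample(1:2, 1L) else 1L,
    concept_left   = if (config$randomize_concept_sides) sample(1:2, 1L) else 1L
  )
  counts <- config$trials_per_block
  steps <- list()
  add <- function(step) steps[[length(steps) + 1L]] <<- step

  if (config$include_instructions) {
    add(list(type = "overview",
             text = "Overview of all attribute and concept stimuli"))
    add(list(type = "instruction",
             text = "General instructions for the implicit association test"))
  }
  for (b in 1:7) {
    n <- counts[b]
    if (b %in% c(1L, 5L)) {
      drawn <- sorting_block_trials(stimuli$concept_items, n)
      kind <- rep("concept", n); cat <- drawn$cat; stim <- drawn$stimulus
    } else if (b == 2L) {
      drawn <- sorting_block_trials(stimuli$attribute_items, n)
      kind <- rep("attribute", n); cat <- drawn$cat; stim <- drawn$stimulus
    } else {
      drawn <- pairing_block_trials(stimuli, n, config$strict_alternation)
      kind <- drawn$kind; cat <- drawn$cat; stim <- drawn$stimulus
    }
    trials <- data.frame(
      stimulus = stim, kind = kind, cat = as.integer(cat),
      correct_side = derive_correct_side(kind, cat, sides, b),
      stringsAsFactors = FALSE
    )
    labels <- block_labels(stimuli, sides, b)
    if (config$include_instructions)
      add(list(type = "instruction",
               text = sprintf("Instructions for block %d (left: %s | right: %s)", b,
                              paste(labels$left, collapse = " or "),
                              paste(labels$right, collapse = " or "))))
    add(list(type = "block", block_index = b, labels = labels, trials = trials))
  }
  if (config$include_completion)
    add(list(type = "completion", text = "The implicit association test is complete"))

  structure(
    list(stimuli = stimuli, config = config, seed = config$seed,
         sides = sides, steps = steps),
    class = "iat_task"
  )
}

#' Extract the seven block steps of a task
#'
#' @param task an `iat_task`.
#' @return A list of seven `trials` data frames, named `block1` ... `block7`.
#' @export
task_blocks <- function(task) {
  stopifnot(inherits(task, "iat_task"))
  blocks <- Filter(function(s) s$type == "block", task$steps)
  blocks <- blocks[order(vapply(blocks, `[[`, 0L, "block_index"))]
  setNames(lapply(blocks, `[[`, "trials"),
           paste0("block", vapply(blocks, `[[`, 0L, "block_index")))
}

#' @export
print.iat_task <- function(x, ...) {
  nb <- vapply(task_blocks(x), nrow, 0L)
  cat("IAT task:", length(x$steps), "steps,", sum(nb), "trials\n")
  cat("  trials per block:", paste(nb, collapse = ", "), "\n")
  cat(sprintf("  left side (blocks 1-4): attribute '%s', concept '%s'\n",
              x$stimuli$attribute_names[x$sides$attribute_left],
              x$stimuli$concept_names[x$sides$concept_left]))
  invisible(x)
}
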