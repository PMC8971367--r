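test_that("stimulus sets are validated", {
  expect_s3_class(tiny_stimuli(), "iat_stimuli")
  expect_error(iat_stimuli(c("a", "a"), c("c1", "c2"),
                           list("x", "y"), list("u", "v")),
               "must differ")
  expect_error(iat_stimuli(c("a", "b"), c("c1", "c2"),
                           list(character(0), "y"), list("u", "v")),
               "non-empty", class = "iat_validation_error")
  expect_error(iat_stimuli(c("a", "b"), c("c1", "c2"),
                           list(c("x", "x"), "y"), list("u", "v")),
               "unique", class = "iat_validation_error")
})

test_that("task config enforces counts and divisibility, with presets", {
  expect_identical(iat_config()$trials_per_block, c(20L, 20L, 20L, 40L, 28L, 20L, 40L))
  expect_identical(iat_config(preset = "german")$trials_per_block[5L], 40L)
  expect_error(iat_config(trials_per_block = c(20, 20, 20, 40, 28, 20, 0)),
               "positive", class = "iat_config_error")
  expect_error(iat_config(trials_per_block = c(20, 20, 18, 40, 28, 20, 40)),
               "divisible by 4", class = "iat_config_error")
  expect_error(iat_config(trials_per_block = c(20, 20)),
               class = "iat_config_error")
})

test_that("default build yields the canonical structure", {
  task <- build_task(tiny_stimuli(), iat_config(seed = 11))
  expect_length(task$steps, 17L)
  sizes <- vapply(task_blocks(task), nrow, 0L)
  expect_identical(unname(sizes), c(20L, 20L, 20L, 40L, 28L, 20L, 40L))
  # pairing blocks hold the 120 scored trials
  expect_identical(sum(sizes[c(3, 4, 6, 7)]), 120L)

  types <- vapply(task$steps, `[[`, "", "type")
  expect_identical(types[1:2], c("overview", "instruction"))
  expect_identical(types[17L], "completion")
  expect_identical(sum(types == "block"), 7L)
  # each block step is directly preceded by its instruction step
  expect_true(all(types[which(types == "block") - 1L] == "instruction"))
})

test_that("instruction and completion steps can be excluded", {
  cfg <- iat_config(include_instructions = FALSE, include_completion = FALSE, seed = 3)
  task <- build_task(tiny_stimuli(), cfg)
  expect_length(task$steps, 7L)
  expect_true(all(vapply(task$steps, `[[`, "", "type") == "block"))
  cfg2 <- iat_config(include_instructions = FALSE, seed = 3)
  expect_length(build_task(tiny_stimuli(), cfg2)$steps, 8L)
})

test_that("the same seed rebuilds an identical task; different seeds reshuffle", {
  s <- tiny_stimuli()
  t1 <- build_task(s, iat_config(seed = 99))
  t2 <- build_task(s, iat_config(seed = 99))
  expect_identical(task_blocks(t1), task_blocks(t2))
  expect_identical(t1$sides, t2$sides)
  t3 <- build_task(s, iat_config(seed = 100))
  expect_false(identical(task_blocks(t1), task_blocks(t3)))
  # composition counts are identical even when the shuffle differs
  comp <- function(task) lapply(task_blocks(task), function(b) table(b$kind, b$cat))
  expect_identical(comp(t1), comp(t3))
})

test_that("pairing blocks are exactly balanced for any valid config and seed", {
  withr::local_seed(42)
  s <- tiny_stimuli()
  for (rep in 1:40) {
    counts <- c(sample(c(5:30), 3L), 4L * sample(1:10, 1L),
                sample(5:40, 1L), 0L, 0L)
    counts[3L] <- 4L * sample(1:8, 1L)
    counts[6L] <- 4L * sample(1:8, 1L)
    counts[7L] <- 4L * sample(1:10, 1L)
    cfg <- iat_config(trials_per_block = counts,
                      strict_alternation = rep %% 2L == 0L)
    task <- build_task(s, cfg)
    bl <- task_blocks(task)
    expect_identical(unname(vapply(bl, nrow, 0L)), as.integer(counts))
    for (b in c(3, 4, 6, 7)) {
      tr <- bl[[paste0("block", b)]]
      tab <- table(tr$kind, tr$cat)
      expect_true(all(tab == counts[b] / 4L),
                  label = sprintf("balance in block %d (counts %s)", b,
                                  paste(counts, collapse = ",")))
      if (cfg$strict_alternation)
        expect_true(all(tr$kind[-1L] != tr$kind[-nrow(tr)]))
    }
    # stored correct sides must equal those re-derived from the side assignment
    for (b in 1:7) {
      tr <- bl[[paste0("block", b)]]
      derived <- iatkit:::derive_correct_side(tr$kind, tr$cat, task$sides, b)
      expect_identical(tr$correct_side, derived)
    }
  }
})

test_that("concept sides swap at block 5 and attribute sides never move", {
  task <- build_task(tiny_stimuli(), iat_config(seed = 5))
  s14 <- task$sides
  s57 <- iatkit:::block_sides(task$sides, 5L)
  expect_identical(s57$concept_left, 3L - s14$concept_left)
  expect_identical(s57$attribute_left, s14$attribute_left)
  lab1 <- iatkit:::block_labels(task$stimuli, task$sides, 1L)
  lab5 <- iatkit:::block_labels(task$stimuli, task$sides, 5L)
  expect_identical(lab1$left, lab5$right)
  lab2 <- iatkit:::block_labels(task$stimuli, task$sides, 2L)
  lab6 <- iatkit:::block_labels(task$stimuli, task$sides, 6L)
  expect_identical(lab2$left, lab6$left[1L])
  # sorting blocks carry one label per side, pairing blocks two
  expect_length(lab1$left, 1L)
  expect_length(lab6$left, 2L)
})

test_that("swapping concept sides twice restores the original assignment", {
  sides <- list(attribute_left = 1L, concept_left = 2L)
  expect_identical(swap_concept_sides(sides)$concept_left, 1L)
  expect_identical(swap_concept_sides(swap_concept_sides(sides)), sides)
})

test_that("with randomization on, each concept starts left in about half of tasks", {
  s <- tiny_stimuli()
  cfg <- iat_config(include_instructions = FALSE, include_completion = FALSE,
                    trials_per_block = c(2, 2, 4, 4, 2, 4, 4))
  left1 <- vapply(1:400, function(i) {
    cfg$seed <- i
    build_task(s, cfg)$sides$concept_left == 1L
  }, TRUE)
  bt <- binom.test(sum(left1), 400, p = 0.5)
  expect_gt(bt$p.value, 0.01)
  # attributes stay first-left by default
  expect_true(all(vapply(1:20, function(i) {
    cfg$seed <- i
    build_task(s, cfg)$sides$attribute_left == 1L
  }, TRUE)))
})
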